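# fastaforge

fastaforge is an R toolkit and command-line suite for building FASTA
sequence datasets — the preparatory work (filtering, sorting, editing,
translating, deduplicating, merging and splitting DNA or protein FASTA
files) that precedes most comparative and phylogenetic analyses — together
with two higher-level components:

- a **conserved-gene annotation pipeline** that, given genomic regions and
  a single reference protein, discovers open reading frames, matches them
  to the reference, and joins the matched exons across canonical GT–AG
  splice junctions into a predicted CDS and protein;
- a **convention-based pipeline engine** that chains toolkit commands into
  declarative task graphs over a workspace directory layout, with
  batching, per-task parameter files, foreign shell tasks, failure
  isolation and resume.

It is aimed at researchers who want reproducible, scriptable dataset
preparation: every command can record its configuration to a JSON
parameter file and replay it byte-identically, and every operation is
exposed both as an R function and as a CLI subcommand with a shared set of
input/output options.

## The methods at the core

**Protein search.** Exact Smith–Waterman local alignment with affine gaps
(Gotoh), BLOSUM62 scoring, gap open 11 / extend 1, implemented in C++.
Significance is assessed with the Karlin–Altschul expectation

    E = K · m · n · exp(−λ · S)

with m the query length, n the total database length and
(λ, K) = (0.267, 0.041), the published gapped values for this scoring.
Hits pass at `E < 0.05` (strict) and are reported in BLAST `outfmt 6`
tabular layout.

**ORF discovery.** Maximal stop-to-stop stretches in all six frames
(sequence ends count as boundaries), reported when strictly longer than
`min_orf_length` nucleotides (default 30), with forward-strand 1-based
coordinates.

**Exon joining.** Significant matches are chained by a maximum-score
dynamic program consistent in genomic and reference coordinates, then
junctions are refined iteratively: candidate GT donor / AG acceptor pairs
within a ±30 nt window (widened by the reference-overlap of adjacent
matches) are ranked by the identity of the resulting translation against
the reference; internal stop codons shift the offending junction to its
next candidate; the model is accepted when the final translation aligns
significantly with non-decreasing reference coverage. Failures keep the
best partial model and a log naming the junction.

See `vignettes/fastaforge-methods.Rmd` for the full description, defaults
and design rationale.

## Worked example

Generate a synthetic three-exon gene and annotate it with its own protein
as the reference:

```r
library(fastaforge)

fx <- make_gene_fixture(3, seed = 11)
fx
#> <gene_fixture> seed 11: 3 exon(s), CDS 468 nt, protein 155 aa, region 4020 nt

out <- tempfile()
s <- run_cga(fx$region, dataset("ref", "", fx$protein), out)
s[, c("region_id", "status", "n_exons")]
#>   region_id status n_exons
#> 1  gene_s11 joined       3

identical(s$pep, fx$protein)
#> [1] TRUE
```

The per-region output directory contains the numbered stage files —
`01_orfs.nuc.fasta` / `01_orfs.prot.fasta` (ORFs), `02_*.ini`
(significant matches), `03_*.ini.sorted` (transcript order),
`04_*.join_exons_results` (joined DNA + refinement log), and the four
`05_` outputs (pre-predict DNA, predicted CDS, predicted protein, and the
reference-vs-prediction search table). The sorted match table for this
run:

```
           orf_id strand start  end ref_start ref_end      e_value score
1 gene_s11_orf192      +   501  602         1      34 1.200669e-14   160
2 gene_s11_orf134      +  2173 2382        32     101 1.116000e-36   350
3 gene_s11_orf182      +  3347 3517        99     155 3.477246e-30   294
```

Three exon candidates in transcript order, each significantly matching a
consecutive stretch of the reference (columns: ORF, strand, genomic span,
reference span, E-value, raw score); joining them recovers the 155-residue
protein exactly.

The same run from a shell:

```sh
fastaforge cga -if region.fasta --reference ref.fasta -od out/
fastaforge filter-by-length -id data/ -od filtered/ --min-length 200 -spf params.json
fastaforge filter-by-length -id data/ -od again/ -pf params.json   # identical outputs
fastaforge pipeline run pipeline.xml workspace/
```

`fastaforge <command> --help` prints the command-specific options followed
by the common option categories; `fastaforge man-pages <dir>` generates
matching man pages.

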