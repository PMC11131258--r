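---
title: "fastaforge: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fastaforge: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastaforge)
```

fastaforge is a toolkit for building FASTA sequence datasets: a library of
filtering/sorting/editing operations with a uniform command-line surface,
reproducible JSON parameter files, a self-contained conserved-gene
annotation pipeline, and a convention-based workflow engine. This vignette
explains the methods behind each component, the tunable parameters and
their defaults, what the synthetic-data generators emulate, and the design
choices made where the design was genuinely open.

## The FASTA data model

A dataset is an ordered collection of records, each with an `id` (the first
whitespace-delimited word of the header), a free-text `description` and a
residue string whose case is preserved. Duplicate ids are allowed — FASTA
permits them — and operations requiring uniqueness say so. The reader is
tolerant (LF or CRLF endings, blank lines, gzip detected by its two magic
bytes rather than by extension) while the writer is strict (LF endings, a
single wrapping width). The wrapping dialect observed at read time travels
with the dataset so a write can reproduce the input's layout; when the
dialect is unknown, 80 columns are used. This tolerant-read / strict-write
asymmetry maximises interoperability: anything plausible is accepted, and
everything produced is canonical.

Two processing modes are offered for multi-file batches. In-memory mode
loads every input before writing any output; on-disk mode streams one file
at a time, bounding the resident record count by the largest single file.
The modes are contractually byte-identical — a property the test suite
enforces for every operation — so the choice is purely a memory/speed
trade-off.

Directory input enumerates files with recognised FASTA suffixes in
C-locale lexicographic order; this filter and order are this package's
convention (deterministic enumeration is what matters). Output grouping
(`--output-group-size N`) moves results into `group_1`, `group_2`, ...
subdirectories of at most N files, all but the last exactly N; the
`group_` prefix is likewise a documented convention. The default 0
creates no subdirectories.

## Dataset operations

All filters report `removed_count` and preserve input order; kept and
removed records always partition the input. Length bounds are inclusive.
Pattern filters use Perl-compatible regular expressions, case-sensitive
unless a flag says otherwise, matching either `"id description"` or the
residues. Sorts are stable (ties keep input order) and therefore
idempotent.

Translation follows transeq conventions: frame *f* skips *f − 1* leading
bases, the trailing partial codon is dropped, stops are written `*`, and a
codon containing IUPAC ambiguity codes is translated by expanding every
concrete codon it denotes — if all expansions agree the unambiguous amino
acid is emitted, otherwise `X` (so `GCN` is `A` but `ATN` is `X`).
Reverse-complement uses the full IUPAC pairing table and preserves case.

Isoform removal needs a concrete grouping rule: two records belong to the
same gene when their headers share a word (maximal alphanumeric run) of at
least `min_word_length` characters, with groups closed transitively.
Within a group the record whose length is closest to `reference_size`
survives, the earliest record winning ties. Grouping depends only on
headers, so it is invariant under permutation of the sequences.

## Parameter files

Every command can save its effective configuration to a JSON file
(`--save-parameters-file`) and reload it (`--parameters-file`). The schema
is `{"command", "version", "parameters"}` with recursively sorted keys and
two-space indentation, so equal configurations serialize to identical
bytes and replayed runs are byte-identical — the replay property is tested
through the CLI for every command. This schema is this package's own
dialect (it is not byte-compatible with other tools' files). Unknown
parameter names are rejected at load rather than ignored: silently
dropping a typo like `min-lenght` would change results without warning.
Precedence is explicit flags > file values > command defaults, which
enables partial reuse of a saved file. A `version` field is recorded
defensively for future migrations.

## Protein similarity search

The annotation pipeline needs a protein search step. Rather than shelling
out to an external aligner, fastaforge implements exact Smith–Waterman
local alignment with affine gaps (Gotoh's algorithm, in C++): a gap of
length $L$ costs $o + Le$ with defaults $o = 11$, $e = 1$, scored with
BLOSUM62. Because scores are exact rather than heuristic, hits are a
superset of what a seeded heuristic search would return at the same
threshold. Traceback is deterministic: at an alignment cell the preference
is diagonal, then up, then left, and within a gap the shortest gap
consistent with the score is reported.

Significance uses the Karlin–Altschul form
$E = K m n\, e^{-\lambda S}$ with $m$ the query length, $n$ the total
database length, and $(\lambda, K) = (0.267, 0.041)$, the published gapped
values for BLOSUM62 with gap open 11 / extend 1. No edge-effect correction
is applied — the databases here (ORF sets of single regions) are small,
where the correction is negligible relative to the 0.05 decision
threshold. Hits pass at `e_value < threshold` (strictly), sorted by
ascending E-value then descending raw score. Tabular output follows the
twelve-column BLAST `outfmt 6` layout.

The implementation is checked two independent ways: against a brute-force
oracle that enumerates all start pairs and runs a plain affine DP over the
suffixes, and against `Biostrings::pairwiseAlignment(type = "local")` with
identical scoring.

## Conserved-gene annotation

Given a FASTA of genomic regions and exactly one reference protein, each
region is annotated independently through five stages, writing numbered
per-region files (`01_` ORFs, `02_` matches, `03_` sorted matches, `04_`
joined sequence, `05_` prediction).

**ORF discovery.** ORFs are maximal stop-to-stop stretches in all six
frames, including stretches bounded by the sequence ends, reported when
strictly longer than `min_orf_length` nucleotides (default 30, taken
literally as "longer than"). They are not ATG-anchored: internal exons do
not begin with a start codon, and anchoring would miss them. Coordinates
are always forward-strand 1-based inclusive; a brute-force scanner oracle
checks the implementation on random sequences.

**Matching.** The reference protein is searched against the ORF
translations; hits with `e_value < 0.05` become exon candidates, their
aligned subject spans mapped back to genomic coordinates. One wrinkle is
resolved here: a short intron whose length is divisible by three and which
happens to contain no in-frame stop lets a single ORF run through two
exons. Such alignments are recognisable by a long subject-side insertion
(the intron's residues) in the traceback, so alignments are split into
separate candidates at insertions of ≥ 8 residues — comfortably above
incidental gaps and below the 20-residue minimum intron.

**Sorting.** Candidates are ordered by genomic start — descending when the
score-weighted dominant strand is minus, so exon order always follows
transcript order. Ties are stable.

**Joining.** The sorted candidates are first reduced to the maximum-score
chain that is consistent in both genomic and reference coordinates.
Alignment tails can creep into introns by chance (a run of random residues
with net positive score), so chain compatibility tolerates overlaps — up
to 120 nt genomic and 40 reference residues, with up to 12 residues of
reference end-regression for the containment case where a creeping tail
swallows a tiny exon's span. These bounds reflect how far a
positive-scoring random extension can plausibly reach under BLOSUM62 with
gap open 11 (the expected drift per column is negative, so long creeps are
exponentially rare).

Junction refinement then runs as an iterative cycle. The translation start
is anchored at the ATG near the mapped position of reference residue 1
(candidates ranked by ungapped identity of the resulting translation
against the reference N-terminus). For each junction, candidate donor
(`GT` after the cut) / acceptor (`AG` before the cut) pairs are enumerated
within a window of ±`junction_window` nt (default 30) around the aligned
boundaries — widened inward by 3 nt per residue of reference-coordinate
overlap between the adjacent matches, since that overlap bounds the
alignment creep. Candidates are ranked by the ungapped positional identity
of the tentative translation against the reference (cheap, and exact when
upstream junctions are correct), requiring a stop-free prefix. The
terminal exon end is chosen frame-consistently, preferring a position
followed by a stop codon when the reference C-terminus is covered. The
assembled CDS is translated; an internal stop shifts the offending
junction to its next-ranked candidate pair and the cycle repeats (at most
8 cycles). The model is accepted when the final translation aligns to the
reference with `e_value` below threshold and non-decreasing coverage;
otherwise the best partial model is kept with status `failed` and a log
naming the problem junction, so the `04_`/`05_` artifacts remain useful
for manual refinement.

**Prediction.** ORF discovery runs on the joined sequence with the
user's `min_cds_size`; the chosen ORF's nucleotides and frame-+1
translation become the `05_*.nuc` / `05_*.pep` outputs, and a search with
the reference as query against the predicted protein is written as
`05_*.pep.blast` as a self-check. Among qualifying ORFs the one whose
translation aligns best to the reference is reported, with alternates
listed in the log. Choosing the *longest* instead would fail on short
genes for a structural reason: the reverse complement of a short stop-free
CDS is itself stop-free in some frame with probability
$(61/64)^{n}$ per frame, which for a 20-codon CDS is about 0.38 — the
longest ORF would then frequently be a reverse-strand artifact. The
reference alignment is precisely the discriminating evidence this stage
computes anyway.

The joined sequence (pre-prediction) is written twice by design — as
`04_*.join_exons_results` and `05_*.join_exons_results` — the former as
the joining stage's artifact, the latter alongside the prediction for
manual refinement. The refinement log goes to a sibling `.log` file so
that every `04_` artifact stays valid FASTA. The ORF files are named
`01_orfs.nuc.fasta` / `01_orfs.prot.fasta` (consistent underscore form).
The `02_`/`03_` match tables are tab-separated with a header row:
`orf_id, strand, start, end, ref_start, ref_end, e_value, score`.

## Pipelines

Pipelines are declarative XML (a YAML front-end with identical semantics
is also accepted): tasks named by the command they run, disambiguated with
a `_<digits>` suffix when a command appears twice, ordered by `after`
dependencies. Inputs follow directory conventions — `input/<task_id>/` for
initial tasks, the union of `output/<predecessor>/` for dependent ones,
with `input/lists/<task_id>.txt` overriding either — and parameters come
from `params/<task_id>.sedaParams` (JSON) or `params/<task_id>.cliParams`
(one line of CLI arguments), both present being an ambiguity error.
Parameter files are keyed by full task id, not bare command name, so
`filter-by-length_1` and `filter-by-length_2` can differ in configuration.
A task element with text content is a foreign task: the text runs under
`bash` with `INPUT_DIR` (a staging directory holding the batch),
`OUTPUT_DIR` and `WORKSPACE` in the environment, nonzero exit meaning
failure.

Execution is sequential in a deterministic topological order (ready tasks
run in definition order). Batching splits a task's inputs into groups of
`batchSize` files, the command running once per group; any partition
yields a byte-identical output tree because outputs are keyed by input
basename. A failed task marks its descendants `failed-upstream` while
independent branches continue; re-running with `resume` skips tasks whose
output directory is non-empty, so deleting one task's output re-executes
exactly that task. Mixed sources (a dependent task also reading
`input/<task_id>`) are deliberately not supported — the list override is
the escape hatch. Logs (one per task plus a pipeline summary) live under
`logs/`, outside the data directories.

## Synthetic data

`random_dataset()` draws uniform residues with `seq_<k> <word>` headers.
`make_gene_fixture()` builds a gene the annotation pipeline should be able
to recover exactly: a CDS starting `ATG`, interior codons drawn from the
61 sense codons (rejection of stops), one terminal stop; split into exons
at codon boundaries; introns beginning `GT` and ending `AG`; random
flanks. Construction re-asserts every invariant (exon slices concatenate
to the CDS, translation is protein + `*`, canonical splice
dinucleotides). All generators are pure functions of their parameters and
seed, and restore the caller's RNG state.

The fixtures emulate what the joining procedure exploits — canonical
splice sites, stop-free single-frame CDS, codon-aligned exon boundaries —
and deliberately omit much of real genomes: realistic codon usage and GC
content, non-canonical splice sites, phase-1/2 exon boundaries,
alternative splicing, paralogues and repeats, sequencing errors. Passing
recovery tests therefore demonstrates the machinery is correct under its
own assumptions, not that it matches curated annotations of real loci.

Default study conditions for recovery experiments: 50 genes with 1–5
exons, exon lengths 60–600 nt, intron lengths 60–2000 nt, 500 nt flanks.
The suite's oracle comparisons use 200 sequences (≤ 2 kb) for the ORF
scanner, 500 pairs (≤ 20 residues) for the aligner, and 200 datasets for
filter recounts; the brute-force oracles dominate the runtime, not the
implementations.

## Known limitations

- The aligner is exact and quadratic; it is sized for reference-vs-ORF
  searches (a few hundred residues against a few hundred short
  translations), not genome-scale databases.
- Karlin–Altschul parameters are fixed for BLOSUM62/gap(11,1); supplying a
  different matrix changes scores but not $(\lambda, K)$.
- The annotation pipeline assumes one gene per region on one strand, with
  GT–AG introns; trans-splicing, overlapping genes and non-canonical
  junctions are out of scope (the latter fail with a diagnosis rather
  than silently).
- The pipeline engine runs tasks sequentially; it trades scheduling
  sophistication for determinism and auditability.
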