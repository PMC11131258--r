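# Deterministic generators for test inputs: random FASTA datasets and
# multi-exon gene fixtures with canonical GT-AG splice sites embedded in
# random genomic context. All generators are pure functions of their
# parameters and seed.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

random_word <- function(len = 6) paste(sample(letters, len, replace = TRUE),
                                       collapse = "")

#' Generate a random FASTA dataset
#'
#' Headers are `seq_<k> <random word>`; residues are drawn uniformly from
#' the alphabet. Reproducible from `seed`.
#'
#' @param n_records number of records.
#' @param length_range inclusive range of sequence lengths.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param seed integer seed.
#' @return a [dataset()].
#' @export
random_dataset <- function(n_records, length_range = c(50, 500),
                           alphabet = c("nucleotide", "protein"), seed = 1) {
  alphabet <- match.arg(alphabet)
  letters_pool <- if (alphabet == "nucleotide") c("A", "C", "G", "T") else AA20
  with_seed(seed, {
    lens <- if (n_records > 0)
      sample(seq(length_range[1], length_range[2]), n_records, replace = TRUE)
    else integer()
    seqs <- vapply(lens, function(l)
      paste(sample(letters_pool, l, replace = TRUE), collapse = ""), character(1))
    words <- vapply(seq_len(n_records), function(i) random_word(), character(1))
    dataset(sprintf("seq_%d", seq_len(n_records)), words, seqs)
  })
}

random_nuc <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

#' Generate a multi-exon gene fixture
#'
#' Builds a stop-free CDS (ATG start, one terminal stop; interior codons
#' drawn by rejection from the 61 sense codons), splits it into `n_exons`
#' exons at codon-respecting cut points, inserts introns beginning `GT` and
#' ending `AG`, and embeds the gene in random flanking sequence. All
#' invariants (exon slices reproduce the CDS; translation reproduces the
#' protein plus terminal `*`; canonical splice dinucleotides) are
#' re-asserted on every construction.
#'
#' @param n_exons number of exons (>= 1).
#' @param exon_len_range inclusive exon-length range in nucleotides; values
#'   are rounded to codon multiples (minimum 6).
#' @param intron_len_range inclusive intron-length range (minimum 10).
#' @param flank_len flanking sequence length on each side.
#' @param seed integer seed.
#' @return a `gene_fixture`: list with `protein`, `cds`, `exons` and
#'   `introns` (forward-strand 1-based interval data frames), `region` (a
#'   single-record [dataset()]) and `seed`.
#' @export
make_gene_fixture <- function(n_exons, exon_len_range = c(60, 600),
                              intron_len_range = c(60, 2000),
                              flank_len = 500, seed = 1) {
  if (n_exons < 1) usage_error("n_exons must be >= 1")
  if (exon_len_range[1] < 6) usage_error("exons must be at least 6 nt")
  if (n_exons > 1 && intron_len_range[1] < 10)
    usage_error("introns must be at least 10 nt")
  with_seed(seed, {
    exon_lens <- 3L * pmax(2L, round(sample(
      seq(exon_len_range[1], exon_len_range[2]), n_exons, replace = TRUE) / 3))
    cds_len <- sum(exon_lens)
    n_cod <- cds_len %/% 3L
    codons <- c("ATG", sample(SENSE_CODONS, n_cod - 2L, replace = TRUE),
                sample(c("TAA", "TAG", "TGA"), 1L))
    cds <- paste(codons, collapse = "")
    intron_lens <- if (n_exons > 1)
      sample(seq(intron_len_range[1], intron_len_range[2]), n_exons - 1L,
             replace = TRUE) else integer()
    introns_seq <- vapply(intron_lens, function(l)
      paste0("GT", random_nuc(l - 4L), "AG"), character(1))
    flank5 <- random_nuc(flank_len); flank3 <- random_nuc(flank_len)
    pieces <- character(2L * n_exons - 1L)
    cut_ends <- cumsum(exon_lens)
    cut_starts <- c(1L, utils::head(cut_ends, -1L) + 1L)
    for (i in seq_len(n_exons)) {
      pieces[2L * i - 1L] <- substr(cds, cut_starts[i], cut_ends[i])
      if (i < n_exons) pieces[2L * i] <- introns_seq[i]
    }
    region_seq <- paste0(flank5, paste(pieces, collapse = ""), flank3)
    # interval bookkeeping
    pos <- flank_len
    exons <- data.frame(start = integer(n_exons), end = integer(n_exons))
    introns <- data.frame(start = integer(max(n_exons - 1L, 0L)),
                          end = integer(max(n_exons - 1L, 0L)))
    for (i in seq_len(n_exons)) {
      exons$start[i] <- pos + 1L
      exons$end[i] <- pos + exon_lens[i]
      pos <- exons$end[i]
      if (i < n_exons) {
        introns$start[i] <- pos + 1L
        introns$end[i] <- pos + intron_lens[i]
        pos <- introns$end[i]
      }
    }
    protein <- sub("\\*$", "", translate_nuc(cds))
    fx <- structure(list(protein = protein, cds = cds, exons = exons,
                         introns = introns,
                         region = dataset(sprintf("gene_s%d", seed),
                                          sprintf("%d exon(s)", n_exons),
                                          region_seq),
                         seed = seed),
                    class = "gene_fixture")
    assert_gene_fixture(fx)
    fx
  })
}

# construction-time invariant checks
assert_gene_fixture <- function(fx) {
  region <- fx$region$seq[1]
  slices <- substring(region, fx$exons$start, fx$exons$end)
  stopifnot(identical(paste(slices, collapse = ""), fx$cds))
  stopifnot(identical(translate_nuc(fx$cds), paste0(fx$protein, "*")))
  stopifnot(!grepl("*", fx$protein, fixed = TRUE))
  if (nrow(fx$introns)) {
    stopifnot(all(substring(region, fx$introns$start,
                            fx$introns$start + 1L) == "GT"))
    stopifnot(all(substring(region, fx$introns$end - 1L,
                            fx$introns$end) == "AG"))
  }
  invisible(TRUE)
}

#' @export
print.gene_fixture <- function(x, ...) {
  cat(sprintf("<gene_fixture> seed %d: %d exon(s), CDS %d nt, protein %d aa, region %d nt\n",
              x$seed, nrow(x$exons), nchar(x$cds), nchar(x$protein),
              nchar(x$region$seq[1])))
  invisible(x)
}

#' Materialise a pipeline-workspace fixture
#'
#' Writes the `input/`, `input/lists/` and `params/` tree plus a
#' `pipeline.xml` for one of the named engine test cases.
#'
#' @param pipeline_case one of `"chain"` (filter -> sort -> edit),
#'   `"diamond"` (`filter-by-length_1`, `filter-by-length_2` ->
#'   `merge-datasets`), `"batching"` (single task over several files),
#'   `"list-override"` (chain whose second task reads an
#'   `input/lists/<id>.txt` subset) or `"empty"` (bare directories only).
#' @param root workspace root directory (created).
#' @param seed seed for the generated input datasets.
#' @return `root`, invisibly.
#' @export
write_workspace <- function(pipeline_case = c("chain", "diamond", "batching",
                                              "list-override", "empty"),
                            root, seed = 1) {
  pipeline_case <- match.arg(pipeline_case)
  for (d in c("input", "input/lists", "params", "output"))
    dir.create(file.path(root, d), showWarnings = FALSE, recursive = TRUE)
  put_inputs <- function(task, n_files, seed0) {
    dir.create(file.path(root, "input", task), showWarnings = FALSE,
               recursive = TRUE)
    vapply(seq_len(n_files), function(k) {
      d <- random_dataset(5, c(30, 120), seed = seed0 + k)
      write_fasta(d, file.path(root, "input", task,
                               sprintf("in_%d.fasta", k)))
    }, character(1))
  }
  xml <- switch(pipeline_case,
    empty = '<pipeline><tasks/></pipeline>',
    chain = {
      put_inputs("filter-by-length", 3, seed)
      save_parameters(operation_config("filter-by-length",
                                       list(`min-length` = 40)),
                      file.path(root, "params", "filter-by-length.sedaParams"))
      writeLines("--by header", file.path(root, "params",
                                          "sort-sequences.cliParams"))
      paste0('<pipeline><tasks>',
             '<task id="filter-by-length"/>',
             '<task id="sort-sequences" after="filter-by-length"/>',
             '<task id="edit-headers" after="sort-sequences"/>',
             '</tasks></pipeline>')
    },
    diamond = {
      put_inputs("filter-by-length_1", 2, seed)
      put_inputs("filter-by-length_2", 2, seed + 100)
      save_parameters(operation_config("filter-by-length",
                                       list(`min-length` = 35)),
                      file.path(root, "params", "filter-by-length_1.sedaParams"))
      save_parameters(operation_config("filter-by-length",
                                       list(`max-length` = 100)),
                      file.path(root, "params", "filter-by-length_2.sedaParams"))
      paste0('<pipeline><tasks>',
             '<task id="filter-by-length_1"/>',
             '<task id="filter-by-length_2"/>',
             '<task id="merge-datasets" after="filter-by-length_1 filter-by-length_2"/>',
             '</tasks></pipeline>')
    },
    batching = {
      put_inputs("sort-sequences", 7, seed)
      '<pipeline><tasks><task id="sort-sequences" batchSize="3"/></tasks></pipeline>'
    },
    "list-override" = {
      files <- put_inputs("filter-by-length", 3, seed)
      dir.create(file.path(root, "input", "sort-sequences"),
                 showWarnings = FALSE)
      writeLines(c("# subset to re-analyse", files[2]),
                 file.path(root, "input", "lists", "filter-by-length.txt"))
      save_parameters(operation_config("filter-by-length",
                                       list(`min-length` = 0)),
                      file.path(root, "params", "filter-by-length.sedaParams"))
      paste0('<pipeline><tasks>',
             '<task id="filter-by-length"/>',
             '</tasks></pipeline>')
    })
  writeLines(xml, file.path(root, "pipeline.xml"))
  invisible(root)
}
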