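# Filtering, sorting and editing operations, plus the transforms used by
# the annotation pipeline.

mkd <- function(ids, seqs, desc = character(length(ids)))
  dataset(ids, desc, seqs)

test_that("length filter honours inclusive bounds and complements", {
  d <- mkd(c("a", "b", "c"), c("AAA", "AAAAA", "AAAAAAA"))
  r <- filter_by_length(d, 4, 6, keep = "inside")
  expect_equal(r$dataset$id, "b")
  expect_equal(r$removed_count, 2L)
  expect_equal(filter_by_length(d, min_len = 0, keep = "inside")$dataset$id,
               d$id)
  out <- filter_by_length(d, 4, 6, keep = "outside")$dataset$id
  expect_setequal(c(out, "b"), d$id)
  expect_error(filter_by_length(d), class = "ff_usage_error")
  # removed + kept partition the input, on random data
  for (seed in 1:25) {
    rd <- random_dataset(10, c(0, 40), seed = seed)
    r2 <- filter_by_length(rd, 10, 25)
    expect_equal(r2$removed_count, 10L - n_records(r2$dataset))
    brute <- sum(nchar(rd$seq) >= 10 & nchar(rd$seq) <= 25)
    expect_equal(n_records(r2$dataset), brute)
  }
})

test_that("pattern filter targets header or sequence and reports bad regex", {
  d <- mkd(c("gene1", "gene2"), c("ACGT", "TTTT"),
           c("kinase", "phosphatase"))
  expect_equal(filter_by_pattern(d, "kinase", "header")$dataset$id, "gene1")
  expect_equal(filter_by_pattern(d, "^T+$", "sequence")$dataset$id, "gene2")
  expect_equal(filter_by_pattern(d, ".*")$dataset$id, d$id)
  expect_equal(filter_by_pattern(d, "KINASE", case_sensitive = FALSE,
                                 keep = "match")$dataset$id, "gene1")
  m <- filter_by_pattern(d, "kin", keep = "match")$dataset$id
  nm <- filter_by_pattern(d, "kin", keep = "no-match")$dataset$id
  expect_setequal(c(m, nm), d$id)
  expect_error(filter_by_pattern(d, "(unclosed"), "unclosed",
               class = "ff_usage_error")
})

test_that("sorting is correct, stable and idempotent", {
  d <- mkd(c("x", "y", "z"), c("AAAAA", "AAA", "AAAA"))
  expect_equal(sort_sequences(d, "length")$id, c("y", "z", "x"))
  expect_equal(sort_sequences(d, "length", descending = TRUE)$id,
               c("x", "z", "y"))
  expect_equal(n_records(sort_sequences(dataset(), "length")), 0L)
  # stability: equal keys keep input order
  d2 <- mkd(c("b", "a", "c"), c("AA", "AA", "AA"))
  expect_equal(sort_sequences(d2, "length")$id, c("b", "a", "c"))
  once <- sort_sequences(d, "header")
  expect_identical(sort_sequences(once, "header"), once)
})

test_that("header editing modes behave as documented", {
  d <- mkd(c("s1", "s2"), c("A", "C"), c("d1", ""))
  expect_equal(edit_headers(d, "add-prefix", text = "v2")$id,
               c("v2_s1", "v2_s2"))
  expect_equal(edit_headers(d, "add-suffix", text = "x", separator = "-")$id,
               c("s1-x", "s2-x"))
  expect_equal(edit_headers(d, "number")$id, c("s1_1", "s2_2"))
  r <- edit_headers(d, "replace", find = "d1", text = "longer description")
  expect_equal(r$desc[1], "longer description")
  expect_identical(edit_headers(d, "replace", find = "zz", text = "q")$id, d$id)
  expect_error(edit_headers(d, "replace", text = "q"), class = "ff_usage_error")
  expect_identical(edit_headers(d, "number")$seq, d$seq)
})

test_that("reverse-complement handles IUPAC codes, case and involution", {
  d <- mkd("a", "AAC")
  expect_equal(reverse_complement(d)$seq, "GTT")
  expect_equal(reverse_complement(mkd("a", "ACGT"))$seq, "ACGT")
  expect_equal(reverse_complement(mkd("a", "aRyK"), reverse = FALSE)$seq,
               "tYrM")
  twice <- reverse_complement(reverse_complement(mkd("a", "ACGGTN")))
  expect_equal(twice$seq, "ACGGTN")
  expect_error(reverse_complement(mkd("p", "MKWQEF")),
               class = "ff_processing_error")
})

test_that("translation matches the standard code in all frames", {
  d <- mkd("a", "ATGAAATAA")
  expect_equal(translate_sequences(d)$seq, "MK*")
  expect_equal(translate_sequences(mkd("a", "TT"))$seq, "")
  expect_equal(translate_sequences(mkd("a", "ATGAAAT"), frame = 2)$seq, "*N")
  # exhaustive 64-codon check against Biostrings' genetic code table
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  got <- translate_sequences(mkd(paste0("c", seq_along(codons)), codons))$seq
  want <- unname(Biostrings::GENETIC_CODE[codons])
  expect_equal(got, want)
  # ambiguity: GCN is always Ala, ATN is ambiguous
  expect_equal(translate_sequences(mkd("a", "GCN"))$seq, "A")
  expect_equal(translate_sequences(mkd("a", "ATN"))$seq, "X")
  # reverse strand translation equals translating the reverse complement
  rd <- random_dataset(5, c(30, 90), seed = 4)
  expect_equal(translate_sequences(rd, use_reverse_strand = TRUE)$seq,
               translate_sequences(reverse_complement(rd))$seq)
})

test_that("isoform removal groups by shared header words transitively", {
  d <- dataset(c("HOMX1", "HOMX1.2", "ABC1"),
               c("iso1", "iso2", ""),
               c("AAAAAAAAA", paste(rep("A", 30), collapse = ""), "AAAAAAA"))
  r <- remove_isoforms(d, min_word_length = 5, reference_size = 10)
  expect_equal(r$dataset$id, c("HOMX1", "ABC1"))
  expect_equal(r$removed_count, 1L)
  # word too long to match anything: identity
  r2 <- remove_isoforms(d, min_word_length = 30, reference_size = 10)
  expect_equal(r2$dataset$id, d$id)
  # transitive closure: A~B via word1, B~C via word2 groups all three
  d3 <- dataset(c("g1", "g2", "g3"),
                c("alpha", "alpha beta", "beta"),
                c("AAAA", "AA", "AAAAAA"))
  r3 <- remove_isoforms(d3, min_word_length = 4, reference_size = 4)
  expect_equal(r3$dataset$id, "g1")
  # grouping depends only on headers, not input order of sequences
  perm <- subset_ds <- dataset(d3$id[c(3, 1, 2)], d3$desc[c(3, 1, 2)],
                               d3$seq[c(3, 1, 2)])
  r4 <- remove_isoforms(perm, min_word_length = 4, reference_size = 4)
  expect_equal(r4$dataset$id, "g1")
})

test_that("deduplication keeps first occurrences", {
  d <- mkd(c("a", "b", "c"), c("AC", "AC", "GT"))
  r <- deduplicate(d, "exact-sequence")
  expect_equal(r$dataset$id, c("a", "c"))
  expect_equal(r$removed_count, 1L)
  expect_equal(deduplicate(mkd(c("a", "b"), c("A", "C")))$removed_count, 0L)
  expect_equal(n_records(deduplicate(dataset())$dataset), 0L)
  d2 <- mkd(c("x", "x", "y"), c("A", "C", "G"))
  expect_equal(deduplicate(d2, "id")$dataset$seq, c("A", "G"))
})

test_that("merge and split conserve records exactly", {
  dir <- tempfile(); dir.create(dir)
  d1 <- random_dataset(2, c(5, 20), seed = 1)
  d2 <- random_dataset(3, c(5, 20), seed = 2)
  p1 <- write_fasta(d1, file.path(dir, "one.fasta"))
  p2 <- write_fasta(d2, file.path(dir, "two.fasta"))
  m <- merge_datasets(fastaforge:::new_fileset(c(p1, p2), "explicit-files"))
  expect_equal(n_records(m), 5L)
  expect_equal(m$seq, c(d1$seq, d2$seq))
  out <- tempfile()
  fs <- split_dataset(m, out, per_file = 2)
  sizes <- vapply(fs$paths, function(p) n_records(read_fasta(p)), integer(1))
  expect_equal(unname(sizes), c(2L, 2L, 1L))
  back <- merge_datasets(fs)
  expect_equal(back$seq, m$seq)
  expect_equal(back$id, m$id)
  expect_error(split_dataset(m, out), class = "ff_usage_error")
  fs2 <- split_dataset(m, tempfile(), parts = 2)
  expect_equal(length(fs2$paths), 2L)
})

test_that("filter survivors agree with brute-force recount on random data", {
  for (seed in 1:40) {
    d <- random_dataset(12, c(0, 60), seed = seed)
    lo <- seed %% 20; hi <- lo + 15
    expect_equal(n_records(filter_by_length(d, lo, hi)$dataset),
                 sum(nchar(d$seq) >= lo & nchar(d$seq) <= hi))
    pat <- c("A{3}", "^seq", "G.C", "T+A")[seed %% 4 + 1]
    tgt <- if (seed %% 2) "header" else "sequence"
    x <- if (tgt == "header") ifelse(nzchar(d$desc), paste(d$id, d$desc),
                                     d$id) else d$seq
    expect_equal(n_records(filter_by_pattern(d, pat, tgt)$dataset),
                 sum(grepl(pat, x, perl = TRUE)))
  }
})
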