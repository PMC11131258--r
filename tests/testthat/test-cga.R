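# ORF discovery and the conserved-gene annotation pipeline.

test_that("a constructed stop-free stretch is reported exactly once", {
  set.seed(2)
  # 99 nt without stop codons in frame 1, flanked by TAA stops
  core <- paste(sample(fastaforge:::SENSE_CODONS, 33, replace = TRUE),
                collapse = "")
  region <- paste0("TAA", core, "TAA")
  orfs <- get_orfs(region, min_orf_length = 30)
  plus1 <- orfs[orfs$strand == "+" & orfs$frame == 1, ]
  expect_equal(nrow(plus1), 1L)
  expect_equal(plus1$start, 4L)
  expect_equal(plus1$end, 102L)
  expect_equal(plus1$nuc, core)
})

test_that("the length threshold is strict and ambiguity regions yield nothing", {
  expect_equal(nrow(get_orfs(strrep("N", 20), 30)), 0L)
  # frame-1 ORFs of 27, 30 and 33 nt: only the 33-nt one passes
  mk <- function(ncod) paste(rep("GCT", ncod), collapse = "")
  region <- paste0("TAA", mk(9), "TAA", mk(10), "TAA", mk(11), "TAA")
  orfs <- get_orfs(region, 30)
  plus1 <- orfs[orfs$strand == "+" & orfs$frame == 1, ]
  expect_equal(nrow(plus1), 1L)
  expect_equal(nchar(plus1$nuc), 33L)
})

test_that("ORF coordinates map back to the region residues on both strands", {
  for (seed in 1:10) {
    d <- random_dataset(1, c(400, 800), seed = seed)
    orfs <- get_orfs(d)
    for (k in seq_len(nrow(orfs))) {
      slice <- substr(d$seq[1], orfs$start[k], orfs$end[k])
      if (orfs$strand[k] == "-") slice <- fastaforge:::revcomp_nuc(slice)
      expect_identical(toupper(slice), orfs$nuc[k])
      expect_equal(nchar(orfs$prot[k]), nchar(orfs$nuc[k]) %/% 3L)
    }
  }
})

test_that("get_orfs agrees with the naive six-frame scanner", {
  for (seed in 1:30) {
    len <- 100 + (seed * 61) %% 1900
    d <- random_dataset(1, c(len, len), seed = seed)
    expect_identical(orf_keys_of(get_orfs(d, 30)),
                     brute_force_orf_keys(d$seq[1], 30),
                     info = paste("seed", seed))
  }
})

test_that("raising min_orf_length never increases the ORF count", {
  d <- random_dataset(1, c(1500, 1500), seed = 99)
  counts <- vapply(c(30, 60, 120, 240), function(m)
    nrow(get_orfs(d, m)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("matching finds an ORF identical to the reference first", {
  fx <- make_gene_fixture(1, seed = 3)
  orfs <- get_orfs(fx$region)
  m <- match_orfs_to_reference(orfs, fx$protein)
  expect_gte(nrow(m), 1L)
  best <- m[1, ]
  expect_equal(best$ref_start, 1L)
  expect_equal(best$ref_end, nchar(fx$protein))
  # the matched genomic span reproduces the stored residues
  slice <- substr(fx$region$seq[1], best$start, best$end)
  orf <- orfs[orfs$orf_id == best$orf_id, ]
  expect_identical(translate_sequences(dataset("s", "", slice))$seq,
                   substr(orf$prot,
                          (best$start - orf$start) / 3 + 1,
                          (best$end + 1 - orf$start) / 3))
})

test_that("raising the e-value threshold never decreases the match count", {
  fx <- make_gene_fixture(2, seed = 8)
  orfs <- get_orfs(fx$region)
  counts <- vapply(c(1e-10, 1e-3, 0.05, 10),
                   function(t) nrow(match_orfs_to_reference(orfs, fx$protein,
                                                           e_value_threshold = t)),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
  # zero threshold yields nothing (strict inequality)
  expect_equal(nrow(match_orfs_to_reference(orfs, fx$protein,
                                            e_value_threshold = 0)), 0L)
})

test_that("sorting orders matches by genomic location, stably", {
  m <- data.frame(orf_id = c("c", "a", "b"), strand = "+",
                  start = c(300L, 100L, 200L), end = c(350L, 150L, 250L),
                  ref_start = c(60L, 1L, 30L), ref_end = c(80L, 25L, 55L),
                  e_value = 1e-5, score = 100,
                  stringsAsFactors = FALSE)
  s <- sort_exon_matches(m)
  expect_equal(s$orf_id, c("a", "b", "c"))
  expect_identical(sort_exon_matches(s), s)
  expect_identical(sort_exon_matches(m[2, ]), m[2, ])
  # minus-strand genes sort in reverse genomic order (transcript order)
  m$strand <- "-"
  expect_equal(sort_exon_matches(m)$orf_id, c("c", "b", "a"))
})

test_that("single-exon genes join trivially and multi-exon fixtures are recovered", {
  fx1 <- make_gene_fixture(1, seed = 21)
  m <- sort_exon_matches(match_orfs_to_reference(get_orfs(fx1$region),
                                                 fx1$protein))
  gm <- join_exons(m, fx1$region, fx1$protein)
  expect_equal(gm$status, "joined")
  expect_equal(nrow(gm$exons), 1L)
  expect_equal(sub("\\*$", "", gm$joined_prot), fx1$protein)

  fx3 <- make_gene_fixture(3, seed = 22)
  m3 <- sort_exon_matches(match_orfs_to_reference(get_orfs(fx3$region),
                                                  fx3$protein))
  gm3 <- join_exons(m3, fx3$region, fx3$protein)
  expect_equal(gm3$status, "joined")
  expect_equal(sub("\\*$", "", gm3$joined_prot), fx3$protein)
  expect_true(all(diff(gm3$exons$start) > 0))
  expect_true(all(gm3$exons$end >= gm3$exons$start))
})

test_that("a junction without canonical sites in the window fails with a diagnosis", {
  # two-exon gene whose intron is edited to remove the GT donor, with a
  # window too small to find an alternative
  fx <- make_gene_fixture(2, seed = 30, intron_len_range = c(200, 400))
  region <- fx$region$seq[1]
  i1 <- fx$introns$start[1]
  substr(region, i1, i1 + 1) <- "CC"
  # remove every GT in the first 80 nt of the intron so none is in range
  chunk <- substr(region, i1, i1 + 80)
  chunk <- gsub("GT", "CC", chunk)
  substr(region, i1, i1 + 80) <- chunk
  d <- dataset(fx$region$id, "", region)
  m <- sort_exon_matches(match_orfs_to_reference(get_orfs(d), fx$protein))
  gm <- join_exons(m, d, fx$protein, window = 10)
  expect_equal(gm$status, "failed")
  expect_true(any(grepl("junction", gm$refinement_log)))
})

test_that("prediction recovers the protein and respects min_cds_size", {
  fx <- make_gene_fixture(2, seed = 31)
  m <- sort_exon_matches(match_orfs_to_reference(get_orfs(fx$region),
                                                 fx$protein))
  gm <- join_exons(m, fx$region, fx$protein)
  pred <- predict_cds(gm, fx$protein)
  expect_identical(pred$pep, fx$protein)
  expect_identical(translate_sequences(dataset("x", "", pred$nuc))$seq,
                   fx$protein)
  # oversized threshold: empty outputs
  pred2 <- predict_cds(gm, fx$protein,
                       min_cds_size = nchar(gm$joined_nuc) + 3)
  expect_equal(pred2$nuc, "")
  expect_equal(pred2$pep, "")
})

test_that("run_cga writes the numbered output contract per region", {
  fx <- make_gene_fixture(2, seed = 35)
  junk <- dataset("nohit", "", random_dataset(1, c(300, 300),
                                              seed = 1000)$seq)
  regions <- dataset(c(fx$region$id, "nohit"),
                     c(fx$region$desc, ""),
                     c(fx$region$seq, junk$seq))
  out <- tempfile()
  expect_warning(s <- run_cga(regions, dataset("ref", "", fx$protein), out),
                 "no significant match")
  expect_equal(s$status, c("joined", "no-match"))
  rid <- fx$region$id
  files <- list.files(file.path(out, rid))
  expect_setequal(files, c("01_orfs.nuc.fasta", "01_orfs.prot.fasta",
                           sprintf("02_%s.ini", rid),
                           sprintf("03_%s.ini.sorted", rid),
                           sprintf("04_%s.join_exons_results", rid),
                           sprintf("04_%s.join_exons_results.log", rid),
                           sprintf("05_%s.join_exons_results", rid),
                           sprintf("05_%s.nuc", rid),
                           sprintf("05_%s.pep", rid),
                           sprintf("05_%s.pep.blast", rid)))
  # four 05_-level outputs exactly
  expect_equal(sum(startsWith(files, "05_")), 4L)
  # the no-match region stops at 02_
  files2 <- list.files(file.path(out, "nohit"))
  expect_false(any(startsWith(files2, "05_")))
  expect_equal(s$pep[1], fx$protein)
  # the 02_ table's spans reproduce the stored residues
  tab <- read.delim(file.path(out, rid, sprintf("02_%s.ini", rid)))
  orfs <- get_orfs(fx$region)
  for (k in seq_len(nrow(tab))) {
    orf <- orfs[orfs$orf_id == tab$orf_id[k], ]
    slice <- substr(fx$region$seq[1], tab$start[k], tab$end[k])
    if (tab$strand[k] == "-") slice <- fastaforge:::revcomp_nuc(slice)
    expect_true(grepl(toupper(slice), orf$nuc, fixed = TRUE))
  }
  # minus-strand region: same gene on the reverse complement
  rc <- dataset("minus", "", fastaforge:::revcomp_nuc(fx$region$seq[1]))
  out2 <- tempfile()
  s2 <- run_cga(rc, dataset("ref", "", fx$protein), out2)
  expect_equal(s2$pep, fx$protein)
})

test_that("a multi-record reference is rejected", {
  fx <- make_gene_fixture(1, seed = 40)
  two <- dataset(c("r1", "r2"), "", c(fx$protein, fx$protein))
  expect_error(run_cga(fx$region, two, tempfile()),
               "exactly one", class = "ff_usage_error")
})
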