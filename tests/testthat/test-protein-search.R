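# Smith-Waterman alignment and the E-value search layer.

test_that("identical sequences score the sum of their diagonal values", {
  mat <- blosum62()
  set.seed(7)
  for (k in 1:10) {
    s <- random_protein(10)
    h <- smith_waterman(s, s)
    ch <- strsplit(s, "")[[1]]
    expect_equal(h$raw_score, sum(mat[cbind(ch, ch)]))
    expect_equal(h$identity_fraction, 1)
    expect_equal(h$query_span, c(1L, 10L))
    expect_equal(h$subject_span, c(1L, 10L))
  }
})

test_that("all-mismatch pairs and empty input give score-0 hits", {
  h <- smith_waterman("AAAA", "CCCC", matrix = {
    m <- blosum62(); m[] <- -1; diag(m) <- -1; m
  })
  expect_equal(h$raw_score, 0)
  expect_equal(h$query_span, c(0L, 0L))
  h2 <- smith_waterman("", "MKL")
  expect_equal(h2$raw_score, 0)
})

test_that("scores are symmetric and self-alignment is maximal", {
  set.seed(11)
  for (k in 1:25) {
    a <- random_protein(sample(5:20, 1))
    b <- random_protein(sample(5:20, 1))
    expect_equal(smith_waterman(a, b)$raw_score,
                 smith_waterman(b, a)$raw_score)
    expect_gte(smith_waterman(a, a)$raw_score,
               smith_waterman(a, b)$raw_score)
  }
})

test_that("scores equal the brute-force all-start-pairs oracle", {
  mat <- blosum62()
  set.seed(23)
  for (k in 1:60) {
    a <- random_protein(sample(1:12, 1))
    b <- random_protein(sample(1:12, 1))
    expect_equal(smith_waterman(a, b)$raw_score,
                 brute_force_local_score(a, b, mat),
                 info = paste(a, b))
  }
})

test_that("scores agree with an independent local-alignment implementation", {
  set.seed(31)
  for (k in 1:120) {
    a <- random_protein(sample(2:20, 1))
    b <- random_protein(sample(2:20, 1))
    ours <- smith_waterman(a, b)$raw_score
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(ours, max(0, ref), info = paste(a, b))
  }
})

test_that("search ranks by E-value, applies the strict threshold and scales with database size", {
  set.seed(5)
  ref <- random_protein(60)
  db <- dataset(c("self", "junk1", "junk2"), "",
                c(ref, random_protein(50), random_protein(40)))
  hits <- search_protein(ref, db, e_value_threshold = 0.05)
  expect_equal(hits[[1]]$subject_id, "self")
  ev <- vapply(hits, `[[`, numeric(1), "e_value")
  expect_true(all(diff(ev) >= 0))
  expect_true(all(ev < 0.05))
  # threshold 0 is strict: nothing passes
  expect_equal(length(search_protein(ref, db, e_value_threshold = 0)), 0L)
  # doubling total database length doubles every E-value at fixed score
  db2 <- dataset(c(db$id, paste0(db$id, "_copy")), "", c(db$seq, db$seq))
  hits2 <- search_protein(ref, db2, e_value_threshold = 0.05)
  e1 <- hits[[1]]$e_value
  e2 <- hits2[[1]]$e_value
  expect_equal(e2 / e1, 2, tolerance = 1e-9)
  # filtering at a threshold equals brute-force filtering of the full list
  all_hits <- search_protein(ref, db, e_value_threshold = Inf)
  thr <- 1e-3
  expect_equal(length(search_protein(ref, db, e_value_threshold = thr)),
               sum(vapply(all_hits, `[[`, numeric(1), "e_value") < thr))
})

test_that("E-value decreases monotonically in score and the table is outfmt6-shaped", {
  s <- seq(20, 200, by = 20)
  e <- fastaforge:::KA_K * 100 * 1000 * exp(-fastaforge:::KA_LAMBDA * s)
  expect_true(all(diff(e) < 0))
  hits <- search_protein("MKWVLLLA", dataset("a", "", "MKWVLLLA"),
                         e_value_threshold = Inf)
  tab <- hits_table(hits)
  expect_equal(names(tab),
               c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore"))
  expect_equal(tab$pident[1], 100)
})
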