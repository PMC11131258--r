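# FASTA data model, readers/writers, input resolution, output grouping and
# the in-memory / on-disk processing contract.

test_that("literal FASTA text parses to the expected records", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 desc", "ACGT", "ACGT", ">s2", "TTT"), p)
  d <- read_fasta(p)
  expect_equal(n_records(d), 2L)
  expect_equal(d$id, c("s1", "s2"))
  expect_equal(d$desc, c("desc", ""))
  expect_equal(d$seq, c("ACGTACGT", "TTT"))
})

test_that("empty files, CRLF endings and blank lines are tolerated", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), p)
  expect_equal(n_records(read_fasta(p)), 0L)
  writeBin(charToRaw("\r\n>a x\r\nAC\r\nGT\r\n\r\n>b\r\nT\r\n"), p)
  d <- read_fasta(p)
  expect_equal(d$seq, c("ACGT", "T"))
  expect_equal(d$desc[1], "x")
})

test_that("non-FASTA leading content is rejected naming the line", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("garbage", ">a", "AC"), p)
  expect_error(read_fasta(p), "line 1", class = "ff_format_error")
})

test_that("wrapping arithmetic: 10 residues at width 4 gives lines 4,4,2", {
  d <- dataset("x", "", "ACGTACGTAC")
  p <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(d, p, line_width = 4)
  expect_equal(readLines(p), c(">x", "ACGT", "ACGT", "AC"))
})

test_that("gzip round-trips byte-identically and is detected by magic bytes", {
  d <- random_dataset(4, c(10, 200), seed = 42)
  plain <- withr::local_tempfile(fileext = ".fasta")
  gz <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(d, plain, line_width = 60)
  gzpath <- write_fasta(d, gz, gzip = TRUE, line_width = 60)
  expect_match(gzpath, "\\.gz$")
  # decompressed bytes equal the plain write
  con <- gzfile(gzpath, "rb")
  bytes <- readBin(con, "raw", 1e6)
  close(con)
  expect_identical(bytes, read_all_bytes(plain))
  d2 <- read_fasta(gzpath)
  expect_identical(d2$seq, d$seq)
})

test_that("round-trip preserves ids, descriptions, residues and order", {
  for (seed in 1:20) {
    alph <- if (seed %% 2) "nucleotide" else "protein"
    d <- random_dataset(seed %% 7, c(0, 300), alphabet = alph, seed = seed)
    for (lw in list(1, 60, Inf)) {
      p <- withr::local_tempfile(fileext = ".fasta")
      write_fasta(d, p, line_width = lw, gzip = seed %% 3 == 0)
      d2 <- read_fasta(if (seed %% 3 == 0) paste0(p, ".gz") else p)
      expect_identical(d2$id, d$id)
      expect_identical(d2$desc, d$desc)
      expect_identical(d2$seq, d$seq)
    }
  }
})

test_that("the observed wrapping dialect is reused on write", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTA", "CGTAC", "GT"), p)
  d <- read_fasta(p)
  expect_equal(d$line_width, 5)
  p2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(d, p2)
  expect_equal(readLines(p2), c(">a", "ACGTA", "CGTAC", "GT"))
})

test_that("resolve_inputs enforces exclusivity and resolves each source", {
  dir <- withr::local_tempdir()
  for (f in c("b.fasta", "a.fasta", "notes.txt"))
    writeLines(">x\nA", file.path(dir, f))
  fs <- resolve_inputs(input_directory = dir)
  expect_equal(basename(fs$paths), c("a.fasta", "b.fasta"))
  expect_equal(fs$origin, "directory")

  lst <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a.fasta", "", "# comment", "b.fasta"), lst)
  file.copy(file.path(dir, c("a.fasta", "b.fasta")), dirname(lst))
  fs2 <- resolve_inputs(input_list = lst)
  expect_equal(length(fs2$paths), 2L)

  expect_error(resolve_inputs(input_directory = dir, input_list = lst),
               class = "ff_usage_error")
  expect_error(resolve_inputs(), class = "ff_usage_error")

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("no/such/file.fasta", bad)
  expect_error(resolve_inputs(input_list = bad), "no/such/file.fasta",
               class = "ff_input_error")
})

test_that("output grouping: sizes, conservation and the zero default", {
  mk <- function(n) {
    out <- tempfile("grp")
    dir.create(out)
    for (k in seq_len(n)) writeLines("x", file.path(out, sprintf("f%02d", k)))
    out
  }
  out <- mk(5)
  group_outputs(list.files(out, full.names = TRUE), out, 0)
  expect_equal(length(list.dirs(out, recursive = FALSE)), 0L)

  out <- mk(5)
  group_outputs(sort(list.files(out, full.names = TRUE)), out, 2)
  dirs <- list.dirs(out, recursive = FALSE)
  expect_equal(basename(dirs), c("group_1", "group_2", "group_3"))
  sizes <- vapply(dirs, function(d) length(list.files(d)), integer(1))
  expect_equal(unname(sizes), c(2L, 2L, 1L))
  all_files <- list.files(out, recursive = TRUE)
  expect_equal(length(all_files), 5L)
  expect_equal(anyDuplicated(basename(all_files)), 0L)

  expect_error(group_outputs(character(), tempdir(), -1),
               class = "ff_usage_error")
})

test_that("in-memory and on-disk modes agree and failures are isolated", {
  dir <- withr::local_tempdir()
  for (k in 1:3)
    write_fasta(random_dataset(5, c(5, 80), seed = k),
                file.path(dir, sprintf("f%d.fasta", k)))
  fs <- resolve_inputs(input_directory = dir)
  op <- function(d) sort_sequences(d, "length")
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  r1 <- process_fileset(fs, op, out1, mode = "in-memory")
  peak_mem <- last_peak_records()
  r2 <- process_fileset(fs, op, out2, mode = "on-disk")
  peak_disk <- last_peak_records()
  expect_identical(tree_bytes(out1), tree_bytes(out2))
  expect_equal(peak_mem, 15L)   # all files resident
  expect_equal(peak_disk, 5L)   # one file at a time
  # corrupt one file: others still processed, error recorded
  writeLines("not fasta at all", file.path(dir, "f2.fasta"))
  out3 <- withr::local_tempdir()
  r3 <- process_fileset(resolve_inputs(input_directory = dir), op, out3)
  expect_equal(length(r3$errors), 1L)
  expect_equal(length(r3$fileset$paths), 2L)
})
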