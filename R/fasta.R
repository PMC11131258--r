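# FASTA data model and readers/writers.
#
# A dataset is an ordered collection of sequence records from one file:
# parallel character vectors for id (first whitespace-delimited word of the
# header), description (remainder, possibly empty) and residues. Residue case
# is preserved; duplicate ids are permitted. The line-wrapping dialect
# observed at read time travels with the dataset so writes can reproduce it.

NUC_CODES <- "ACGTURYSWKMBDHVN"
PROT_CODES <- "ACDEFGHIKLMNPQRSTVWYBZJXUO*"

#' Construct a sequence dataset
#'
#' @param id character vector of record identifiers (no whitespace).
#' @param desc character vector of descriptions (may be empty strings).
#' @param seq character vector of residues.
#' @param source optional path the dataset was read from.
#' @param line_width wrapping dialect: a positive integer, `Inf` for
#'   unwrapped (one line per record), or `NA` when unknown/mixed.
#' @return an object of class `fasta_dataset`.
#' @export
dataset <- function(id = character(), desc = character(length(id)),
                    seq = character(length(id)), source = NULL,
                    line_width = NA_real_) {
  id <- as.character(id); desc <- as.character(desc); seq <- as.character(seq)
  if (length(desc) == 1L && length(id) > 1L) desc <- rep(desc, length(id))
  if (length(desc) != length(id) || length(seq) != length(id))
    usage_error("id, desc and seq must have equal length")
  if (any(!nzchar(id)) || any(grepl("[[:space:]]", id)))
    format_error("record ids must be non-empty and contain no whitespace")
  if (any(grepl("[[:space:]>]", seq)))
    format_error("residues must contain no whitespace or '>' characters")
  structure(list(id = id, desc = desc, seq = seq, source = source,
                 line_width = line_width),
            class = "fasta_dataset")
}

#' Number of records in a dataset
#' @param x a `fasta_dataset`.
#' @return integer count.
#' @export
n_records <- function(x) length(x$id)

#' @export
print.fasta_dataset <- function(x, ...) {
  cat(sprintf("<fasta_dataset> %d record(s)", n_records(x)))
  if (!is.null(x$source)) cat(" from ", x$source, sep = "")
  cat("\n")
  k <- min(n_records(x), 6L)
  if (k > 0) {
    hdr <- ifelse(nzchar(x$desc[seq_len(k)]),
                  paste(x$id[seq_len(k)], x$desc[seq_len(k)]), x$id[seq_len(k)])
    cat(sprintf("  >%s [%d residues]\n", hdr, nchar(x$seq[seq_len(k)])),
        sep = "")
  }
  if (n_records(x) > k) cat("  ...\n")
  invisible(x)
}

# Subset records by index, keeping metadata.
subset_dataset <- function(d, idx) {
  dataset(d$id[idx], d$desc[idx], d$seq[idx], source = d$source,
          line_width = d$line_width)
}

datasets_equal <- function(a, b) {
  identical(a$id, b$id) && identical(a$desc, b$desc) && identical(a$seq, b$seq)
}

#' Guess the alphabet of residues
#'
#' Sequences using only IUPAC nucleotide codes (including ambiguity codes
#' and gaps) are called `nucleotide`; otherwise sequences using amino-acid
#' codes are `protein`; anything else is `unknown`. Note the nucleotide
#' codes are a subset of the protein codes, so short protein sequences made
#' only of A/C/G/T-like letters are (deliberately) called nucleotide.
#'
#' @param seq character vector of residues.
#' @return character vector over `c("nucleotide", "protein", "unknown")`.
#' @export
guess_alphabet <- function(seq) {
  up <- toupper(seq)
  nuc <- !grepl(sprintf("[^%s.-]", NUC_CODES), up)
  prot <- !grepl(sprintf("[^%s.-]", gsub("([*])", "\\\\\\1", PROT_CODES)), up)
  out <- ifelse(nuc, "nucleotide", ifelse(prot, "protein", "unknown"))
  out[!nzchar(seq)] <- "unknown"
  out
}

# gzip magic bytes 1f 8b
is_gzip_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

#' Read a FASTA file
#'
#' Tolerant reader: accepts LF and CRLF line endings, leading/trailing and
#' interior blank lines, and gzip-compressed input (detected by magic bytes,
#' not file extension, when `gzip_auto`). Rejects non-FASTA text before the
#' first header and residue lines containing whitespace.
#'
#' @param path path to a FASTA file, plain or gzip-compressed.
#' @param gzip_auto detect gzip compression from the file's magic bytes.
#' @return a [dataset()] with the observed line-wrapping dialect recorded.
#' @export
read_fasta <- function(path, gzip_auto = TRUE) {
  if (!file.exists(path)) input_error(sprintf("cannot read '%s': no such file", path))
  con <- if (gzip_auto && is_gzip_file(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- sub("\r$", "", lines)
  parse_fasta_lines(lines, path)
}

parse_fasta_lines <- function(lines, path = "<text>") {
  blank <- !nzchar(trimws(lines))
  keep <- which(!blank)
  if (length(keep) == 0L)
    return(dataset(source = path, line_width = NA_real_))
  lines <- lines[keep]
  orig_line_no <- keep
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1])
    format_error(sprintf("'%s': non-FASTA content before first header at line %d: %s",
                         path, orig_line_no[1], lines[1]))
  bad <- which(!is_hdr & grepl("[[:space:]]", lines))
  if (length(bad))
    format_error(sprintf("'%s': residue line %d contains whitespace",
                         path, orig_line_no[bad[1]]))
  rec_of <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  headers <- trimws(headers)
  id <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 trimws(sub("^[^[:space:]]+[[:space:]]+", "", headers)), "")
  if (any(!nzchar(id)))
    format_error(sprintf("'%s': empty header (record %d)", path, which(!nzchar(id))[1]))
  body <- split(lines[!is_hdr], factor(rec_of[!is_hdr], levels = seq_along(headers)))
  seqs <- vapply(body, function(x) paste(x, collapse = ""), character(1))
  # observe wrapping dialect: width shared by all non-terminal body lines
  widths <- unlist(lapply(body, function(x) {
    if (length(x) > 1L) nchar(x[-length(x)]) else integer()
  }), use.names = FALSE)
  line_width <- if (length(widths) == 0L) {
    Inf  # every record on one line (or empty)
  } else if (length(unique(widths)) == 1L) {
    as.numeric(widths[1])
  } else NA_real_
  dataset(id, desc, unname(seqs), source = path, line_width = line_width)
}

#' Write a dataset to a FASTA file
#'
#' @param d a [dataset()].
#' @param path destination path. When `gzip` is set and `path` lacks a
#'   `.gz` extension, `.gz` is appended.
#' @param gzip write a gzip-compressed stream.
#' @param line_width wrapping width; `NULL` uses the dataset's observed
#'   dialect, falling back to 80; `Inf` writes each sequence on one line.
#' @return the path actually written (invisibly).
#' @export
write_fasta <- function(d, path, gzip = FALSE, line_width = NULL) {
  stopifnot(inherits(d, "fasta_dataset"))
  lw <- line_width %||% d$line_width
  if (is.na(lw)) lw <- 80
  if (!is.infinite(lw) && (lw < 1 || lw != as.integer(lw)))
    usage_error("line_width must be a positive integer or Inf")
  if (gzip && !grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lines <- fasta_lines(d, lw)
  con <- tryCatch(if (gzip) gzfile(path, "wb") else file(path, "wb"),
                  error = function(e) input_error(sprintf("cannot write '%s'", path)))
  on.exit(close(con))
  # writes LF endings regardless of platform (strict-write dialect)
  if (length(lines)) writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  invisible(path)
}

fasta_lines <- function(d, lw) {
  n <- n_records(d)
  if (n == 0L) return(character())
  hdr <- ifelse(nzchar(d$desc), paste0(">", d$id, " ", d$desc), paste0(">", d$id))
  out <- vector("list", 2L * n)
  for (k in seq_len(n)) {
    out[[2L * k - 1L]] <- hdr[k]
    s <- d$seq[k]
    if (!nzchar(s)) {
      out[[2L * k]] <- character()
    } else if (is.infinite(lw) || nchar(s) <= lw) {
      out[[2L * k]] <- s
    } else {
      starts <- seq(1L, nchar(s), by = lw)
      out[[2L * k]] <- substring(s, starts, pmin(starts + lw - 1L, nchar(s)))
    }
  }
  unlist(out, use.names = FALSE)
}
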