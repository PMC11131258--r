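# The core filtering / sorting / editing operation family, plus the
# transforms the annotation pipeline needs (translation, reverse-complement,
# deduplication, isoform removal, merge/split). All operations preserve
# input order unless sorting is the point, and report removed-record counts.

op_result <- function(dataset, removed_count = 0L, notes = character()) {
  structure(list(dataset = dataset, removed_count = as.integer(removed_count),
                 notes = notes),
            class = "op_result")
}

#' @export
print.op_result <- function(x, ...) {
  cat(sprintf("<op_result> %d record(s) kept, %d removed\n",
              n_records(x$dataset), x$removed_count))
  invisible(x)
}

keep_result <- function(d, keep_idx, notes = character()) {
  op_result(subset_dataset(d, keep_idx), n_records(d) - sum(keep_idx), notes)
}

#' Filter records by sequence length
#'
#' Bounds are inclusive; `keep = "inside"` retains records whose length is
#' within `[min_len, max_len]`, `keep = "outside"` retains the complement.
#' At least one bound must be given.
#'
#' @param d a [dataset()].
#' @param min_len,max_len inclusive bounds (either may be omitted).
#' @param keep `"inside"` or `"outside"`.
#' @return an `op_result`.
#' @export
filter_by_length <- function(d, min_len = NULL, max_len = NULL,
                             keep = c("inside", "outside")) {
  keep <- match.arg(keep)
  if (is.null(min_len) && is.null(max_len))
    usage_error("filter-by-length needs --min-length and/or --max-length")
  lo <- min_len %||% 0
  hi <- max_len %||% Inf
  if (lo > hi) usage_error("--min-length must not exceed --max-length")
  len <- nchar(d$seq)
  inside <- len >= lo & len <= hi
  keep_result(d, if (keep == "inside") inside else !inside)
}

#' Filter records by a regular expression
#'
#' The header target matches against `"id description"` (just the id when
#' the description is empty); the sequence target matches the residues.
#' Perl-compatible regular expression syntax.
#'
#' @param d a [dataset()].
#' @param pattern regular expression.
#' @param target `"header"` or `"sequence"`.
#' @param case_sensitive match case-sensitively (default) or not.
#' @param keep `"match"` or `"no-match"`.
#' @return an `op_result`.
#' @export
filter_by_pattern <- function(d, pattern, target = c("header", "sequence"),
                              case_sensitive = TRUE,
                              keep = c("match", "no-match")) {
  target <- match.arg(target); keep <- match.arg(keep)
  x <- if (target == "header") header_string(d) else d$seq
  hit <- tryCatch(suppressWarnings(grepl(pattern, x, perl = TRUE,
                                         ignore.case = !case_sensitive)),
                  error = function(e)
                    usage_error(sprintf("invalid pattern '%s': %s", pattern,
                                        conditionMessage(e))))
  keep_result(d, if (keep == "match") hit else !hit)
}

header_string <- function(d) ifelse(nzchar(d$desc), paste(d$id, d$desc), d$id)

#' Sort records
#'
#' Stable sort (ties keep input order) by length, full header
#' (lexicographic, C locale) or residues.
#'
#' @param d a [dataset()].
#' @param by `"length"`, `"header"` or `"sequence"`.
#' @param descending reverse the order.
#' @return a [dataset()].
#' @export
sort_sequences <- function(d, by = c("length", "header", "sequence"),
                           descending = FALSE) {
  by <- match.arg(by)
  key <- switch(by, length = nchar(d$seq), header = header_string(d),
                sequence = d$seq)
  ord <- order(key, decreasing = descending, method = "radix")
  subset_dataset(d, ord)
}

#' Edit record headers
#'
#' Modes: `add-prefix` / `add-suffix` attach `text` to the id with
#' `separator`; `replace` substitutes every occurrence of `find` with
#' `text` throughout the header (id and description); `number` appends a
#' 1-based ordinal to the id with `separator`. Residues are untouched.
#'
#' @param d a [dataset()].
#' @param mode one of `add-prefix`, `add-suffix`, `replace`, `number`.
#' @param text replacement / affix text.
#' @param find substring to replace (mode `replace`).
#' @param separator affix separator (default `"_"`).
#' @return a [dataset()].
#' @export
edit_headers <- function(d, mode = c("add-prefix", "add-suffix", "replace",
                                     "number"),
                         text = NULL, find = NULL, separator = "_") {
  mode <- match.arg(mode)
  id <- d$id; desc <- d$desc
  if (mode %in% c("add-prefix", "add-suffix") && is.null(text))
    usage_error(sprintf("mode %s requires --text", mode))
  switch(mode,
    "add-prefix" = id <- paste0(text, separator, id),
    "add-suffix" = id <- paste0(id, separator, text),
    "number" = id <- paste0(id, separator, seq_along(id)),
    "replace" = {
      if (is.null(find)) usage_error("mode replace requires --find")
      hdr <- gsub(find, text %||% "", header_string(d), fixed = TRUE)
      hdr <- trimws(hdr)
      if (any(!nzchar(hdr)))
        processing_error("header replacement produced an empty header")
      id <- sub("[[:space:]].*$", "", hdr)
      desc <- ifelse(grepl("[[:space:]]", hdr),
                     trimws(sub("^[^[:space:]]+[[:space:]]+", "", hdr)), "")
    })
  dataset(id, desc, d$seq, source = d$source, line_width = d$line_width)
}

#' Reverse and/or complement nucleotide records
#'
#' IUPAC ambiguity codes are complemented by the IUPAC pairing table and
#' case is preserved. Applying both flags twice is the identity.
#'
#' @param d a [dataset()] of nucleotide records.
#' @param reverse,complement which transforms to apply (both by default).
#' @return a [dataset()].
#' @export
reverse_complement <- function(d, reverse = TRUE, complement = TRUE) {
  bad <- guess_alphabet(d$seq) == "protein"
  if (any(bad))
    processing_error(sprintf("record '%s' is not a nucleotide sequence", d$id[bad][1]))
  dataset(d$id, d$desc, revcomp_nuc(d$seq, reverse, complement),
          source = d$source, line_width = d$line_width)
}

#' Translate nucleotide records to protein
#'
#' Standard genetic code; frame `f` skips `f - 1` leading bases; the
#' trailing partial codon is dropped; stops are written `*` and codons that
#' are ambiguous at the amino-acid level are written `X` (transeq
#' conventions).
#'
#' @param d a [dataset()] of nucleotide records.
#' @param frame reading frame 1, 2 or 3.
#' @param use_reverse_strand translate the reverse complement.
#' @return a [dataset()] of protein records.
#' @export
translate_sequences <- function(d, frame = 1, use_reverse_strand = FALSE) {
  if (!frame %in% 1:3) usage_error("--frame must be 1, 2 or 3")
  bad <- guess_alphabet(d$seq) == "protein"
  if (any(bad))
    processing_error(sprintf("record '%s' is not a nucleotide sequence", d$id[bad][1]))
  s <- if (use_reverse_strand) revcomp_nuc(d$seq) else d$seq
  dataset(d$id, d$desc, translate_nuc(s, frame = frame), source = d$source,
          line_width = d$line_width)
}

#' Remove isoforms, keeping one representative per header-word group
#'
#' Records are grouped when their headers share at least one common word of
#' at least `min_word_length` characters (a word is a maximal alphanumeric
#' run; grouping is by transitive closure). Within each group the record
#' whose length is closest to `reference_size` is kept, earliest record
#' winning ties. Survivors keep input order.
#'
#' @param d a [dataset()].
#' @param min_word_length minimum shared-word length.
#' @param reference_size target sequence length for the kept record.
#' @return an `op_result`; removed isoforms are named in `notes`.
#' @export
remove_isoforms <- function(d, min_word_length = 5, reference_size = 0) {
  n <- n_records(d)
  if (n == 0L) return(op_result(d))
  words <- lapply(regmatches(header_string(d), gregexpr("[A-Za-z0-9]+",
                                                        header_string(d))),
                  function(w) unique(w[nchar(w) >= min_word_length]))
  # union-find over records sharing a word
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  by_word <- split(rep(seq_len(n), lengths(words)), unlist(words))
  for (idx in by_word) {
    if (length(idx) > 1L) {
      r <- find(idx[1])
      for (j in idx[-1]) { rj <- find(j); if (rj != r) parent[rj] <- r }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  notes <- character()
  for (g in split(seq_len(n), root)) {
    dist <- abs(nchar(d$seq[g]) - reference_size)
    win <- g[which.min(dist)]  # earliest on ties
    keep[win] <- TRUE
    if (length(g) > 1L)
      notes <- c(notes, sprintf("kept %s; removed %s", d$id[win],
                                paste(d$id[setdiff(g, win)], collapse = ", ")))
  }
  keep_result(d, keep, notes)
}

#' Remove duplicate records
#'
#' First occurrence kept; duplicates identified by exact residue string or
#' by id.
#'
#' @param d a [dataset()].
#' @param by `"exact-sequence"` or `"id"`.
#' @return an `op_result`.
#' @export
deduplicate <- function(d, by = c("exact-sequence", "id")) {
  by <- match.arg(by)
  key <- if (by == "exact-sequence") d$seq else d$id
  keep_result(d, !duplicated(key))
}

#' Merge the files of a file set into one dataset
#'
#' @param x a `file_set` (files are read in order) or a list of datasets.
#' @return a [dataset()] with records concatenated in input order.
#' @export
merge_datasets <- function(x) {
  ds <- if (inherits(x, "file_set")) lapply(x$paths, read_fasta) else x
  dataset(unlist(lapply(ds, `[[`, "id")) %||% character(),
          unlist(lapply(ds, `[[`, "desc")) %||% character(),
          unlist(lapply(ds, `[[`, "seq")) %||% character())
}

#' Split a dataset into several files
#'
#' Contiguous partition: either `per_file` records per output (last file
#' possibly smaller) or `parts` files of near-equal size (earlier files one
#' record larger when sizes differ).
#'
#' @param d a [dataset()].
#' @param output_dir destination directory.
#' @param per_file records per file (exclusive with `parts`).
#' @param parts number of files (exclusive with `per_file`).
#' @param prefix output basename prefix; files are `<prefix>_<k>.fasta`.
#' @param gzip,line_width forwarded to [write_fasta()].
#' @return a `file_set` of the written files.
#' @export
split_dataset <- function(d, output_dir, per_file = NULL, parts = NULL,
                          prefix = "part", gzip = FALSE, line_width = NULL) {
  if (is.null(per_file) == is.null(parts))
    usage_error("give exactly one of --per-file or --parts")
  n <- n_records(d)
  sizes <- if (!is.null(per_file)) {
    if (per_file < 1) usage_error("--per-file must be positive")
    if (n == 0L) integer() else {
      full <- n %/% per_file
      c(rep(per_file, full), if (n %% per_file) n %% per_file)
    }
  } else {
    if (parts < 1) usage_error("--parts must be positive")
    base <- n %/% parts
    rep(base, parts) + c(rep(1L, n %% parts), rep(0L, parts - n %% parts))
  }
  sizes <- sizes[sizes > 0]
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  paths <- character(length(sizes))
  for (k in seq_along(sizes)) {
    chunk <- subset_dataset(d, seq(starts[k], ends[k]))
    paths[k] <- write_fasta(chunk,
                            file.path(output_dir, sprintf("%s_%d.fasta", prefix, k)),
                            gzip = gzip, line_width = line_width)
  }
  new_fileset(paths, "explicit-files")
}
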