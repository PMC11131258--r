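# Open reading frame discovery: maximal stop-to-stop stretches in all six
# frames (getorf default semantics: stretches are also bounded by the
# sequence ends), kept when strictly longer than `min_orf_length`
# nucleotides. Coordinates are reported in forward-strand 1-based inclusive
# numbering regardless of strand.

#' Find open reading frames in a nucleotide region
#'
#' @param region a single-record [dataset()] (or a residue string) of
#'   nucleotides.
#' @param min_orf_length keep ORFs strictly longer than this many
#'   nucleotides (default 30).
#' @param region_id id used for naming when `region` is a bare string.
#' @return a data frame with one row per ORF: `orf_id`, `region_id`,
#'   `strand` (`+`/`-`), `frame` (1-3 on the reported strand), `start`,
#'   `end` (forward-strand coordinates, `start <= end`), `nuc` and `prot`
#'   residues. Ordered by strand, frame, start.
#' @export
get_orfs <- function(region, min_orf_length = 30, region_id = "region") {
  if (inherits(region, "fasta_dataset")) {
    stopifnot(n_records(region) == 1L)
    region_id <- region$id[1]
    region <- region$seq[1]
  }
  L <- nchar(region)
  rows <- list()
  for (strand in c("+", "-")) {
    work <- if (strand == "+") toupper(region) else toupper(revcomp_nuc(region))
    for (frame in 1:3) {
      ncod <- (L - frame + 1L) %/% 3L
      if (ncod < 1L) next
      starts <- seq(frame, by = 3L, length.out = ncod)
      codons <- substring(work, starts, starts + 2L)
      is_stop <- codons %in% STOP_CODONS
      r <- rle(!is_stop)
      ends_idx <- cumsum(r$lengths)
      starts_idx <- ends_idx - r$lengths + 1L
      for (k in which(r$values)) {
        i0 <- starts_idx[k]; i1 <- ends_idx[k]
        nlen <- 3L * (i1 - i0 + 1L)
        if (nlen <= min_orf_length) next
        w_start <- starts[i0]; w_end <- starts[i1] + 2L
        nuc <- substr(work, w_start, w_end)
        if (strand == "+") {
          g_start <- w_start; g_end <- w_end
        } else {
          g_start <- L - w_end + 1L; g_end <- L - w_start + 1L
        }
        rows[[length(rows) + 1L]] <-
          data.frame(region_id = region_id, strand = strand, frame = frame,
                     start = g_start, end = g_end, nuc = nuc,
                     prot = translate_nuc(nuc), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(region_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      nuc = character(), prot = character(),
                      stringsAsFactors = FALSE)
    out$orf_id <- character()
    return(out[c("orf_id", names(out)[-8])])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$strand, out$frame, out$start), , drop = FALSE]
  out$orf_id <- sprintf("%s_orf%d", out$region_id, seq_len(nrow(out)))
  rownames(out) <- NULL
  out[c("orf_id", "region_id", "strand", "frame", "start", "end", "nuc", "prot")]
}

orfs_to_datasets <- function(orfs) {
  desc <- sprintf("strand=%s frame=%d start=%d end=%d", orfs$strand,
                  orfs$frame, orfs$start, orfs$end)
  list(nuc = dataset(orfs$orf_id, desc, orfs$nuc),
       prot = dataset(orfs$orf_id, desc, orfs$prot))
}
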