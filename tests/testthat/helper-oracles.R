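# Independent oracles used across the suite. Each is written as plainly as
# possible (naive loops, no shared code with the implementation) so that
# agreement is meaningful.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) paste(sample(AA_LETTERS, len, replace = TRUE),
                                      collapse = "")

# Brute-force local alignment with affine gaps: enumerate every start pair
# and run a forward DP over the suffixes, taking the best cell anywhere.
# Gap of length L costs open + L * extend (same convention as the package).
brute_force_local_score <- function(q, s, mat, open = 11, extend = 1) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  if (m == 0 || n == 0) return(0)
  best <- 0
  for (i0 in seq_len(m)) {
    for (j0 in seq_len(n)) {
      mm <- m - i0 + 1L; nn <- n - j0 + 1L
      H <- matrix(-Inf, mm + 1L, nn + 1L)
      E <- matrix(-Inf, mm + 1L, nn + 1L)
      F <- matrix(-Inf, mm + 1L, nn + 1L)
      H[1, 1] <- 0
      for (i in seq_len(mm + 1L)) {
        for (j in seq_len(nn + 1L)) {
          if (i == 1 && j == 1) next
          if (j > 1) E[i, j] <- max(H[i, j - 1] - open - extend,
                                    E[i, j - 1] - extend)
          if (i > 1) F[i, j] <- max(H[i - 1, j] - open - extend,
                                    F[i - 1, j] - extend)
          d <- if (i > 1 && j > 1)
            H[i - 1, j - 1] + mat[qc[i0 + i - 2L], sc[j0 + j - 2L]] else -Inf
          H[i, j] <- max(d, E[i, j], F[i, j])
          if (H[i, j] > best) best <- H[i, j]
        }
      }
    }
  }
  best
}

# Naive six-frame stop-to-stop ORF scanner (codon-by-codon loop); returns
# sorted "strand:frame:start:end" keys for comparison with get_orfs().
brute_force_orf_keys <- function(seq, min_len) {
  stops <- c("TAA", "TAG", "TGA")
  rc <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ch <- rev(strsplit(toupper(x), "")[[1]])
    paste(ifelse(ch %in% names(comp), comp[ch], ch), collapse = "")
  }
  L <- nchar(seq)
  keys <- character()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") toupper(seq) else rc(seq)
    for (frame in 1:3) {
      run_start <- NA_integer_
      pos <- frame
      while (pos + 2L <= L) {
        codon <- substr(w, pos, pos + 2L)
        if (codon %in% stops) {
          if (!is.na(run_start)) {
            keys <- c(keys, orf_key(strand, frame, run_start, pos - 1L, L,
                                    min_len))
            run_start <- NA_integer_
          }
        } else if (is.na(run_start)) run_start <- pos
        pos <- pos + 3L
      }
      if (!is.na(run_start))
        keys <- c(keys, orf_key(strand, frame, run_start, pos - 1L, L, min_len))
    }
  }
  sort(keys[nzchar(keys)])
}

orf_key <- function(strand, frame, w_start, w_end, L, min_len) {
  if (w_end - w_start + 1L <= min_len) return("")
  if (strand == "+") sprintf("%s:%d:%d:%d", strand, frame, w_start, w_end)
  else sprintf("%s:%d:%d:%d", strand, frame, L - w_end + 1L, L - w_start + 1L)
}

orf_keys_of <- function(orfs) {
  sort(sprintf("%s:%d:%d:%d", orfs$strand, orfs$frame, orfs$start, orfs$end))
}

read_all_bytes <- function(path) readBin(path, "raw", file.info(path)$size)

tree_bytes <- function(dir, exclude = "^logs/") {
  files <- list.files(dir, recursive = TRUE, full.names = FALSE)
  files <- files[!grepl(exclude, files)]
  out <- lapply(file.path(dir, files), read_all_bytes)
  names(out) <- files
  out[order(names(out))]
}
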