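# Conserved-gene annotation: ORF discovery -> protein search against a
# reference -> exon sorting -> iterative exon joining across canonical
# GT-AG splice junctions -> CDS prediction. Each input genomic region is
# processed independently; per-region outputs follow the numbered naming
# scheme 01_ (ORFs), 02_ (significant matches), 03_ (sorted matches),
# 04_ (joined sequence) and 05_ (final prediction + self-check search).

MATCH_COLS <- c("orf_id", "strand", "start", "end", "ref_start", "ref_end",
                "e_value", "score")

empty_matches <- function() {
  out <- data.frame(orf_id = character(), strand = character(),
                    start = integer(), end = integer(),
                    ref_start = integer(), ref_end = integer(),
                    e_value = numeric(), score = numeric(),
                    stringsAsFactors = FALSE)
  out
}

#' Match ORFs against a reference protein
#'
#' Runs the Smith-Waterman search with the reference protein as query and
#' the ORF translations as database, keeps significant hits
#' (`e_value < e_value_threshold`), and maps each aligned subject span back
#' to genomic coordinates. An alignment whose traceback contains a
#' subject-side insertion of at least `split_gap` residues is split into
#' separate exon candidates at the insertion: such alignments arise when a
#' short intron with length divisible by three and no in-frame stop lets a
#' single ORF run through two exons.
#'
#' @param orfs ORF table from [get_orfs()].
#' @param reference single protein residue string or single-record
#'   [dataset()].
#' @param e_value_threshold significance threshold (default 0.05).
#' @param split_gap minimum subject-insertion length (residues) that
#'   splits a match.
#' @param matrix,gap_open,gap_extend alignment scoring.
#' @return a data frame of exon matches with columns `orf_id`, `strand`,
#'   `start`, `end` (genomic, forward-strand 1-based), `ref_start`,
#'   `ref_end`, `e_value`, `score`.
#' @export
match_orfs_to_reference <- function(orfs, reference, e_value_threshold = 0.05,
                                    split_gap = 8, matrix = blosum62(),
                                    gap_open = 11, gap_extend = 1) {
  if (inherits(reference, "fasta_dataset")) {
    if (n_records(reference) != 1L)
      usage_error("the reference protein file must contain exactly one record")
    reference <- reference$seq[1]
  }
  if (nrow(orfs) == 0L) return(empty_matches())
  db <- protein_database(orfs_to_datasets(orfs)$prot)
  qenc <- encode_protein(reference, matrix)
  senc <- lapply(db$records$seq, encode_protein, mat = matrix)
  scores <- sw_score_many_c(qenc, senc, matrix, gap_open, gap_extend)
  e <- KA_K * nchar(reference) * db$total_length * exp(-KA_LAMBDA * scores)
  sel <- which(e < e_value_threshold)
  rows <- list()
  for (k in sel) {
    aln <- sw_align_c(qenc, senc[[k]], matrix, gap_open, gap_extend, TRUE)
    orf <- orfs[k, ]
    for (seg in split_alignment(aln, split_gap)) {
      g <- subject_span_to_genomic(orf, seg$s_span)
      rows[[length(rows) + 1L]] <-
        data.frame(orf_id = orf$orf_id, strand = orf$strand,
                   start = g[1], end = g[2],
                   ref_start = seg$q_span[1], ref_end = seg$q_span[2],
                   e_value = e[k], score = aln$score,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_matches())
  out <- do.call(rbind, rows)
  out[order(out$e_value, -out$score), , drop = FALSE]
}

# Split alignment columns at long subject insertions; returns per-segment
# query and subject spans. Segments with fewer than 5 aligned pairs drop.
split_alignment <- function(aln, split_gap) {
  qa <- aln$q_aln; sa <- aln$s_aln
  if (length(qa) == 0L) return(list())
  ins <- is.na(qa)  # subject-side insertion (gap in query)
  r <- rle(ins)
  cut_after <- cumsum(r$lengths)[r$values & r$lengths >= split_gap]
  seg_id <- findInterval(seq_along(qa), cut_after + 1L) + 1L
  out <- list()
  for (g in split(seq_along(qa), seg_id)) {
    qs <- qa[g]; ss <- sa[g]
    both <- !is.na(qs) & !is.na(ss)
    if (sum(both) < 5L) next
    out[[length(out) + 1L]] <- list(q_span = range(qs[both]),
                                    s_span = range(ss[both]))
  }
  out
}

# Genomic interval covered by subject (ORF protein) residues [s1, s2].
subject_span_to_genomic <- function(orf, s_span) {
  s1 <- s_span[1]; s2 <- s_span[2]
  if (orf$strand == "+") {
    c(orf$start + 3L * (s1 - 1L), orf$start + 3L * s2 - 1L)
  } else {
    c(orf$end - 3L * s2 + 1L, orf$end - 3L * (s1 - 1L))
  }
}

dominant_strand <- function(matches) {
  if (nrow(matches) == 0L) return("+")
  w <- tapply(matches$score, matches$strand, sum)
  names(w)[which.max(w)]
}

#' Sort exon matches into transcript order
#'
#' Plus-strand genes are ordered by ascending genomic start; when the
#' (score-weighted) dominant strand is minus, ordering is by descending
#' genomic start so exon order follows transcript order on the
#' reverse-complement. Stable on ties.
#'
#' @param matches data frame from [match_orfs_to_reference()].
#' @return the reordered data frame.
#' @export
sort_exon_matches <- function(matches) {
  if (nrow(matches) <= 1L) return(matches)
  desc <- dominant_strand(matches) == "-"
  out <- matches[order(matches$start, decreasing = desc, method = "radix"), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

# Maximum-score chain of matches compatible in both genomic and reference
# coordinates (small overlaps tolerated); input must be in transcript order
# on the working (plus) strand.
chain_matches <- function(ms, tol_g = 120, tol_r = 40) {
  n <- nrow(ms)
  if (n <= 1L) return(ms)
  best <- ms$score
  prev <- integer(n)
  for (j in seq(2L, n)) {
    for (i in seq_len(j - 1L)) {
      ok <- ms$start[j] > ms$end[i] - tol_g &&
        ms$ref_start[j] > ms$ref_end[i] - tol_r &&
        ms$ref_start[j] > ms$ref_start[i] &&
        ms$ref_end[j] >= ms$ref_end[i] - 12
      if (ok && best[i] + ms$score[j] > best[j]) {
        best[j] <- best[i] + ms$score[j]
        prev[j] <- i
      }
    }
  }
  k <- which.max(best)
  path <- integer()
  while (k != 0L) { path <- c(k, path); k <- prev[k] }
  out <- ms[path, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Ungapped positional identity of a candidate CDS translation against the
# reference; cheap junction-candidate score (positions compare one-to-one
# when earlier junctions are correct).
prefix_identity <- function(prot, ref_chars) {
  p <- strsplit(prot, "")[[1]]
  k <- min(length(p), length(ref_chars))
  if (k == 0L) return(0L)
  sum(p[seq_len(k)] == ref_chars[seq_len(k)])
}

#' Join exon matches into a gene model
#'
#' Iterative junction refinement: exon candidates (in transcript order) are
#' merged; each internal junction is refined to a canonical GT donor / AG
#' acceptor pair found within `window` nucleotides of the aligned exon
#' boundaries; the concatenation is translated in frame +1; when an
#' internal stop codon appears the offending junction is shifted to its
#' next-best candidate pair and the cycle repeats; the model is accepted
#' when the translation aligns significantly to the reference with
#' non-decreasing coverage. Minus-strand matches trigger
#' reverse-complementation of the region before joining; reported exon
#' coordinates remain forward-strand 1-based.
#'
#' @param sorted_matches output of [sort_exon_matches()].
#' @param region single-record nucleotide [dataset()] (or residue string).
#' @param reference single protein residue string or single-record
#'   [dataset()].
#' @param window junction search half-width in nucleotides (default 30).
#' @param e_value_threshold acceptance threshold for the final alignment.
#' @param max_cycles bound on refinement cycles.
#' @return a `gene_model`: list with `status` (`joined` / `failed`),
#'   `joined_nuc`, `joined_prot`, `exons` (refined forward-strand
#'   intervals), `strand`, `hit` (final alignment) and `refinement_log`.
#' @export
join_exons <- function(sorted_matches, region, reference, window = 30,
                       e_value_threshold = 0.05, max_cycles = 8) {
  if (inherits(region, "fasta_dataset")) region <- region$seq[1]
  if (inherits(reference, "fasta_dataset")) reference <- reference$seq[1]
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  fail <- function(model_nuc = "", model_prot = "", exons = NULL, strand = "+") {
    structure(list(status = "failed", joined_nuc = model_nuc,
                   joined_prot = model_prot, exons = exons, strand = strand,
                   hit = NULL, refinement_log = log), class = "gene_model")
  }
  if (is.null(sorted_matches) || nrow(sorted_matches) == 0L) {
    say("no exon matches to join")
    return(fail())
  }
  L <- nchar(region)
  strand <- dominant_strand(sorted_matches)
  ms <- sorted_matches[sorted_matches$strand == strand, , drop = FALSE]
  W <- toupper(region)
  if (strand == "-") {
    W <- toupper(revcomp_nuc(region))
    new_start <- L - ms$end + 1L
    ms$end <- L - ms$start + 1L
    ms$start <- new_start
  }
  ms <- ms[order(ms$start), , drop = FALSE]
  ms <- chain_matches(ms)
  n <- nrow(ms)
  say("joining %d exon candidate(s) on strand %s", n, strand)
  ref_chars <- strsplit(reference, "")[[1]]
  Lr <- length(ref_chars)

  # --- anchor the translation start at an ATG near the mapped position of
  # reference residue 1 (only meaningful when the first exon reaches the
  # reference N-terminus) ---
  target <- ms$start[1] - 3L * (ms$ref_start[1] - 1L)
  start_cands <- integer()
  if (ms$ref_start[1] <= 3L) {
    rng <- max(1L, target - window):min(L - 2L, target + window)
    rng <- rng[rng >= 1L]
    hit <- rng[substring(W, rng, rng + 2L) == "ATG"]
    if (length(hit)) {
      k <- pmin((ms$end[1] - hit + 1L) %/% 3L, 40L)
      sc <- vapply(seq_along(hit), function(j) {
        if (k[j] < 1L) return(-1L)
        prefix_identity(translate_nuc(substr(W, hit[j], hit[j] + 3L * k[j] - 1L)),
                        ref_chars)
      }, numeric(1))
      start_cands <- hit[order(-sc, abs(hit - target))]
    }
  }
  if (length(start_cands) == 0L) {
    start_cands <- max(1L, target)
    say("no ATG anchor found near position %d; using aligned start", target)
  } else {
    say("start anchored at ATG, position %d (working strand)", start_cands[1])
  }

  # candidate donor/acceptor pairs for junction i (between exon i and i+1),
  # ranked lazily inside the refinement cycle
  junction_pairs <- function(i, seg_start_i, prefix_nuc) {
    t_est <- ms$end[i]; s_est <- ms$start[i + 1L]
    # when adjacent matches overlap in reference coordinates, one (or both)
    # alignment tails crept into the intron by chance; the overlap bounds
    # the creep, so widen the search inward by three nucleotides per
    # overlapping residue (donor may lie earlier, acceptor later)
    ov <- 3L * max(0L, ms$ref_end[i] - ms$ref_start[i + 1L] + 1L)
    dd <- max(seg_start_i + 2L, t_est - window - ov):min(L - 2L, t_est + window)
    dd <- dd[substring(W, dd + 1L, dd + 2L) == "GT"]
    aa <- max(3L, s_est - window):min(ms$end[i + 1L], s_est + window + ov)
    aa <- aa[substring(W, aa - 2L, aa - 1L) == "AG"]
    pairs <- expand.grid(d = dd, a = aa)
    pairs <- pairs[pairs$a >= pairs$d + 5L, , drop = FALSE]
    if (nrow(pairs) == 0L) {
      say("junction %d: no canonical GT-AG pair within window %d", i, window)
      return(NULL)
    }
    tail_end <- ms$end[i + 1L]
    sc <- numeric(nrow(pairs))
    feasible <- logical(nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      d <- pairs$d[p]; a <- pairs$a[p]
      pre <- paste0(prefix_nuc, substr(W, seg_start_i, d))
      pre_prot <- translate_nuc(pre)
      feasible[p] <- !grepl("*", pre_prot, fixed = TRUE)
      cand <- translate_nuc(paste0(pre, substr(W, a, tail_end)))
      sc[p] <- prefix_identity(cand, ref_chars)
    }
    ord <- order(-feasible, -sc, abs(pairs$d - t_est) + abs(pairs$a - s_est))
    pairs <- pairs[ord, , drop = FALSE]
    pairs
  }

  assemble <- function(choice, start_pos) {
    seg_starts <- integer(n); seg_ends <- integer(n)
    seg_starts[1] <- start_pos
    prefix <- ""
    for (i in seq_len(n - 1L)) {
      pr <- choice[[i]]
      seg_ends[i] <- pr$d
      seg_starts[i + 1L] <- pr$a
      prefix <- paste0(prefix, substr(W, seg_starts[i], seg_ends[i]))
    }
    # terminal exon end: frame-consistent position, preferring one followed
    # by a stop codon (then the stop is included in the joined CDS)
    cum <- nchar(prefix)
    t_est <- ms$end[n]
    tt <- max(seg_starts[n], t_est - window):min(L, t_est + window)
    tt <- tt[(cum + tt - seg_starts[n] + 1L) %% 3L == 0L]
    t_final <- NA_integer_; with_stop <- FALSE
    if (length(tt)) {
      stops <- tt[tt + 3L <= L & substring(W, tt + 1L, tt + 3L) %in% STOP_CODONS]
      if (length(stops) && ms$ref_end[n] >= Lr - 2L) {
        t_final <- stops[which.min(abs(stops - t_est))]
        with_stop <- TRUE
      } else {
        t_final <- tt[which.min(abs(tt - t_est))]
      }
    } else {
      t_final <- t_est + ((seg_starts[n] - t_est - 1L - cum) %% 3L)
      say("no frame-consistent terminal position in window; extending to %d", t_final)
    }
    seg_ends[n] <- if (with_stop) t_final + 3L else t_final
    list(seg_starts = seg_starts, seg_ends = seg_ends,
         nuc = paste0(prefix, substr(W, seg_starts[n], seg_ends[n])),
         with_stop = with_stop)
  }

  # --- refinement cycles ---
  start_idx <- 1L
  cand_idx <- rep(1L, max(n - 1L, 0L))
  best_cov <- 0
  for (cycle in seq_len(max_cycles)) {
    start_pos <- start_cands[min(start_idx, length(start_cands))]
    choice <- vector("list", max(n - 1L, 0L))
    prefix <- ""
    seg_start <- start_pos
    ok <- TRUE
    for (i in seq_len(n - 1L)) {
      pairs <- junction_pairs(i, seg_start, prefix)
      if (is.null(pairs)) {
        say("junction %d unresolvable; best partial model kept", i)
        ok <- FALSE
        break
      }
      pick <- min(cand_idx[i], nrow(pairs))
      choice[[i]] <- list(d = pairs$d[pick], a = pairs$a[pick],
                          n_cand = nrow(pairs))
      prefix <- paste0(prefix, substr(W, seg_start, pairs$d[pick]))
      seg_start <- pairs$a[pick]
    }
    if (!ok) {
      asm <- list(seg_starts = ms$start, seg_ends = ms$end,
                  nuc = paste(substring(W, ms$start, ms$end), collapse = ""))
      prot <- translate_nuc(asm$nuc)
      return(fail(asm$nuc, prot,
                  exons_forward(ms$start, ms$end, strand, L), strand))
    }
    asm <- assemble(choice, start_pos)
    prot <- translate_nuc(asm$nuc)
    core <- sub("\\*$", "", prot)
    stop_at <- regexpr("*", core, fixed = TRUE)
    if (stop_at > 0) {
      # locate the segment containing the offending codon; shift that
      # junction (or the start anchor) to its next candidate
      off <- 3L * (stop_at - 1L) + 1L
      seg_len <- asm$seg_ends - asm$seg_starts + 1L
      seg <- findInterval(off, cumsum(c(1L, seg_len)), rightmost.closed = FALSE)
      seg <- min(max(seg, 1L), n)
      say("cycle %d: internal stop at codon %d (segment %d); shifting junction",
          cycle, stop_at, seg)
      if (seg > 1L) {
        j <- seg - 1L
        if (cand_idx[j] < choice[[j]]$n_cand) cand_idx[j] <- cand_idx[j] + 1L
        else if (start_idx < length(start_cands)) start_idx <- start_idx + 1L
        else { say("junction %d: candidate pairs exhausted", j); break }
      } else if (start_idx < length(start_cands)) {
        start_idx <- start_idx + 1L
      } else if (n > 1L && cand_idx[1] < choice[[1]]$n_cand) {
        cand_idx[1] <- cand_idx[1] + 1L
      } else { say("start anchor candidates exhausted"); break }
      next
    }
    # alignment acceptance
    hit <- smith_waterman(reference, core, query_id = "reference",
                          subject_id = "joined")
    hit$e_value <- KA_K * Lr * max(nchar(core), 1L) *
      exp(-KA_LAMBDA * hit$raw_score)
    cov <- if (hit$raw_score > 0)
      (hit$query_span[2] - hit$query_span[1] + 1) / Lr else 0
    if (hit$e_value < e_value_threshold && cov >= best_cov) {
      say("cycle %d: joined; reference coverage %.3f, e-value %.3g",
          cycle, cov, hit$e_value)
      return(structure(list(status = "joined", joined_nuc = asm$nuc,
                            joined_prot = prot,
                            exons = exons_forward(asm$seg_starts, asm$seg_ends,
                                                  strand, L),
                            strand = strand, hit = hit,
                            refinement_log = log),
                       class = "gene_model"))
    }
    best_cov <- max(best_cov, cov)
    say("cycle %d: alignment not acceptable (coverage %.3f, e-value %.3g)",
        cycle, cov, hit$e_value)
    if (start_idx < length(start_cands)) start_idx <- start_idx + 1L else break
  }
  say("refinement cycles exhausted")
  asm <- assemble(lapply(seq_len(max(n - 1L, 0L)), function(i)
    list(d = ms$end[i], a = ms$start[i + 1L], n_cand = 1L)), start_cands[1])
  fail(asm$nuc, translate_nuc(asm$nuc),
       exons_forward(asm$seg_starts, asm$seg_ends, strand, L), strand)
}

# working-strand intervals back to forward-strand numbering
exons_forward <- function(starts, ends, strand, L) {
  if (strand == "-") {
    fs <- L - ends + 1L; fe <- L - starts + 1L
    data.frame(start = rev(fs), end = rev(fe))
  } else data.frame(start = starts, end = ends)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> status: %s, %d exon(s), strand %s, %d nt\n",
              x$status, NROW(x$exons), x$strand, nchar(x$joined_nuc)))
  invisible(x)
}

#' Predict the CDS and protein from a joined gene model
#'
#' Runs ORF discovery on the joined nucleotide sequence with the
#' user-supplied minimum size, translates in frame +1, and self-checks with
#' a protein search using the reference as query. Among qualifying ORFs the
#' one whose translation aligns best to the reference is reported
#' (alternates are listed in the log): for short CDSs the longest ORF is
#' frequently a stop-free reverse-strand artifact, and the reference
#' alignment is precisely the discriminating evidence the search step
#' provides.
#'
#' @param gene_model output of [join_exons()].
#' @param reference single protein residue string or single-record
#'   [dataset()].
#' @param min_cds_size minimum CDS length in nucleotides (strict, as in
#'   [get_orfs()]).
#' @return list with `nuc`, `pep` (possibly empty strings), `orf` (the
#'   chosen ORF row or NULL), `hits` (reference vs predicted protein) and
#'   `log`.
#' @export
predict_cds <- function(gene_model, reference, min_cds_size = 30) {
  if (inherits(reference, "fasta_dataset")) reference <- reference$seq[1]
  log <- character()
  joined <- gene_model$joined_nuc
  if (!nzchar(joined))
    return(list(nuc = "", pep = "", orf = NULL, hits = list(),
                log = "empty joined sequence; nothing to predict"))
  orfs <- get_orfs(joined, min_orf_length = min_cds_size,
                   region_id = "joined")
  if (nrow(orfs) == 0L)
    return(list(nuc = "", pep = "", orf = NULL, hits = list(),
                log = sprintf("no ORF longer than %d nt in joined sequence",
                              min_cds_size)))
  mat <- blosum62()
  qenc <- encode_protein(reference, mat)
  sc <- sw_score_many_c(qenc, lapply(orfs$prot, encode_protein, mat = mat),
                        mat, 11, 1)
  ord <- order(-sc, -nchar(orfs$nuc))
  pick <- ord[1]
  if (length(ord) > 1L)
    log <- c(log, sprintf("alternate qualifying ORFs: %s",
                          paste(orfs$orf_id[ord[-1]], collapse = ", ")))
  pred_nuc <- orfs$nuc[pick]
  pred_pep <- orfs$prot[pick]
  hits <- search_protein(reference,
                         dataset("predicted", "", pred_pep),
                         e_value_threshold = Inf, query_id = "reference")
  list(nuc = pred_nuc, pep = pred_pep, orf = orfs[pick, ], hits = hits,
       log = log)
}

#' Run the conserved-gene annotation pipeline
#'
#' For every nucleotide region in `regions_fasta`, runs ORF discovery,
#' reference-protein search, exon sorting, exon joining and CDS prediction,
#' writing the numbered per-region output files into
#' `output_dir/<region_id>/`. Regions are processed independently; a
#' failure in one region does not stop the others.
#'
#' @param regions_fasta path to a FASTA file of genomic regions (or a
#'   [dataset()]).
#' @param reference_protein_fasta path to a FASTA file containing exactly
#'   one reference protein (or a single-record [dataset()]).
#' @param output_dir output directory (created).
#' @param min_orf_length ORF length threshold in nucleotides (strict;
#'   default 30).
#' @param e_value significance threshold for matches (default 0.05).
#' @param min_cds_size minimum predicted-CDS length (default 30).
#' @param junction_window junction search half-width (default 30).
#' @return invisibly, a data frame summarising each region: `region_id`,
#'   `status` (`joined`, `failed`, `no-match`), `n_exons`, `pep` (predicted
#'   protein residues, possibly empty).
#' @export
run_cga <- function(regions_fasta, reference_protein_fasta, output_dir,
                    min_orf_length = 30, e_value = 0.05, min_cds_size = 30,
                    junction_window = 30) {
  regions <- if (inherits(regions_fasta, "fasta_dataset")) regions_fasta
             else read_fasta(regions_fasta)
  reference <- if (inherits(reference_protein_fasta, "fasta_dataset"))
    reference_protein_fasta else read_fasta(reference_protein_fasta)
  if (n_records(reference) != 1L)
    usage_error("the reference protein file must contain exactly one record")
  ref_seq <- reference$seq[1]
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list()
  for (r in seq_len(n_records(regions))) {
    rid <- regions$id[r]
    rdir <- file.path(output_dir, rid)
    dir.create(rdir, showWarnings = FALSE, recursive = TRUE)
    region <- subset_dataset(regions, r)
    res <- tryCatch(
      annotate_region(region, ref_seq, rdir, min_orf_length, e_value,
                      min_cds_size, junction_window),
      error = function(e) {
        warning(sprintf("region %s failed: %s", rid, conditionMessage(e)),
                call. = FALSE)
        list(status = "failed", n_exons = 0L, pep = "")
      })
    summary[[r]] <- data.frame(region_id = rid, status = res$status,
                               n_exons = res$n_exons, pep = res$pep,
                               stringsAsFactors = FALSE)
  }
  out <- if (length(summary)) do.call(rbind, summary) else
    data.frame(region_id = character(), status = character(),
               n_exons = integer(), pep = character(), stringsAsFactors = FALSE)
  invisible(out)
}

annotate_region <- function(region, ref_seq, rdir, min_orf_length, e_value,
                            min_cds_size, junction_window) {
  rid <- region$id[1]
  # 01: ORFs
  orfs <- get_orfs(region, min_orf_length = min_orf_length)
  ds <- orfs_to_datasets(orfs)
  write_fasta(ds$nuc, file.path(rdir, "01_orfs.nuc.fasta"))
  write_fasta(ds$prot, file.path(rdir, "01_orfs.prot.fasta"))
  # 02: significant matches
  matches <- match_orfs_to_reference(orfs, ref_seq, e_value_threshold = e_value)
  write_match_table(matches, file.path(rdir, sprintf("02_%s.ini", rid)))
  if (nrow(matches) == 0L) {
    warning(sprintf("region %s: no significant match against the reference; annotation cannot proceed", rid),
            call. = FALSE)
    return(list(status = "no-match", n_exons = 0L, pep = ""))
  }
  # 03: transcript order
  sorted <- sort_exon_matches(matches)
  write_match_table(sorted, file.path(rdir, sprintf("03_%s.ini.sorted", rid)))
  # 04: exon joining
  model <- join_exons(sorted, region, ref_seq, window = junction_window,
                      e_value_threshold = e_value)
  write_fasta(dataset(paste0(rid, "_joined"), paste0("status=", model$status),
                      model$joined_nuc %||% ""),
              file.path(rdir, sprintf("04_%s.join_exons_results", rid)))
  writeLines(model$refinement_log,
             file.path(rdir, sprintf("04_%s.join_exons_results.log", rid)))
  if (!nzchar(model$joined_nuc))
    return(list(status = model$status, n_exons = 0L, pep = ""))
  # 05: prediction + self-check search
  pred <- predict_cds(model, ref_seq, min_cds_size = min_cds_size)
  write_fasta(dataset(paste0(rid, "_prejoin"), "", model$joined_nuc),
              file.path(rdir, sprintf("05_%s.join_exons_results", rid)))
  nuc_d <- if (nzchar(pred$nuc))
    dataset(paste0(rid, "_cds"), "", pred$nuc) else dataset()
  pep_d <- if (nzchar(pred$pep))
    dataset(paste0(rid, "_pep"), "", pred$pep) else dataset()
  write_fasta(nuc_d, file.path(rdir, sprintf("05_%s.nuc", rid)))
  write_fasta(pep_d, file.path(rdir, sprintf("05_%s.pep", rid)))
  write_hits_table(pred$hits, file.path(rdir, sprintf("05_%s.pep.blast", rid)))
  if (!nzchar(pred$nuc))
    warning(sprintf("region %s: no ORF of at least %d nt in the joined sequence",
                    rid, min_cds_size), call. = FALSE)
  list(status = model$status, n_exons = NROW(model$exons), pep = pred$pep)
}

write_match_table <- function(matches, path) {
  utils::write.table(matches[MATCH_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
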