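# Nucleotide-level primitives: IUPAC reverse-complement and frame-aware
# translation under the standard genetic code. Translation follows transeq
# conventions: stop codons are written '*', codons whose IUPAC expansion is
# ambiguous at the amino-acid level are written 'X', and a trailing partial
# codon is dropped.

IUPAC_FROM <- "ACGTURYSWKMBDHVN"
IUPAC_TO   <- "TGCAAYRSWMKVHDBN"

# codon -> amino acid lookup, filled lazily (includes ambiguity codes)
.codon_env <- new.env(parent = emptyenv())

codon_aa <- function(codons) {
  vapply(codons, function(cd) {
    hit <- .codon_env[[cd]]
    if (!is.null(hit)) return(hit)
    aa <- if (grepl("[^ACGT]", cd)) {
      map <- Biostrings::IUPAC_CODE_MAP
      parts <- strsplit(cd, "")[[1]]
      if (all(parts %in% names(map))) {
        ex <- expand.grid(strsplit(map[parts[1]], "")[[1]],
                          strsplit(map[parts[2]], "")[[1]],
                          strsplit(map[parts[3]], "")[[1]],
                          stringsAsFactors = FALSE)
        aas <- unique(Biostrings::GENETIC_CODE[paste0(ex[[1]], ex[[2]], ex[[3]])])
        if (length(aas) == 1L) aas else "X"
      } else "X"
    } else {
      unname(Biostrings::GENETIC_CODE[[cd]])
    }
    assign(cd, aa, envir = .codon_env)
    aa
  }, character(1), USE.NAMES = FALSE)
}

# Translate one or more nucleotide strings starting at the first base
# ("frame +1" convention); vectorised over x.
translate_nuc <- function(x, frame = 1L) {
  stopifnot(frame %in% 1:3)
  vapply(x, function(s) {
    s <- toupper(s)
    s <- substr(s, frame, nchar(s))
    n <- nchar(s) %/% 3L
    if (n == 0L) return("")
    starts <- seq(1L, by = 3L, length.out = n)
    paste(codon_aa(substring(s, starts, starts + 2L)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# IUPAC-aware complement (case preserved); reverse and complement composable.
revcomp_nuc <- function(x, reverse = TRUE, complement = TRUE) {
  if (complement)
    x <- chartr(paste0(IUPAC_FROM, tolower(IUPAC_FROM)),
                paste0(IUPAC_TO, tolower(IUPAC_TO)), x)
  if (reverse) x <- str_rev(x)
  x
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
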