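DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random uniform DNA sequence
#'
#' @param n sequence length in bp.
#' @param gc GC content (probability of G or C per base).
#' @return a single character string.
#' @export
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# all k-mers of a sequence; windows containing non-ACGT are dropped
seq_kmers <- function(seq, k) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < k) return(character(0))
  km <- substring(seq, seq_len(L - k + 1L), k:L)
  km[!grepl("[^ACGT]", km)]
}

# lexicographic min of k-mer and its reverse complement
canonical_kmers <- function(kmers) {
  if (length(kmers) == 0) return(character(0))
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# DNA string -> integer codes 0..3 (A,C,G,T), -1 for anything else
dna_to_int <- function(x) {
  code <- utf8ToInt(toupper(x))
  out <- rep(-1L, length(code))
  out[code == 65L] <- 0L  # A
  out[code == 67L] <- 1L  # C
  out[code == 71L] <- 2L  # G
  out[code == 84L] <- 3L  # T
  out
}

int_to_dna <- function(v) {
  chars <- c("A", "C", "G", "T")[v + 1L]
  chars[is.na(chars)] <- "N"
  paste(chars, collapse = "")
}

# named character vector of aligned sequences -> integer matrix (taxa x L)
aln_to_int <- function(aln) {
  stopifnot(length(aln) >= 2)
  L <- unique(nchar(aln))
  if (length(L) != 1)
    stop("aligned sequences must have equal length")
  m <- t(vapply(aln, dna_to_int, integer(L)))
  rownames(m) <- names(aln)
  m
}

#' Wilson score interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

fs_log <- function(...) {
  if (isTRUE(getOption("fusionscape.verbose", FALSE)))
    message(sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
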