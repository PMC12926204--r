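#' Windowed nucleotide diversity (pi)
#'
#' Per window, `pi = sum_sites 2 p (1 - p) n / (n - 1) / window_span`:
#' the unbiased per-site heterozygosity summed over segregating sites and
#' divided by the window span in bp.  Sites with missing haplotypes use
#' the site-wise complete-case sample size.  Windows are anchored at the
#' region start; a final partial window is reported with its true span.
#'
#' @param vm a [variant_matrix()].
#' @param region one-row interval data.frame delimiting the scan; default
#'   spans position 0 to one past the last site.
#' @param window window size in bp.
#' @param step step size in bp (may be smaller than `window` for sliding
#'   windows).
#' @return data.frame with columns `seqname`, `start`, `end`, `n`, `S`,
#'   `pi`.
#' @examples
#' vm <- variant_matrix(rbind(c(0L, 1L), c(1L, 0L)), c(10, 60))
#' pi_windows(vm, genomic_interval("chr1", 0, 100), window = 100)
#' @export
pi_windows <- function(vm, region = NULL, window = 20000, step = window) {
  stopifnot(inherits(vm, "variant_matrix"))
  if (n_haplotypes(vm) < 2) stop("need >= 2 haplotypes")
  region <- region %||%
    genomic_interval(vm$seqname, 0, max(vm$positions, 0) + 1)
  wins <- window_grid(region, window, step)
  stats <- site_stats(vm)
  out <- wins
  out$n <- n_haplotypes(vm)
  out$S <- 0L
  out$pi <- 0
  for (i in seq_len(nrow(wins))) {
    inw <- vm$positions >= wins$start[i] & vm$positions < wins$end[i]
    seg <- inw & stats$segregating
    out$S[i] <- sum(seg)
    out$pi[i] <- sum(stats$het[seg]) / (wins$end[i] - wins$start[i])
  }
  out
}

#' Windowed Tajima's D
#'
#' `D = (pi_hat - S / a1) / sqrt(e1 S + e2 S (S - 1))` with the standard
#' constants `a1, a2, b1, b2, c1, c2, e1, e2`, where `pi_hat` is the mean
#' number of pairwise differences in the window (a count, not per site).
#' Windows with `S = 0` report `D = NaN` (undefined), never 0.
#'
#' @inheritParams pi_windows
#' @return data.frame with columns `seqname`, `start`, `end`, `n`, `S`,
#'   `pi`, `tajima_d`.
#' @export
tajima_d_windows <- function(vm, region = NULL, window = 20000,
                             step = window) {
  stopifnot(inherits(vm, "variant_matrix"))
  n <- n_haplotypes(vm)
  if (n < 3) stop("Tajima's D needs >= 3 haplotypes")
  out <- pi_windows(vm, region, window, step)
  stats <- site_stats(vm)
  cst <- tajima_constants(n)
  out$tajima_d <- NaN
  for (i in seq_len(nrow(out))) {
    inw <- vm$positions >= out$start[i] & vm$positions < out$end[i]
    seg <- inw & stats$segregating
    S <- sum(seg)
    if (S == 0) next
    pihat <- sum(stats$het[seg])  # mean pairwise differences (count)
    denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
    out$tajima_d[i] <- (pihat - S / cst$a1) / denom
  }
  out
}

#' Tajima's D variance constants
#'
#' @param n number of sequences (>= 3).
#' @return list with `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 3)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# per-site complete-case heterozygosity contribution and segregation flag
site_stats <- function(vm) {
  m <- vm$mat
  n1 <- colSums(m == 1L, na.rm = TRUE)
  neff <- colSums(!is.na(m))
  p <- ifelse(neff > 0, n1 / neff, 0)
  segregating <- n1 > 0 & n1 < neff & neff >= 2
  het <- ifelse(neff >= 2, 2 * p * (1 - p) * neff / (neff - 1), 0)
  list(segregating = segregating, het = het, neff = neff)
}

window_grid <- function(region, window, step) {
  stopifnot(nrow(region) == 1, window >= 1, step >= 1)
  starts <- seq(region$start, max(region$start, region$end - 1), by = step)
  ends <- pmin(starts + window, region$end)
  keep <- starts < region$end & ends > starts
  genomic_interval(region$seqname, starts[keep], ends[keep])
}
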