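#' Simulate a neutral coalescent haplotype panel
#'
#' Samples one Kingman coalescent genealogy for `n_haplotypes` lineages
#' and drops infinite-sites mutations on it at per-site rate `theta / 2`
#' per `2 Ne` generations, so the expected number of segregating sites is
#' `theta * seq_len * a1` with `a1 = sum(1 / 1:(n-1))` (the Watterson
#' expectation).
#'
#' @param n_haplotypes number of haploid samples (>= 2).
#' @param seq_len sequence length in bp.
#' @param theta_per_site scaled mutation rate per site (`4 Ne mu`), > 0.
#' @param seed optional integer seed.
#' @param seqname sequence name for the resulting matrix.
#' @return a [variant_matrix()] of derived-allele indicators.
#' @examples
#' vm <- simulate_haplotype_panel(10, 1e4, 1e-3, seed = 1)
#' @export
simulate_haplotype_panel <- function(n_haplotypes, seq_len, theta_per_site,
                                     seed = NULL, seqname = "chr1") {
  if (n_haplotypes < 2) stop("need at least 2 haplotypes")
  if (theta_per_site < 0) stop("theta must be >= 0")
  if (theta_per_site == 0)
    return(variant_matrix(matrix(integer(0), nrow = n_haplotypes, ncol = 0),
                          numeric(0), seqname = seqname))
  if (!is.null(seed)) set.seed(seed)
  n <- n_haplotypes
  # genealogy: membership of each coalescent branch, branch length in 2Ne
  active <- as.list(seq_len(n))
  blen <- numeric(0)
  bmem <- list()
  t <- 0
  k <- n
  birth <- rep(0, n)  # time each active lineage was created
  while (k > 1) {
    t <- t + rexp(1) / choose(k, 2)
    pr <- sample.int(k, 2)
    for (i in pr) {
      blen <- c(blen, t - birth[i])
      bmem[[length(bmem) + 1L]] <- active[[i]]
    }
    active[[pr[1]]] <- c(active[[pr[1]]], active[[pr[2]]])
    birth[pr[1]] <- t
    active <- active[-pr[2]]
    birth <- birth[-pr[2]]
    k <- k - 1L
  }
  total_len <- sum(blen)
  n_mut <- rpois(1, theta_per_site / 2 * seq_len * total_len)
  if (n_mut == 0)
    return(variant_matrix(matrix(integer(0), nrow = n, ncol = 0),
                          numeric(0), seqname = seqname))
  branch <- sample.int(length(blen), n_mut, replace = TRUE, prob = blen)
  pos <- sort(sample.int(seq_len, min(n_mut, seq_len))) - 1L
  branch <- branch[seq_along(pos)]
  mat <- matrix(0L, nrow = n, ncol = length(pos))
  for (j in seq_along(pos)) mat[bmem[[branch[j]]], j] <- 1L
  variant_matrix(mat, pos, seqname = seqname)
}
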