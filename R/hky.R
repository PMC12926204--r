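#' HKY85 substitution model parameters
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param base_freqs stationary frequencies in A, C, G, T order; must be
#'   non-negative and sum to 1 (tolerance 1e-9).
#' @param gamma_shape optional shape of gamma rate heterogeneity across
#'   sites; `NULL` disables heterogeneity (equivalently, shape = Inf).
#' @param n_rate_categories number of discrete gamma categories used when
#'   `gamma_shape` is set.
#' @return an object of class `hky_params`.
#' @examples
#' hky_params(kappa = 4)
#' @export
hky_params <- function(kappa = 4, base_freqs = c(0.3, 0.2, 0.2, 0.3),
                       gamma_shape = NULL, n_rate_categories = 4L) {
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (length(base_freqs) != 4 || any(base_freqs < 0))
    stop("base_freqs must be 4 non-negative values")
  if (abs(sum(base_freqs) - 1) > 1e-9)
    stop("base_freqs must sum to 1")
  if (!is.null(gamma_shape)) {
    if (is.infinite(gamma_shape)) gamma_shape <- NULL
    else if (gamma_shape <= 0) stop("gamma_shape must be > 0")
  }
  structure(list(kappa = kappa, base_freqs = as.numeric(base_freqs),
                 gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories)),
            class = "hky_params")
}

#' @export
print.hky_params <- function(x, ...) {
  cat(sprintf("HKY85: kappa = %g, freqs = (%s)%s\n", x$kappa,
              paste(signif(x$base_freqs, 3), collapse = ", "),
              if (is.null(x$gamma_shape)) ""
              else sprintf(", gamma shape = %g (%d categories)",
                           x$gamma_shape, x$n_rate_categories)))
  invisible(x)
}

#' HKY85 transition probability matrix
#'
#' @param t branch length in expected substitutions per site.
#' @param params an [hky_params()] object.
#' @return 4x4 matrix `P[i, j] = P(j | i, t)` in A, C, G, T order.
#' @export
hky_pmatrix <- function(t, params = hky_params()) {
  stopifnot(t >= 0)
  P <- cpp_hky_pmat(t, params$base_freqs, params$kappa)
  dimnames(P) <- list(DNA_BASES, DNA_BASES)
  P
}

# mean rates of the n equal-probability categories of Gamma(shape, shape)
discrete_gamma_rates <- function(shape, n) {
  if (is.null(shape)) return(1)
  q <- qgamma(seq(0, 1, length.out = n + 1), shape = shape, rate = shape)
  # category mean via incomplete gamma (mean of Gamma(shape, shape) is 1)
  up <- pgamma(q, shape = shape + 1, rate = shape)
  n * (up[-1] - up[-(n + 1)])
}

model_rates <- function(params) {
  if (is.null(params$gamma_shape)) return(1.0)
  r <- discrete_gamma_rates(params$gamma_shape, params$n_rate_categories)
  r / mean(r)
}
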