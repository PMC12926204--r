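#' Simulate a CpG methylation track over a satellite/spacer region
#'
#' Places methylation sites on a regular grid and draws per-site
#' frequencies around interval-specific means: hypermethylated satellite,
#' hypomethylated spacer pockets, and (optionally) a localized dip inside
#' a higher-order-repeat array, mimicking a centromere dip region.
#' Frequencies are clipped to `[0, 1]`.
#'
#' @param region_len region length in bp.
#' @param truth optional BED-style data.frame labelling `satellite` /
#'   `spacer` intervals (as produced by
#'   [simulate_satellite_chromosome()]); positions outside any labelled
#'   interval use the satellite level.
#' @param dip optional one-row interval data.frame marking the dip; must
#'   lie inside the region.
#' @param levels numeric vector `c(sat, spacer, dip)` of mean
#'   frequencies, each in `[0, 1]`.
#' @param noise_sd gaussian noise standard deviation added per site.
#' @param site_spacing bp between consecutive sites.
#' @param coverage mean read coverage (Poisson) reported per site.
#' @param seed optional integer seed.
#' @param seqname sequence name for the track.
#' @return bedMethyl-style data.frame (`seqname`, `start`, `end`,
#'   `coverage`, `frequency`), one row per site.
#' @export
simulate_methylation_track <- function(region_len, truth = NULL, dip = NULL,
                                       levels = c(sat = 0.85, spacer = 0.2,
                                                  dip = 0.1),
                                       noise_sd = 0.02, site_spacing = 20,
                                       coverage = 30, seed = NULL,
                                       seqname = "chrCap") {
  if (any(levels < 0 | levels > 1))
    stop("all level means must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(dip)) {
    if (dip$start < 0 || dip$end > region_len)
      stop("dip interval outside the region")
  }
  pos <- seq(0, region_len - 1, by = site_spacing)
  mean_at <- rep(levels[[1]], length(pos))
  if (!is.null(truth)) {
    sp <- truth[truth$name == "spacer", , drop = FALSE]
    for (i in seq_len(nrow(sp)))
      mean_at[pos >= sp$start[i] & pos < sp$end[i]] <- levels[[2]]
  }
  if (!is.null(dip))
    mean_at[pos >= dip$start & pos < dip$end] <- levels[[3]]
  freq <- pmin(1, pmax(0, mean_at + rnorm(length(pos), 0, noise_sd)))
  data.frame(seqname = seqname, start = pos, end = pos + 1,
             coverage = rpois(length(pos), coverage), frequency = freq,
             stringsAsFactors = FALSE)
}
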