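#' Windowed mean methylation
#'
#' Mean site frequency per window, assigning each site by its midpoint;
#' empty windows report `NA`.  With `weighted = TRUE` the mean is
#' coverage-weighted.
#'
#' @param track bedMethyl-style data.frame (`seqname`, `start`, `end`,
#'   `coverage`, `frequency`).
#' @param window window size in bp.
#' @param step step size in bp (<= window).
#' @param region optional one-row interval to scan; defaults to the
#'   track's span.
#' @param weighted coverage-weighted means.
#' @return data.frame `seqname`, `start`, `end`, `n_sites`,
#'   `mean_frequency`.
#' @export
windowed_methylation <- function(track, window = 1000, step = 500,
                                 region = NULL, weighted = FALSE) {
  if (step > window) stop("step must be <= window")
  region <- region %||%
    genomic_interval(track$seqname[1], min(track$start), max(track$end))
  wins <- window_grid(region, window, step)
  mid <- (track$start + track$end) / 2
  out <- wins
  out$n_sites <- 0L
  out$mean_frequency <- NA_real_
  for (i in seq_len(nrow(wins))) {
    inw <- mid >= wins$start[i] & mid < wins$end[i]
    out$n_sites[i] <- sum(inw)
    if (any(inw)) {
      out$mean_frequency[i] <- if (weighted)
        sum(track$frequency[inw] * track$coverage[inw]) /
          sum(track$coverage[inw])
      else mean(track$frequency[inw])
    }
  }
  out
}

#' Call centromere dip regions (CDRs) within a HOR array
#'
#' Tiles the higher-order-repeat (HOR) interval with non-overlapping
#' `window` bp windows, computes mean methylation per window and calls
#' CDRs as runs of hypomethylated windows below the lower quartile (Q1)
#' of all HOR window means.  In the default `"deep"` mode a window must
#' additionally be deep — `mean <= min + depth_frac * (Q1 - min)` — and
#' each run must contain a local minimum, which anchors calls to genuine
#' dips rather than quantile noise (a quartile cutoff alone admits a
#' quarter of background windows by construction).  `mode = "q1"` applies
#' the literal below-Q1 rule with local-minimum contact only.
#'
#' @param hor one-row interval data.frame delimiting the HOR array.
#' @param track bedMethyl-style data.frame of site frequencies.
#' @param window window size in bp.
#' @param mode `"deep"` (default) or `"q1"`.
#' @param depth_frac depth requirement for `"deep"` mode, in `[0, 1]`:
#'   0 keeps only minima as deep as the global minimum, 1 reduces to the
#'   Q1 rule.
#' @return object of class `cdr_call`: list with `hor`, `cdrs` (interval
#'   data.frame), `window_means`, `q1`, `flagged` (TRUE when the track
#'   was flat and no CDR is callable).
#' @export
call_cdrs <- function(hor, track, window = 5000, mode = c("deep", "q1"),
                      depth_frac = 0.5) {
  mode <- match.arg(mode)
  if (interval_length(hor) < 2 * window)
    stop("HOR must span at least two windows")
  wm <- windowed_methylation(track, window = window, step = window,
                             region = hor)
  means <- wm$mean_frequency
  usable <- !is.na(means)
  out <- structure(list(hor = hor, cdrs = wm[0, c("seqname", "start",
                                                  "end")],
                        window_means = wm, q1 = NA_real_,
                        flagged = FALSE), class = "cdr_call")
  if (sum(usable) < 2) {
    out$flagged <- TRUE
    return(out)
  }
  mu <- means[usable]
  q1 <- unname(quantile(mu, 0.25, type = 7))
  gmin <- min(mu)
  out$q1 <- q1
  if (diff(range(mu)) < 1e-12) {
    out$flagged <- TRUE  # flat track: no dip to call
    return(out)
  }
  below <- !is.na(means) & means < q1
  deep_thr <- gmin + depth_frac * (q1 - gmin)
  is_deep <- !is.na(means) & means <= deep_thr
  # local minima of the window-mean profile (ties count)
  n <- length(means)
  localmin <- vapply(seq_len(n), function(i) {
    if (is.na(means[i])) return(FALSE)
    lo <- if (i > 1 && !is.na(means[i - 1])) means[i - 1] else Inf
    hi <- if (i < n && !is.na(means[i + 1])) means[i + 1] else Inf
    means[i] <= lo && means[i] <= hi
  }, TRUE)
  member <- if (mode == "deep") below & is_deep else below
  runs <- rle(member)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- list()
  for (ri in which(runs$values)) {
    idx <- starts[ri]:ends[ri]
    seeded <- if (mode == "deep") any(localmin[idx] & is_deep[idx])
    else any(localmin[idx])
    if (seeded)
      keep[[length(keep) + 1L]] <-
        c(wm$start[idx[1]], wm$end[idx[length(idx)]])
  }
  if (length(keep) > 0) {
    kv <- do.call(rbind, keep)
    cdrs <- reduce_intervals(genomic_interval(hor$seqname, kv[, 1],
                                              kv[, 2]), hor$seqname)
    out$cdrs <- cdrs
  }
  out
}

#' @export
print.cdr_call <- function(x, ...) {
  cat(sprintf("cdr_call: %d CDR(s) in %s (Q1 = %.3f)%s\n", nrow(x$cdrs),
              format_region(x$hor), x$q1,
              if (x$flagged) " [flagged: flat/unusable track]" else ""))
  invisible(x)
}

#' Compare methylation between two HOR groups
#'
#' Chunks each track into sliding `chunk` bp windows (step `step`),
#' excludes chunks overlapping the given CDR intervals, and compares the
#' chunk mean-methylation distributions with a two-sided Mann-Whitney U
#' test (normal approximation with tie correction).
#'
#' @param track_a,track_b bedMethyl-style data.frames.
#' @param chunk chunk size in bp (default 17.1 kbp).
#' @param step step size in bp (default half a chunk).
#' @param exclude_a,exclude_b optional interval data.frames (e.g. CDR
#'   calls) whose overlapping chunks are dropped.
#' @return list with `U`, `p`, `n_a`, `n_b`, `mean_a`, `mean_b`.
#' @export
compare_methylation_groups <- function(track_a, track_b, chunk = 17100,
                                       step = 8550, exclude_a = NULL,
                                       exclude_b = NULL) {
  chunk_means <- function(track, exclude) {
    wm <- windowed_methylation(track, window = chunk, step = step)
    if (!is.null(exclude) && nrow(exclude) > 0) {
      drop <- rep(FALSE, nrow(wm))
      for (i in seq_len(nrow(exclude)))
        drop <- drop | (wm$start < exclude$end[i] &
                          wm$end > exclude$start[i])
      wm <- wm[!drop, , drop = FALSE]
    }
    wm$mean_frequency[!is.na(wm$mean_frequency)]
  }
  a <- chunk_means(track_a, exclude_a)
  b <- chunk_means(track_b, exclude_b)
  if (length(a) == 0 || length(b) == 0)
    stop("a group is empty after chunking and exclusion")
  if (length(unique(c(a, b))) == 1)
    return(list(U = length(a) * length(b) / 2, p = 1, n_a = length(a),
                n_b = length(b), mean_a = mean(a), mean_b = mean(b)))
  wt <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  list(U = unname(wt$statistic), p = wt$p.value, n_a = length(a),
       n_b = length(b), mean_a = mean(a), mean_b = mean(b))
}
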