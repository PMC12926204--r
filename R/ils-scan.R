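TOPOLOGY_CALLS <- c("concordant", "ILS_HG", "ILS_PG", "unresolved")

#' Classify a gene-tree topology against the species triplet
#'
#' After rooting with the outgroup, the call is determined by which pair
#' of \{H, P, G\} is sister: `concordant` = ((H,P),G) (the species-tree
#' arrangement), `ILS_HG` = ((H,G),P), `ILS_PG` = ((P,G),H).  Extra taxa
#' are pruned; a missing outgroup or an unresolved triplet yields
#' `unresolved`.
#'
#' @param tree `ape::phylo` containing the four mapped taxa.
#' @param taxon_map see [default_taxon_map()].
#' @return one of `"concordant"`, `"ILS_HG"`, `"ILS_PG"`, `"unresolved"`.
#' @examples
#' classify_topology(ape::read.tree(text = "((H,P),(G,O));"),
#'                   default_taxon_map("H", "P", "G", "O"))
#' @export
classify_topology <- function(tree, taxon_map = default_taxon_map()) {
  need <- unlist(taxon_map[c("H", "P", "G", "outgroup")])
  if (!all(need %in% tree$tip.label)) return("unresolved")
  tr <- ape::keep.tip(tree, need)
  tr <- tryCatch(ape::root(tr, outgroup = taxon_map$outgroup,
                           resolve.root = TRUE),
                 error = function(e) NULL)
  if (is.null(tr)) return("unresolved")
  tr <- ape::drop.tip(tr, taxon_map$outgroup)
  # rooted 3-tip tree: the two tips sharing a non-root parent are sisters
  ntip <- length(tr$tip.label)
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])
  tip_parent <- tr$edge[match(seq_len(ntip), tr$edge[, 2]), 1]
  inner <- which(tip_parent != root)
  if (length(inner) != 2) return("unresolved")
  sisters <- sort(tr$tip.label[inner])
  key <- paste(sisters, collapse = "\r")
  if (key == paste(sort(c(taxon_map$H, taxon_map$P)), collapse = "\r"))
    "concordant"
  else if (key == paste(sort(c(taxon_map$H, taxon_map$G)), collapse = "\r"))
    "ILS_HG"
  else if (key == paste(sort(c(taxon_map$P, taxon_map$G)), collapse = "\r"))
    "ILS_PG"
  else "unresolved"
}

# the three resolved quartet topologies as C++ encodings; row order of the
# alignment matrices must be H, P, G, outgroup
quartet_candidates <- function() {
  # nodes: 0 root, 3..6 = H,P,G,O; 1,2 spare internal
  list(
    concordant = list(parent = c(-1L, 0L, 0L, 1L, 1L, 2L, 2L),
                      leafrow = c(-1L, -1L, -1L, 0L, 1L, 2L, 3L)),
    ILS_HG = list(parent = c(-1L, 0L, 0L, 1L, 2L, 1L, 2L),
                  leafrow = c(-1L, -1L, -1L, 0L, 1L, 2L, 3L)),
    ILS_PG = list(parent = c(-1L, 0L, 0L, 2L, 1L, 1L, 2L),
                  leafrow = c(-1L, -1L, -1L, 0L, 1L, 2L, 3L)))
}

#' Per-window maximum-likelihood topology scan
#'
#' For each window alignment, fits the three resolved quartet topologies
#' under HKY85 (branch lengths optimized per candidate) and assigns the
#' triplet call of the best one.  Windows with fewer than `min_sites`
#' parsimony-informative sites, or with best-vs-runner-up support below
#' `support_threshold` log-likelihood units, are `unresolved`.
#'
#' @param alignments list of window alignments: named character vectors
#'   or integer matrices whose rows are the taxa of `taxon_map`.
#' @param windows optional interval data.frame (one row per window) used
#'   to annotate the calls.
#' @param taxon_map see [default_taxon_map()].
#' @param min_sites minimum parsimony-informative sites for a call.
#' @param support_threshold minimum delta log-likelihood for a call; the
#'   default 0 applies no support filter.
#' @param params an [hky_params()]; `base_freqs = NULL` (via
#'   `empirical_freqs = TRUE`) estimates frequencies per window.
#' @param empirical_freqs estimate base frequencies per window.
#' @return data.frame of topology calls: `call`, `delta_lnl`,
#'   `n_informative_sites`, plus window coordinates when supplied.
#' @export
scan_windows <- function(alignments, windows = NULL,
                         taxon_map = default_taxon_map(), min_sites = 3,
                         support_threshold = 0, params = hky_params(),
                         empirical_freqs = TRUE) {
  taxa <- unlist(taxon_map[c("H", "P", "G", "outgroup")])
  mats <- lapply(alignments, function(a) {
    m <- if (is.matrix(a)) a else aln_to_int(a)
    if (!all(taxa %in% rownames(m)))
      stop("window alignment missing mapped taxa")
    m[taxa, , drop = FALSE]
  })
  nwin <- length(mats)
  use_emp <- empirical_freqs || is.null(params$base_freqs)
  freqs <- if (use_emp) vapply(mats, empirical_freqs, numeric(4))
  else matrix(params$base_freqs, 4, nwin)
  cands <- quartet_candidates()
  res <- cpp_hky_ml_batch(mats, lapply(cands, `[[`, "parent"),
                          lapply(cands, `[[`, "leafrow"), freqs,
                          params$kappa, model_rates(params), 3L, 1e-6,
                          4.0, 0.05)
  lnl <- res$lnl
  ninf <- res$n_informative
  best <- max.col(lnl, ties.method = "first")
  delta <- apply(lnl, 1, function(r) {
    s <- sort(r, decreasing = TRUE)
    s[1] - s[2]
  })
  call <- names(cands)[best]
  call[ninf < min_sites | delta < support_threshold] <- "unresolved"
  out <- data.frame(call = factor(call, levels = TOPOLOGY_CALLS),
                    delta_lnl = delta, n_informative_sites = ninf,
                    stringsAsFactors = FALSE)
  if (!is.null(windows)) out <- cbind(windows, out)
  out
}

#' ILS proportion with Wilson confidence interval
#'
#' The proportion of resolved windows called discordant
#' (`ILS_HG` + `ILS_PG`), with a 95% Wilson score interval.  The
#' proportion over all windows (counting unresolved in the denominator)
#' is reported alongside.
#'
#' @param calls data.frame from [scan_windows()] (or a factor/character
#'   vector of calls).
#' @param region optional interval; restricts to windows whose midpoint
#'   falls inside it (requires coordinates in `calls`).
#' @param conf confidence level.
#' @return list with `proportion`, `ci`, `n_resolved`, `n_windows`,
#'   `n_ils`, `proportion_all`.
#' @export
ils_proportion <- function(calls, region = NULL, conf = 0.95) {
  cl <- if (is.data.frame(calls)) calls else data.frame(call = calls)
  if (!is.null(region)) {
    if (!all(c("start", "end") %in% names(cl)))
      stop("region subsetting requires window coordinates")
    mid <- (cl$start + cl$end) / 2
    cl <- cl[mid >= region$start & mid < region$end, , drop = FALSE]
  }
  v <- as.character(cl$call)
  n_res <- sum(v != "unresolved")
  n_ils <- sum(v %in% c("ILS_HG", "ILS_PG"))
  if (n_res == 0) {
    warning("no resolved windows in region; proportion undefined")
    return(list(proportion = NaN, ci = c(NA, NA), n_resolved = 0L,
                n_windows = length(v), n_ils = 0L, proportion_all = NaN))
  }
  list(proportion = n_ils / n_res, ci = wilson_ci(n_ils, n_res, conf),
       n_resolved = n_res, n_windows = length(v), n_ils = n_ils,
       proportion_all = n_ils / length(v))
}

#' Fold change of a regional ILS proportion over background
#'
#' @param region_prop regional discordance proportion.
#' @param background_prop background (e.g. chromosome-wide mean)
#'   proportion; must be > 0.
#' @return ratio `region_prop / background_prop`.
#' @export
fold_change <- function(region_prop, background_prop) {
  if (is.na(background_prop) || background_prop <= 0)
    stop("fold change undefined for zero background")
  region_prop / background_prop
}

#' Breakpoint polarity contrast with permutation p-value
#'
#' Tests whether the ILS proportion differs between the distal and
#' proximal sides of a breakpoint: `delta = distal - proximal` over
#' resolved windows, with a two-sided p-value from permuting side labels
#' across windows.
#'
#' @param proximal_calls,distal_calls call data.frames or vectors (see
#'   [ils_proportion()]).
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return list with `delta`, `p`, `proximal`, `distal`.
#' @export
polarity_contrast <- function(proximal_calls, distal_calls, n_perm = 1999,
                              seed = NULL) {
  if (n_perm < 100) warning("n_perm < 100: p-value resolution is coarse")
  if (!is.null(seed)) set.seed(seed)
  get_calls <- function(x)
    as.character(if (is.data.frame(x)) x$call else x)
  pv <- get_calls(proximal_calls)
  dv <- get_calls(distal_calls)
  pv <- pv[pv != "unresolved"]
  dv <- dv[dv != "unresolved"]
  if (length(pv) == 0 || length(dv) == 0)
    stop("both sides need at least one resolved call")
  x <- c(pv, dv) %in% c("ILS_HG", "ILS_PG")
  side <- rep(c(FALSE, TRUE), c(length(pv), length(dv)))
  delta_fun <- function(s) mean(x[s]) - mean(x[!s])
  obs <- delta_fun(side)
  n <- length(x)
  n_d <- sum(side)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    s <- rep(FALSE, n)
    s[sample.int(n, n_d)] <- TRUE
    if (abs(delta_fun(s)) >= abs(obs) - 1e-15) hits <- hits + 1L
  }
  list(delta = obs, p = (1 + hits) / (1 + n_perm),
       proximal = mean(x[!side]), distal = mean(x[side]))
}

#' Expected total discordance under the multispecies coalescent
#'
#' For a species triplet whose internal branch spans `tau` coalescent
#' units, each discordant topology has probability `exp(-tau) / 3`, so
#' total discordance is `(2/3) exp(-tau)`.
#'
#' @param tau internal branch length in coalescent units (>= 0).
#' @return probability in `[0, 2/3]`.
#' @examples
#' expected_discordance(1)  # 0.2452...
#' @export
expected_discordance <- function(tau) {
  if (any(tau < 0)) stop("tau must be >= 0")
  (2 / 3) * exp(-tau)
}

#' Binned ILS profile along a scanned chromosome
#'
#' @param calls call data.frame with window coordinates.
#' @param bin bin width in bp.
#' @return data.frame with one row per bin: coordinates, resolved and
#'   discordant counts, and the discordance proportion.
#' @export
ils_profile <- function(calls, bin = 100000) {
  stopifnot(all(c("start", "end", "call") %in% names(calls)))
  mid <- (calls$start + calls$end) / 2
  b <- floor(mid / bin)
  v <- as.character(calls$call)
  agg <- function(f) tapply(f, b, sum)
  res <- agg(v != "unresolved")
  ils <- agg(v %in% c("ILS_HG", "ILS_PG"))
  bins <- as.numeric(names(res))
  data.frame(start = bins * bin, end = (bins + 1) * bin,
             n_resolved = as.integer(res), n_ils = as.integer(ils),
             proportion = ifelse(res > 0, ils / res, NaN))
}
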