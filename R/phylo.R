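#' Pairwise distances from a window alignment
#'
#' Raw p-distance, Jukes-Cantor or Kimura-2-parameter distances with
#' pairwise deletion of sites containing gaps or ambiguity codes.  Under
#' JC, pairs with `p >= 0.75` are beyond the model's saturation point and
#' are reported as `Inf` (flagged with a warning).
#'
#' @param aln named character vector of equal-length aligned sequences.
#' @param model `"p"`, `"JC"` or `"K2P"`.
#' @return symmetric distance matrix with zero diagonal.
#' @examples
#' aln <- c(a = "ACGTACGTAC", b = "ACGTACGTAT")
#' pairwise_distance(aln, "JC")
#' @export
pairwise_distance <- function(aln, model = c("p", "JC", "K2P")) {
  model <- match.arg(model)
  if (length(aln) < 2) stop("need >= 2 sequences")
  if (length(unique(nchar(aln))) != 1)
    stop("sequences must have equal aligned length")
  m <- do.call(rbind, strsplit(tolower(aln), ""))
  rownames(m) <- names(aln)
  bin <- ape::as.DNAbin(m)
  # comparable-site count per pair (gap/N excluded pairwise)
  okm <- matrix(toupper(m) %in% DNA_BASES, nrow = nrow(m))
  comp <- okm %*% t(okm)
  if (any(comp[upper.tri(comp)] == 0))
    stop("a sequence pair shares no comparable (gap-free) sites")
  mdl <- c(p = "raw", JC = "JC69", K2P = "K80")[[model]]
  d <- suppressWarnings(
    as.matrix(ape::dist.dna(bin, model = mdl, pairwise.deletion = TRUE)))
  if (model == "JC") {
    praw <- as.matrix(ape::dist.dna(bin, model = "raw",
                                    pairwise.deletion = TRUE))
    sat <- praw >= 0.75
    if (any(sat[upper.tri(sat)])) {
      warning("p-distance >= 0.75: JC distance saturated, reported as Inf")
      d[sat] <- Inf
    }
  }
  d[is.nan(d)] <- Inf
  diag(d) <- 0
  d
}

#' Neighbor-joining tree
#'
#' Validated front end to the canonical neighbor-joining algorithm: on an
#' additive distance matrix the generating topology and branch lengths
#' are recovered exactly.
#'
#' @param dm symmetric distance matrix with zero diagonal and finite
#'   entries; at least 3 taxa.
#' @return unrooted `ape::phylo`.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need >= 3 taxa")
  if (any(!is.finite(dm))) stop("distance matrix contains NaN/Inf")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix not symmetric")
  ape::nj(dm)
}

# nontrivial bipartitions of an unrooted tree as canonical strings
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  labs <- sort(tree$tip.label)
  out <- character(0)
  for (node in setdiff(tree$edge[, 2], seq_len(ntip))) {
    tips <- ape::extract.clade(tree, node)$tip.label
    side <- labs %in% tips
    # canonical orientation: side not containing the first label
    if (side[1]) side <- !side
    if (sum(side) >= 2 && sum(!side) >= 2)
      out <- c(out, paste(labs[side], collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the bipartitions present in exactly one of the two unrooted
#' trees; the normalized variant divides by `2 (n - 3)`, the maximum for
#' two binary trees.
#'
#' @param t1,t2 `ape::phylo` objects with identical leaf sets.
#' @param normalized divide by the maximum attainable distance.
#' @return non-negative numeric.
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  if (normalized) {
    n <- length(t1$tip.label)
    if (n <= 3) stop("normalized RF undefined for n <= 3")
    rf <- rf / (2 * (n - 3))
  }
  rf
}

#' Co-phylogeny congruence permutation test
#'
#' Observed statistic: normalized Robinson-Foulds distance between the
#' trees.  The null distribution permutes the leaf labels of `t2`;
#' `p = (1 + #{perm <= observed}) / (1 + n_perm)`, the probability of a
#' topological match at least this close under random labelling.
#'
#' @param t1,t2 `ape::phylo` objects with identical leaf sets.
#' @param n_perm number of label permutations.
#' @param seed optional integer seed.
#' @return list with `distance` (normalized RF), `p`, and `n_perm`.
#' @export
cophylogeny_permutation_test <- function(t1, t2, n_perm = 10000,
                                         seed = NULL) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  if (n_perm < 100) warning("n_perm < 100: p-value resolution is coarse")
  if (!is.null(seed)) set.seed(seed)
  obs <- rf_distance(t1, t2, normalized = TRUE)
  hits <- 0L
  perm <- t2
  for (i in seq_len(n_perm)) {
    perm$tip.label <- sample(t2$tip.label)
    if (rf_distance(t1, perm, normalized = TRUE) <= obs) hits <- hits + 1L
  }
  list(distance = obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}

#' All resolved unrooted topologies over a taxon set
#'
#' @param taxa character vector of 4 or 5 tip labels.
#' @return list of unrooted `ape::phylo` objects (3 for quartets, 15 for
#'   quintets).
#' @export
candidate_topologies <- function(taxa) {
  n <- length(taxa)
  if (n < 4 || n > 5) stop("candidate enumeration supports 4-5 taxa")
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  lapply(trees, function(tr) { tr$edge.length <- NULL; tr })
}

#' Maximum-likelihood topology selection for small alignments
#'
#' Computes the HKY85 log-likelihood of each candidate topology by
#' Felsenstein pruning, optimizing branch lengths coordinate-wise
#' (golden-section per branch, up to `n_sweeps` sweeps, tolerance 1e-6),
#' and returns the best candidate.  Exact likelihood ties are broken by
#' candidate order and flagged.
#'
#' @param aln named character vector of aligned sequences (4-5 taxa), or
#'   an integer matrix in 0..3 coding with taxon rownames.
#' @param candidates list of candidate `phylo` topologies over the
#'   alignment's taxa; default all resolved unrooted topologies.
#' @param params an [hky_params()]; `base_freqs = NULL` uses empirical
#'   frequencies from the alignment.
#' @param n_sweeps optimisation sweeps over the branches.
#' @return list with `best` (phylo), `best_index`, `lnl` (per candidate),
#'   `delta_lnl` (best minus runner-up) and `tie` flag.
#' @export
best_topology_ml <- function(aln, candidates = NULL, params = hky_params(),
                             n_sweeps = 3) {
  mat <- if (is.matrix(aln)) aln else aln_to_int(aln)
  taxa <- rownames(mat)
  if (length(taxa) < 4 || length(taxa) > 5)
    stop("best_topology_ml supports 4-5 taxa")
  candidates <- candidates %||% candidate_topologies(taxa)
  freqs <- params$base_freqs %||% empirical_freqs(mat)
  rates <- model_rates(params)
  lnl <- vapply(candidates, function(tr) {
    enc <- phylo_to_parent(tr, taxa)
    fit <- cpp_hky_fit(mat, enc$parent, enc$leafrow, freqs, params$kappa,
                       rates, as.integer(n_sweeps), 1e-6, 4.0, 0.05)
    fit$lnl
  }, 0)
  if (any(!is.finite(lnl))) stop("non-finite log-likelihood")
  best <- which.max(lnl)
  srt <- sort(lnl, decreasing = TRUE)
  delta <- if (length(srt) > 1) srt[1] - srt[2] else Inf
  tie <- is.finite(delta) && delta < 1e-9
  if (tie) best <- which(lnl >= max(lnl) - 1e-9)[1]
  list(best = candidates[[best]], best_index = best, lnl = lnl,
       delta_lnl = delta, tie = tie)
}

empirical_freqs <- function(mat, pseudo = 1) {
  f <- tabulate(mat + 1L, nbins = 4) + pseudo
  f / sum(f)
}

#' Root a tree with an outgroup, balancing the root under a clock
#'
#' Standard outgroup rooting places the root at the outgroup's attachment
#' node, leaving the entire outgroup path on one side; under a molecular
#' clock the root lies somewhere along that edge.  With `clock = TRUE`
#' the root position is chosen so that the mean root-to-tip depth of the
#' ingroup equals the root-to-outgroup depth, which is what strict-clock
#' dating assumes.
#'
#' @param tree unrooted (or arbitrarily rooted) `ape::phylo`.
#' @param outgroup outgroup tip label.
#' @param clock balance the root position on the outgroup edge.
#' @return rooted `ape::phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup, clock = TRUE) {
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (!clock || is.null(tr$edge.length)) return(tr)
  ntip <- length(tr$tip.label)
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])
  kids_e <- which(tr$edge[, 1] == root)
  if (length(kids_e) != 2) return(tr)
  og <- which(tr$tip.label == outgroup)
  clade_tips <- function(node) {
    if (node <= ntip) return(node)
    which(tr$tip.label %in% ape::extract.clade(tr, node)$tip.label)
  }
  has_og <- vapply(kids_e, function(e) og %in% clade_tips(tr$edge[e, 2]),
                   TRUE)
  e_og <- kids_e[has_og]
  e_in <- kids_e[!has_og]
  if (length(e_og) != 1) return(tr)
  total <- sum(tr$edge.length[kids_e])
  dn <- ape::dist.nodes(tr)
  d_in <- mean(dn[tr$edge[e_in, 2], setdiff(seq_len(ntip), og)])
  d_og <- if (tr$edge[e_og, 2] == og) 0 else dn[tr$edge[e_og, 2], og]
  new_og <- min(max((total + d_in - d_og) / 2, 0), total)
  tr$edge.length[e_og] <- new_og
  tr$edge.length[e_in] <- total - new_og
  tr
}

#' Strict-clock least-squares node dating
#'
#' Fits a single substitution rate by least squares through the origin,
#' regressing the mean node-to-tip path length of the calibrated nodes on
#' their calibration ages, then converts every internal node's mean depth
#' into an age.  Confidence intervals, when an alignment is supplied,
#' come from a nonparametric bootstrap over alignment columns with the
#' tree re-estimated (neighbor joining on the chosen distance) per
#' replicate.
#'
#' @param tree rooted `ape::phylo` with branch lengths in
#'   substitutions/site.
#' @param calibrations list of `list(tips = c(...), age = <mya>)`
#'   entries; each calibrates the MRCA of `tips`.
#' @param aln optional alignment (named character vector) for bootstrap
#'   CIs.
#' @param outgroup outgroup label used to root bootstrap trees.
#' @param model distance model for bootstrap re-estimation.
#' @param n_boot bootstrap replicates (0 disables CIs).
#' @param conf CI level.
#' @param seed optional integer seed.
#' @return data.frame with one row per internal node: `node`, `age`,
#'   `ci_low`, `ci_high`, plus attribute `rate` (subs/site/mya).
#' @export
strict_clock_dating <- function(tree, calibrations, aln = NULL,
                                outgroup = NULL, model = "JC",
                                n_boot = 1000, conf = 0.95, seed = NULL) {
  if (length(calibrations) == 0) stop("need >= 1 calibration")
  if (!is.null(seed)) set.seed(seed)
  ages_of <- function(tr) {
    ntip <- length(tr$tip.label)
    dn <- ape::dist.nodes(tr)
    nodes <- (ntip + 1):(ntip + tr$Nnode)
    depth <- vapply(nodes, function(nd) {
      tips <- which(tr$tip.label %in% ape::extract.clade(tr, nd)$tip.label)
      mean(dn[nd, tips])
    }, 0)
    names(depth) <- nodes
    cal_nodes <- vapply(calibrations, function(cl)
      ape::getMRCA(tr, cl$tips), 0L)
    cal_ages <- vapply(calibrations, function(cl) cl$age, 0)
    cal_depth <- depth[as.character(cal_nodes)]
    if (any(cal_depth <= 0)) stop("calibration at a zero-depth node")
    rate <- sum(cal_depth * cal_ages) / sum(cal_ages^2)
    list(ages = depth / rate, rate = rate, nodes = nodes)
  }
  est <- ages_of(tree)
  out <- data.frame(node = est$nodes, age = unname(est$ages),
                    ci_low = NA_real_, ci_high = NA_real_)
  if (!is.null(aln) && n_boot > 0) {
    mat <- do.call(rbind, strsplit(aln, ""))
    rownames(mat) <- names(aln)
    L <- ncol(mat)
    boots <- matrix(NA_real_, n_boot, length(est$nodes))
    for (b in seq_len(n_boot)) {
      cols <- sample.int(L, L, replace = TRUE)
      baln <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      d <- pairwise_distance(baln, model)
      tr <- nj_tree(d)
      if (!is.null(outgroup))
        tr <- root_with_outgroup(tr, outgroup)
      bt <- tryCatch(ages_of(tr), error = function(e) NULL)
      if (is.null(bt)) next
      # match bootstrap nodes to original nodes by clade membership
      orig_clades <- lapply(est$nodes, function(nd)
        sort(ape::extract.clade(tree, nd)$tip.label))
      bt_clades <- lapply(bt$nodes, function(nd)
        sort(ape::extract.clade(tr, nd)$tip.label))
      for (j in seq_along(orig_clades)) {
        hit <- which(vapply(bt_clades, identical, TRUE, orig_clades[[j]]))
        if (length(hit) == 1) boots[b, j] <- bt$ages[hit]
      }
    }
    alpha <- (1 - conf) / 2
    out$ci_low <- apply(boots, 2, quantile, probs = alpha, na.rm = TRUE)
    out$ci_high <- apply(boots, 2, quantile, probs = 1 - alpha,
                         na.rm = TRUE)
  }
  attr(out, "rate") <- est$rate
  out
}
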