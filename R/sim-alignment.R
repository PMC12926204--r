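# phylo -> node encoding for the C++ engine: nodes renumbered so the root
# is first and every parent precedes its children; 0-based indices.
phylo_to_parent <- function(tr, taxa = tr$tip.label) {
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  root <- setdiff(unique(tr$edge[, 1]), tr$edge[, 2])
  kids <- split(tr$edge[, 2], factor(tr$edge[, 1], levels = seq_len(nn)))
  ord <- integer(0)
  queue <- root
  while (length(queue)) {
    x <- queue[1]
    queue <- c(queue[-1], kids[[x]])
    ord <- c(ord, x)
  }
  newid <- integer(nn)
  newid[ord] <- seq_along(ord)
  parent <- rep(-1L, nn)
  elen <- numeric(nn)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- newid[tr$edge[e, 2]]
    parent[ch] <- newid[tr$edge[e, 1]] - 1L
    elen[ch] <- if (is.null(tr$edge.length)) 0 else tr$edge.length[e]
  }
  leafrow <- rep(-1L, nn)
  leafrow[newid[seq_len(ntip)]] <- match(tr$tip.label, taxa) - 1L
  if (anyNA(leafrow)) stop("tree tips not covered by 'taxa'")
  list(parent = parent, elen = elen, leafrow = leafrow, ntip = ntip)
}

#' Simulate a gap-free alignment along a gene tree under HKY85
#'
#' One ungapped sequence per leaf, evolved site-independently under the
#' HKY85 model; optional gamma rate heterogeneity draws one rate per site
#' from the discrete-gamma distribution of `params`.  Branch lengths are
#' expected substitutions per site.
#'
#' @param gene_tree a rooted `ape::phylo` with non-negative branch lengths.
#' @param params an [hky_params()] object.
#' @param length alignment length in bp (>= 1).
#' @param seed optional integer seed.
#' @return named character vector (one sequence per leaf), the
#'   window-alignment representation used throughout the package.
#' @examples
#' tr <- ape::read.tree(text = "((A:0.05,B:0.05):0.02,C:0.07);")
#' aln <- simulate_alignment(tr, hky_params(), length = 100, seed = 1)
#' @export
simulate_alignment <- function(gene_tree, params = hky_params(), length,
                               seed = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), length >= 1)
  if (!is.null(gene_tree$edge.length) && any(gene_tree$edge.length < 0))
    stop("negative branch lengths")
  if (!is.null(seed)) set.seed(seed)
  enc <- phylo_to_parent(gene_tree)
  leaf_node <- matrix(which(enc$leafrow >= 0)[order(enc$leafrow[enc$leafrow >= 0])] - 1L,
                      ncol = 1)
  site_rates <- NULL
  if (!is.null(params$gamma_shape)) {
    r <- model_rates(params)
    site_rates <- sample(r, length, replace = TRUE)
  }
  sim <- cpp_sim_hky_batch(matrix(enc$parent, ncol = 1),
                           matrix(enc$elen, ncol = 1), leaf_node,
                           as.integer(length), params$base_freqs,
                           params$kappa, site_rates)[[1]]
  out <- apply(sim, 1, int_to_dna)
  names(out) <- gene_tree$tip.label
  out
}

#' Discordance-gradient specification for window panels
#'
#' Describes the breakpoint-polarized pattern the scan is designed to
#' detect: a background gene-tree discordance probability everywhere,
#' multiplied by `flank_fold` in the `flank_span` bp immediately distal to
#' the breakpoint.
#'
#' @param breakpoint coordinate (bp) of the polarity switch on the
#'   simulated chromosome.
#' @param background_discordance total discordance probability away from
#'   the elevated flank, in `[0, 2/3]`.
#' @param flank_fold multiplier applied distal to the breakpoint.
#' @param flank_span width (bp) of the elevated flank.
#' @return an object of class `ils_gradient_spec`.
#' @export
ils_gradient_spec <- function(breakpoint, background_discordance = 0.365,
                              flank_fold = 1.39, flank_span = Inf) {
  if (background_discordance < 0 || background_discordance > 1)
    stop("background_discordance must lie in [0, 1]")
  p_hi <- background_discordance * flank_fold
  if (p_hi > 1) stop("background_discordance * flank_fold exceeds 1")
  if (p_hi > 2 / 3 + 1e-12 || background_discordance > 2 / 3 + 1e-12)
    stop("the multispecies coalescent caps total discordance at 2/3; ",
         "requested ", signif(max(p_hi, background_discordance), 4))
  structure(list(breakpoint = breakpoint,
                 background_discordance = background_discordance,
                 flank_fold = flank_fold, flank_span = flank_span),
            class = "ils_gradient_spec")
}

#' Simulate a panel of orthologous windows with a discordance gradient
#'
#' Tiles a synthetic chromosome with consecutive `window_len` bp windows.
#' Each window's genealogy is drawn from the multispecies coalescent for
#' the (H, Pan, G, outgroup) quartet of `tree_spec`, with the Homo-Pan
#' ancestral branch rescaled per window so that the target total
#' discordance equals `background_discordance` proximal to the breakpoint
#' and `background * flank_fold` within the distal flank.  The recorded
#' truth label is the realised gene-tree triplet topology, so realised
#' discordance is binomial around the target.
#'
#' @param tree_spec a [species_tree_spec()] containing the four mapped
#'   taxa.
#' @param gradient an [ils_gradient_spec()].
#' @param n_windows number of windows (>= 1).
#' @param window_len window length in bp.
#' @param seed optional integer seed.
#' @param params an [hky_params()] for sequence simulation.
#' @param taxon_map mapping of scan roles to tip labels,
#'   see [default_taxon_map()].
#' @param as_matrix return alignments as integer matrices (A,C,G,T =
#'   0..3) instead of character vectors; avoids conversion overhead in
#'   large scans.
#' @return list with elements `windows` (interval data.frame),
#'   `alignments` (list of window alignments), `truth` (character vector
#'   of realised topology labels) and `target_p` (per-window target
#'   discordance).
#' @export
simulate_window_panel <- function(tree_spec, gradient, n_windows,
                                  window_len = 500, seed = NULL,
                                  params = hky_params(),
                                  taxon_map = default_taxon_map(),
                                  as_matrix = FALSE) {
  stopifnot(inherits(gradient, "ils_gradient_spec"), n_windows >= 1)
  if (!is.null(seed)) set.seed(seed)
  proj <- project_quartet(tree_spec, taxon_map)
  chrom_len <- n_windows * window_len
  if (gradient$breakpoint < 0 || gradient$breakpoint > chrom_len)
    stop("breakpoint outside the simulated chromosome [0, ", chrom_len, "]")
  starts <- (seq_len(n_windows) - 1) * window_len
  mid <- starts + window_len / 2
  distal <- mid > gradient$breakpoint &
    mid <= gradient$breakpoint + gradient$flank_span
  p <- ifelse(distal, gradient$background_discordance * gradient$flank_fold,
              gradient$background_discordance)
  # (2/3) exp(-tau) = p  =>  tau = -log(3 p / 2)
  tau <- ifelse(p > 0, -log(1.5 * p), Inf)
  dt_gen <- proj$g2 - proj$g1
  ne_hp <- ifelse(is.finite(tau), dt_gen / (2 * pmax(tau, 1e-12)), 0)
  gen <- msc_sample_quartets(n_windows, proj, ne_hp = ne_hp)
  leaf_node <- matrix(rep(3:6, n_windows), nrow = 4)
  sims <- cpp_sim_hky_batch(gen$parent, gen$elen, leaf_node,
                            as.integer(window_len), params$base_freqs,
                            params$kappa, NULL)
  taxa <- unlist(taxon_map[c("H", "P", "G", "outgroup")])
  alns <- lapply(sims, function(m) {
    rownames(m) <- taxa
    if (as_matrix) m else {
      out <- apply(m, 1, int_to_dna)
      names(out) <- taxa
      out
    }
  })
  list(windows = genomic_interval("chrS", starts, starts + window_len),
       alignments = alns, truth = gen$label, target_p = p)
}
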