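#' Species tree specification for coalescent simulation
#'
#' Describes a rooted species tree with absolute split times (years),
#' per-branch diploid effective population sizes, a generation time and a
#' per-site per-generation mutation rate.  Internal nodes of `topology`
#' must carry labels so that `split_times` and `ancestral_ne` can refer to
#' them; `ancestral_ne` names branches by the node (or tip) at their lower
#' end.
#'
#' Within an internal branch spanning `dt` years, the scaled length in
#' coalescent units is `tau = dt / generation_time / (2 * Ne)`; for a
#' species triplet with internal branch `tau`, the multispecies coalescent
#' gives each discordant gene-tree topology probability `exp(-tau) / 3`.
#'
#' @param topology Newick string (or `phylo`) with labelled internal nodes.
#' @param split_times named numeric vector, years before present per
#'   internal node label; must strictly decrease toward the leaves.
#' @param ancestral_ne named numeric vector of diploid effective sizes,
#'   one per tip and internal node label (the branch above that node).
#' @param generation_time years per generation.
#' @param mutation_rate substitutions per site per generation.
#' @return an object of class `species_tree_spec`.
#' @seealso [great_ape_tree_spec()], [sample_gene_tree()]
#' @export
species_tree_spec <- function(topology, split_times, ancestral_ne,
                              generation_time, mutation_rate) {
  tr <- if (inherits(topology, "phylo")) topology else
    ape::read.tree(text = topology)
  if (is.null(tr$node.label) || any(!nzchar(tr$node.label)))
    stop("all internal nodes must be labelled")
  labs <- c(tr$tip.label, tr$node.label)
  if (anyDuplicated(labs)) stop("duplicate node labels")
  if (!setequal(names(split_times), tr$node.label))
    stop("split_times must name every internal node")
  if (!all(labs %in% names(ancestral_ne)))
    stop("ancestral_ne must name every tip and internal node")
  if (any(ancestral_ne <= 0)) stop("all Ne must be > 0")
  if (mutation_rate <= 0) stop("mutation_rate must be > 0")
  if (generation_time <= 0) stop("generation_time must be > 0")
  ntip <- length(tr$tip.label)
  node_time <- c(rep(0, ntip), split_times[tr$node.label])
  for (e in seq_len(nrow(tr$edge))) {
    up <- tr$edge[e, 1]; dn <- tr$edge[e, 2]
    if (node_time[up] <= node_time[dn])
      stop("split times must strictly decrease toward the leaves ",
           "(non-ultrametric or inverted ages)")
  }
  structure(list(tree = tr, split_times = split_times,
                 ancestral_ne = ancestral_ne,
                 generation_time = generation_time,
                 mutation_rate = mutation_rate,
                 node_time = node_time),
            class = "species_tree_spec")
}

#' @export
print.species_tree_spec <- function(x, ...) {
  cat("species_tree_spec:", ape::write.tree(x$tree), "\n")
  cat(sprintf("  splits (Mya): %s\n",
              paste(sprintf("%s=%.2f", names(x$split_times),
                            x$split_times / 1e6), collapse = ", ")))
  cat(sprintf("  generation time %g y, mutation rate %g /site/gen\n",
              x$generation_time, x$mutation_rate))
  invisible(x)
}

#' Default great-ape species tree
#'
#' Five taxa (human, chimpanzee, bonobo, gorilla, orangutan) with splits
#' at 2.5, 7, 9.1 and 16.5 Mya, a 20-year generation time, mutation rate
#' 1.25e-8 per site per generation, and large ancestral effective sizes
#' in the Homo-Pan and African-ape ancestors, which is what makes
#' incomplete lineage sorting common around the fusion site.
#'
#' @param taxa either `5` (default, includes bonobo) or `4` (chimpanzee
#'   as the single Pan representative).
#' @return a [species_tree_spec()].
#' @export
great_ape_tree_spec <- function(taxa = 5) {
  if (taxa == 5) {
    species_tree_spec(
      "(((human,(chimpanzee,bonobo)pan)hp,gorilla)hpg,orangutan)root;",
      split_times = c(pan = 2.5e6, hp = 7e6, hpg = 9.1e6, root = 16.5e6),
      ancestral_ne = c(human = 15000, chimpanzee = 25000, bonobo = 15000,
                       gorilla = 25000, orangutan = 25000, pan = 30000,
                       hp = 65000, hpg = 80000, root = 100000),
      generation_time = 20, mutation_rate = 1.25e-8)
  } else if (taxa == 4) {
    species_tree_spec(
      "(((human,chimpanzee)hp,gorilla)hpg,orangutan)root;",
      split_times = c(hp = 7e6, hpg = 9.1e6, root = 16.5e6),
      ancestral_ne = c(human = 15000, chimpanzee = 25000, gorilla = 25000,
                       orangutan = 25000, hp = 65000, hpg = 80000,
                       root = 100000),
      generation_time = 20, mutation_rate = 1.25e-8)
  } else stop("taxa must be 4 or 5")
}

#' Benchmark species tree for windowed-scan calibration
#'
#' A 4-taxon (human, chimpanzee, gorilla, orangutan) tree used to
#' calibrate the window scan against closed-form coalescent expectations.
#' The internal Homo-Pan branch is parameterised directly by `tau`
#' (coalescent units), and the remaining parameters are chosen so that
#' the per-window maximum-likelihood call tracks the true genealogy:
#' the mutation rate is elevated to 1e-7 per site per generation (at
#' realistic hominid rates a 500 bp window holds about one informative
#' site and most windows cannot be classified, so the scan would measure
#' resolution rate rather than coalescent recovery), and the
#' African-ape-ancestor population is large (3e5) so that gene-tree
#' internal branches — the signal the classifier reads — are rarely near
#' zero.  Use [ils_benchmark_params()] for the matching substitution
#' model in simulation and scanning.
#'
#' @param tau internal-branch length in coalescent units
#'   (`delta_generations / (2 Ne)`); total discordance under the MSC is
#'   `(2/3) exp(-tau)`.
#' @param mutation_rate substitutions per site per generation.
#' @param ne_ancestral diploid Ne of the African-ape ancestral branch.
#' @return a [species_tree_spec()].
#' @export
ils_benchmark_spec <- function(tau = 1, mutation_rate = 1e-7,
                               ne_ancestral = 3e5) {
  stopifnot(tau >= 0)
  gen <- 20
  dt_gen <- (9.1e6 - 7e6) / gen
  ne_hp <- if (tau == 0) 1e12 else dt_gen / (2 * tau)
  species_tree_spec(
    "(((human,chimpanzee)hp,gorilla)hpg,orangutan)root;",
    split_times = c(hp = 7e6, hpg = 9.1e6, root = 16.5e6),
    ancestral_ne = c(human = 15000, chimpanzee = 15000, gorilla = 15000,
                     orangutan = 15000, hp = ne_hp, hpg = ne_ancestral,
                     root = 100000),
    generation_time = gen, mutation_rate = mutation_rate)
}

#' Substitution model for the windowed-scan benchmark
#'
#' Equal-frequency, kappa = 1 parameters (the Jukes-Cantor special case
#' of HKY85) used for both simulating and scanning benchmark panels:
#' spreading mutations evenly over substitution targets minimises
#' homoplasic convergence, which would otherwise bias topology calls
#' toward the uniform 1/3 mixture.
#'
#' @return an [hky_params()] object.
#' @export
ils_benchmark_params <- function() {
  hky_params(kappa = 1, base_freqs = rep(0.25, 4))
}

#' Coalescent-unit length of an internal branch
#'
#' `tau = delta_t_generations / (2 Ne)` for the branch above the named
#' internal node.
#'
#' @param spec a [species_tree_spec()].
#' @param node internal node label.
#' @return numeric scalar.
#' @export
coalescent_tau <- function(spec, node) {
  tr <- spec$tree
  ntip <- length(tr$tip.label)
  idx <- ntip + match(node, tr$node.label)
  if (is.na(idx)) stop("unknown internal node: ", node)
  par <- tr$edge[tr$edge[, 2] == idx, 1]
  if (length(par) == 0) stop("node ", node, " is the root; tau undefined")
  dt <- (spec$node_time[par] - spec$node_time[idx]) / spec$generation_time
  unname(dt / (2 * spec$ancestral_ne[[node]]))
}

# project a spec onto the (H, Pan, G, outgroup) quartet used by the scan:
# generation-scaled split times and branch Ne values
project_quartet <- function(spec, taxon_map = default_taxon_map()) {
  tr <- spec$tree
  need <- unlist(taxon_map[c("H", "P", "G", "outgroup")])
  if (!all(need %in% tr$tip.label))
    stop("taxon_map names missing from species tree: ",
         paste(setdiff(need, tr$tip.label), collapse = ", "))
  gt <- spec$generation_time
  mrca_time <- function(tips) {
    n <- ape::getMRCA(tr, tips)
    spec$node_time[n]
  }
  mrca_label <- function(tips) {
    n <- ape::getMRCA(tr, tips)
    tr$node.label[n - length(tr$tip.label)]
  }
  hp_lab <- mrca_label(c(taxon_map$H, taxon_map$P))
  hpg_lab <- mrca_label(c(taxon_map$H, taxon_map$G))
  ntip <- length(tr$tip.label)
  root_lab <- tr$node.label[setdiff(tr$edge[, 1], tr$edge[, 2]) - ntip]
  list(g1 = mrca_time(c(taxon_map$H, taxon_map$P)) / gt,
       g2 = mrca_time(c(taxon_map$H, taxon_map$G)) / gt,
       g3 = mrca_time(c(taxon_map$H, taxon_map$outgroup)) / gt,
       ne_hp = spec$ancestral_ne[[hp_lab]],
       ne_hpg = spec$ancestral_ne[[hpg_lab]],
       ne_root = spec$ancestral_ne[[root_lab]],
       mu = spec$mutation_rate)
}

#' Default taxon mapping for triplet classification
#'
#' Maps the scan roles H (human), P (the Pan representative), G (gorilla)
#' and outgroup to tip labels.  The Pan slot defaults to chimpanzee.
#'
#' @param H,P,G,outgroup tip labels.
#' @return named list.
#' @export
default_taxon_map <- function(H = "human", P = "chimpanzee", G = "gorilla",
                              outgroup = "orangutan") {
  list(H = H, P = P, G = G, outgroup = outgroup)
}
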