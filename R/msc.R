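#' Sample a gene tree under the multispecies coalescent
#'
#' Simulates one gene genealogy for a single haploid lineage per species,
#' coalescing lineages within species-tree branches at rate
#' `choose(k, 2) / (2 Ne)` per generation.  For a species triplet whose
#' internal branch has scaled length `tau` coalescent units, each of the
#' two discordant triplet topologies arises with probability
#' `exp(-tau) / 3`.
#'
#' @param spec a [species_tree_spec()].
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param units branch-length units of the returned tree:
#'   `"subs"` (expected substitutions per site, default) or
#'   `"generations"`.
#' @return a rooted `ape::phylo` with one tip per species.
#' @examples
#' tr <- sample_gene_tree(great_ape_tree_spec(), seed = 1)
#' @export
sample_gene_tree <- function(spec, seed = NULL, units = c("subs",
                                                          "generations")) {
  stopifnot(inherits(spec, "species_tree_spec"))
  units <- match.arg(units)
  if (!is.null(seed)) set.seed(seed)
  tr <- spec$tree
  ntip <- length(tr$tip.label)
  gt <- spec$generation_time
  node_gen <- spec$node_time / gt
  labs <- c(tr$tip.label, tr$node.label)
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])
  parent_of <- integer(ntip + tr$Nnode)
  parent_of[tr$edge[, 2]] <- tr$edge[, 1]
  kids <- split(tr$edge[, 2], factor(tr$edge[, 1], levels = seq_along(labs)))

  n_merge <- 0L
  m_a <- m_b <- integer(ntip - 1L)
  m_t <- numeric(ntip - 1L)
  lin_time <- numeric(2L * ntip - 1L)  # birth time (gen) of each lineage

  # returns lineage ids surviving to the top of the branch above node x
  run_branch <- function(x) {
    lin <- if (x <= ntip) x else
      unlist(lapply(kids[[x]], function(ch) run_branch(ch)))
    t0 <- node_gen[x]
    t1 <- if (x == root) Inf else node_gen[parent_of[x]]
    ne <- spec$ancestral_ne[[labs[x]]]
    t <- t0
    while (length(lin) >= 2) {
      k <- length(lin)
      t <- t + rexp(1) * 2 * ne / choose(k, 2)
      if (t >= t1) break
      pr <- sample.int(k, 2)
      n_merge <<- n_merge + 1L
      new_id <- ntip + n_merge
      m_a[n_merge] <<- lin[pr[1]]
      m_b[n_merge] <<- lin[pr[2]]
      m_t[n_merge] <<- t
      lin_time[new_id] <<- t
      lin <- c(lin[-pr], new_id)
    }
    lin
  }
  run_branch(root)
  stopifnot(n_merge == ntip - 1L)

  # ape phylo: internal ids ntip+1..2*ntip-1, root first by age
  ord <- order(m_t, decreasing = TRUE)           # merge index -> age rank
  ape_id <- integer(2L * ntip - 1L)
  ape_id[seq_len(ntip)] <- seq_len(ntip)
  ape_id[ntip + ord] <- ntip + seq_len(ntip - 1L)
  scale <- if (units == "subs") spec$mutation_rate else 1
  edge <- matrix(0L, 2L * (ntip - 1L), 2)
  elen <- numeric(nrow(edge))
  r <- 0L
  for (j in seq_len(n_merge)) {
    for (ch in c(m_a[j], m_b[j])) {
      r <- r + 1L
      edge[r, ] <- c(ape_id[ntip + j], ape_id[ch])
      elen[r] <- (m_t[j] - lin_time[ch]) * scale
    }
  }
  out <- list(edge = edge, edge.length = elen, tip.label = tr$tip.label,
              Nnode = ntip - 1L)
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

# Fast sampler for (H, P, G, outgroup) quartet genealogies; ne_hp may vary
# per replicate.  Returns encodings ready for cpp_sim_hky_batch plus the
# realised triplet topology label.  Uses the current RNG stream.
msc_sample_quartets <- function(n, proj, ne_hp = proj$ne_hp) {
  ne_hp <- rep_len(ne_hp, n)
  parent <- matrix(-1L, 7, n)
  elen <- matrix(0, 7, n)
  label <- character(n)
  g1 <- proj$g1; g2 <- proj$g2; g3 <- proj$g3
  mu <- proj$mu
  TRIP <- 7L  # mask of H|P|G
  for (w in seq_len(n)) {
    mk1 <- mk2 <- integer(3); mt <- numeric(3); k <- 0L
    # phase 1: H (1) and P (2) in the Homo-Pan ancestral branch
    lin <- c(1L, 2L)
    dt <- rexp(1) * 2 * ne_hp[w]
    if (g1 + dt < g2) {
      k <- 1L; mk1[1] <- 1L; mk2[1] <- 2L; mt[1] <- g1 + dt
      lin <- 3L
    }
    # phase 2: gorilla joins
    lin <- c(lin, 4L); t <- g2
    repeat {
      nk <- length(lin)
      if (nk < 2) break
      t2 <- t + rexp(1) * 2 * proj$ne_hpg / choose(nk, 2)
      if (t2 >= g3) break
      t <- t2
      pr <- sample.int(nk, 2)
      k <- k + 1L
      mk1[k] <- lin[pr[1]]; mk2[k] <- lin[pr[2]]; mt[k] <- t
      lin <- c(lin[-pr], bitwOr(lin[pr[1]], lin[pr[2]]))
    }
    # phase 3: outgroup joins at the root branch
    lin <- c(lin, 8L); t <- g3
    while (length(lin) >= 2) {
      nk <- length(lin)
      t <- t + rexp(1) * 2 * proj$ne_root / choose(nk, 2)
      pr <- sample.int(nk, 2)
      k <- k + 1L
      mk1[k] <- lin[pr[1]]; mk2[k] <- lin[pr[2]]; mt[k] <- t
      lin <- c(lin[-pr], bitwOr(lin[pr[1]], lin[pr[2]]))
    }
    # triplet label: first merge joining two clusters that both carry
    # members of {H, P, G}
    label[w] <- "concordant"
    for (j in 1:3) {
      b1 <- bitwAnd(mk1[j], TRIP); b2 <- bitwAnd(mk2[j], TRIP)
      if (b1 > 0L && b2 > 0L) {
        pairbits <- bitwOr(b1, b2)
        label[w] <- if (pairbits == 3L) "concordant"
                    else if (pairbits == 5L) "ILS_HG"
                    else "ILS_PG"
        break
      }
    }
    # node encoding: merges 1..3 -> indices 2,1,0 (root first); leaves
    # H,P,G,O -> 3,4,5,6 (0-based)
    mask_node <- integer(15)
    mask_node[c(1L, 2L, 4L, 8L)] <- 3:6
    birth <- numeric(7)
    for (j in 1:3) {
      idx <- 3L - j
      mask <- bitwOr(mk1[j], mk2[j])
      for (cm in c(mk1[j], mk2[j])) {
        ch <- mask_node[cm]
        parent[ch + 1L, w] <- idx
        elen[ch + 1L, w] <- (mt[j] - birth[ch + 1L]) * mu
      }
      if (j < 3) {
        mask_node[mask] <- idx
        birth[idx + 1L] <- mt[j]
      }
    }
  }
  list(parent = parent, elen = elen, label = label)
}
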