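test_that("pairwise distances invert the JC closed form", {
  aln <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  expect_equal(unname(pairwise_distance(aln, "p")[1, 2]), 0)
  # p = 0.0936 -> JC d ~ 0.1000
  set.seed(200)
  L <- 10000
  s1 <- random_dna(L)
  v <- strsplit(s1, "")[[1]]
  idx <- sample(L, round(0.0936 * L))
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  aln2 <- c(a = s1, b = paste(v, collapse = ""))
  d <- pairwise_distance(aln2, "JC")[1, 2]
  expect_equal(unname(d), -0.75 * log(1 - 4 * 0.0936 / 3),
               tolerance = 1e-9)
  expect_equal(unname(d), 0.1, tolerance = 2e-3)
})

test_that("saturated and incomparable pairs are handled", {
  sat <- c(a = strrep("A", 100), b = strrep("C", 100))
  expect_warning(d <- pairwise_distance(sat, "JC"), "saturated")
  expect_true(is.infinite(d[1, 2]))
  gaps <- c(a = "AC--", b = "--GT")
  expect_error(pairwise_distance(gaps), "comparable")
})

test_that("neighbor joining recovers additive trees exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:1,D:1):0);")
  dm <- ape::cophenetic.phylo(tr)
  out <- nj_tree(dm)
  expect_equal(rf_distance(out, tr), 0)
  tip_edge <- function(t) setNames(
    t$edge.length[match(seq_along(t$tip.label), t$edge[, 2])], t$tip.label)
  expect_equal(tip_edge(out)[c("A", "B", "C", "D")],
               c(A = 1, B = 2, C = 1, D = 1), tolerance = 1e-10)
  # internal edge length 1 (the two root-adjacent internal edges sum to 1)
  internal <- sum(out$edge.length) - sum(tip_edge(out))
  expect_equal(internal, 1, tolerance = 1e-10)
  set.seed(201)
  for (rep in 1:100) {
    t0 <- ape::rtree(sample(4:10, 1))
    t0$edge.length <- t0$edge.length + 0.1
    rec <- nj_tree(ape::cophenetic.phylo(t0))
    expect_equal(rf_distance(rec, t0), 0)
  }
})

test_that("nj handles 3 taxa and rejects bad matrices", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(dm)
  expect_equal(sort(unname(setNames(
    tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)[c("a", "b", "c")])),
    sort(c((3 + 4 - 5) / 2, (3 + 5 - 4) / 2, (4 + 5 - 3) / 2)))
  dm2 <- dm; dm2[1, 2] <- Inf; dm2[2, 1] <- Inf
  expect_error(nj_tree(dm2), "NaN/Inf")
})

test_that("nj output is invariant to taxon input order", {
  set.seed(202)
  t0 <- ape::rtree(8)
  t0$edge.length <- t0$edge.length + 0.05
  dm <- ape::cophenetic.phylo(t0)
  perm <- sample(rownames(dm))
  expect_equal(rf_distance(nj_tree(dm), nj_tree(dm[perm, perm])), 0)
})

test_that("RF distance counts conflicting bipartitions", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  expect_equal(rf_distance(t1, t2, normalized = TRUE), 1)
  expect_error(rf_distance(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "leaf sets")
  set.seed(203)
  for (rep in 1:150) {
    a <- ape::rtree(8)
    b <- ape::rtree(8)
    expect_equal(rf_distance(a, b),
                 as.numeric(phangorn::RF.dist(a, b)))
  }
})

test_that("window ML likelihoods agree with an independent implementation", {
  set.seed(204)
  tr <- ape::read.tree(text = "((H:0.05,P:0.07):0.03,(G:0.09,O:0.2):0.01);")
  aln <- simulate_alignment(tr, hky_params(kappa = 3,
                                           c(0.28, 0.22, 0.21, 0.29)),
                            length = 800)
  f <- c(0.28, 0.22, 0.21, 0.29)
  enc <- fusionscape:::phylo_to_parent(tr, names(aln))
  mine <- fusionscape:::cpp_hky_lnl(fusionscape:::aln_to_int(aln),
                                    enc$parent, enc$leafrow, enc$elen,
                                    f, 3, 1)
  pd <- phangorn::phyDat(t(sapply(aln, function(s) strsplit(s, "")[[1]])))
  fit <- phangorn::pml(tr, pd, bf = f, Q = c(1, 3, 1, 1, 3, 1))
  expect_equal(mine, as.numeric(stats::logLik(fit)), tolerance = 1e-6)
})

test_that("best_topology_ml selects the generating quartet", {
  set.seed(205)
  gen <- ape::read.tree(text = "((A:0.05,B:0.05):0.2,(C:0.05,D:0.05):0.2);")
  hits <- 0
  for (rep in 1:30) {
    aln <- simulate_alignment(gen, hky_params(), length = 600)
    best <- best_topology_ml(aln)
    if (rf_distance(best$best, gen) == 0) hits <- hits + 1
  }
  expect_gte(hits, 29)
})

test_that("zero internal branch gives symmetric weak support", {
  set.seed(206)
  gen <- ape::read.tree(text = "((A:0.08,B:0.08):0.0001,(C:0.08,D:0.08):0.0001);")
  picks <- integer(0)
  deltas <- numeric(0)
  for (rep in 1:60) {
    aln <- simulate_alignment(gen, hky_params(), length = 500)
    best <- best_topology_ml(aln)
    picks <- c(picks, best$best_index)
    deltas <- c(deltas, best$delta_lnl)
  }
  expect_lt(median(deltas), 3)
  expect_equal(length(unique(picks)), 3)  # all three appear
})

test_that("resolved-topology likelihood dominates the star tree", {
  set.seed(207)
  gen <- ape::read.tree(text = "((A:0.06,B:0.06):0.05,(C:0.06,D:0.06):0.05);")
  aln <- simulate_alignment(gen, hky_params(), length = 500)
  mat <- fusionscape:::aln_to_int(aln)
  best <- best_topology_ml(aln)
  star <- fusionscape:::cpp_hky_fit(
    mat, parent = c(-1L, 0L, 0L, 0L, 0L), leafrow = c(-1L, 0:3),
    freqs = fusionscape:::empirical_freqs(mat), kappa = 4, rates = 1,
    nsweeps = 3L, tol = 1e-6, tmax = 4, t_init = 0.05)
  expect_gte(max(best$lnl) + 1e-6, star$lnl)
})

test_that("cophylogeny permutation p behaves at its extremes", {
  set.seed(208)
  t1 <- ape::rtree(10)
  out <- cophylogeny_permutation_test(t1, t1, n_perm = 400)
  expect_equal(out$distance, 0)
  expect_equal(out$p, 1 / 401)
  # distances increase as trees diverge; identical tree attains min p
  nni <- phangorn::rNNI(t1, 1)
  rand <- ape::rtree(10)
  rand$tip.label <- sample(t1$tip.label)
  d_id <- rf_distance(t1, t1, normalized = TRUE)
  d_nni <- rf_distance(t1, nni, normalized = TRUE)
  d_rand <- rf_distance(t1, rand, normalized = TRUE)
  expect_lte(d_id, d_nni)
  expect_lte(d_nni, d_rand + 1e-12)
  expect_warning(cophylogeny_permutation_test(t1, t1, n_perm = 50),
                 "n_perm")
})

test_that("null permutation p-values are not anticonservative", {
  set.seed(209)
  t1 <- ape::rtree(8)
  ps <- replicate(40, {
    t2 <- t1
    t2$tip.label <- sample(t1$tip.label)
    cophylogeny_permutation_test(t1, t2, n_perm = 200)$p
  })
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps <= 0.05), 0.25)
})

test_that("strict-clock dating is exact on clocklike trees", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  out <- strict_clock_dating(tr, list(list(tips = c("A", "C"), age = 10)))
  expect_equal(out$age[out$node == 5], 10)   # root
  expect_equal(sort(out$age[out$node != 5]), c(5, 5))
  expect_equal(attr(out, "rate"), 0.2)       # depth 2 / age 10
  # two taxa: rate = d / (2 A)
  t2 <- ape::read.tree(text = "(A:0.1,B:0.1);")
  out2 <- strict_clock_dating(t2, list(list(tips = c("A", "B"), age = 5)))
  expect_equal(attr(out2, "rate"), 0.1 / 5)
  zero <- ape::read.tree(text = "((A:0,B:0):1,C:1);")
  expect_error(strict_clock_dating(
    zero, list(list(tips = c("A", "B"), age = 3))), "zero-depth")
})

test_that("dating recovers simulated ages within 10%", {
  set.seed(210)
  rate <- 0.01  # subs/site/mya; at 10 kbp the youngest node's depth is
                # then well above distance noise
  ages <- c(ab = 2, abc = 5, root = 10)
  tr <- ape::read.tree(text = sprintf(
    "(((A:%f,B:%f):%f,C:%f):%f,O:%f);",
    2 * rate, 2 * rate, 3 * rate, 5 * rate, 5 * rate, 10 * rate))
  errs <- replicate(8, {
    aln <- simulate_alignment(tr, hky_params(kappa = 1, rep(0.25, 4)),
                              length = 10000)
    d <- pairwise_distance(aln, "JC")
    est <- root_with_outgroup(nj_tree(d), "O")
    out <- strict_clock_dating(est, list(list(tips = c("A", "O"),
                                              age = 10)))
    clade_age <- function(tips) {
      nd <- ape::getMRCA(est, tips)
      out$age[out$node == nd]
    }
    c(abs(clade_age(c("A", "B")) - 2) / 2,
      abs(clade_age(c("A", "C")) - 5) / 5)
  })
  expect_lt(median(errs), 0.1)
})

test_that("candidate topology enumeration is complete", {
  expect_length(candidate_topologies(letters[1:4]), 3)
  expect_length(candidate_topologies(letters[1:5]), 15)
  expect_error(candidate_topologies(letters[1:6]), "4-5")
})
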