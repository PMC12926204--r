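test_that("species tree specs validate split times and rates", {
  expect_error(species_tree_spec(
    "((a,b)x,c)r;", split_times = c(x = 5e6, r = 4e6),
    ancestral_ne = c(a = 1e4, b = 1e4, c = 1e4, x = 1e4, r = 1e4),
    generation_time = 20, mutation_rate = 1e-8), "decrease")
  expect_error(species_tree_spec(
    "((a,b)x,c)r;", split_times = c(x = 4e6, r = 5e6),
    ancestral_ne = c(a = 1e4, b = 1e4, c = 1e4, x = -1, r = 1e4),
    generation_time = 20, mutation_rate = 1e-8), "Ne")
  expect_error(species_tree_spec(
    "((a,b)x,c)r;", split_times = c(x = 4e6, r = 5e6),
    ancestral_ne = c(a = 1e4, b = 1e4, c = 1e4, x = 1e4, r = 1e4),
    generation_time = 20, mutation_rate = 0), "mutation_rate")
  expect_equal(coalescent_tau(ils_benchmark_spec(tau = 0.37), "hp"), 0.37)
})

test_that("HKY transition probabilities match the matrix exponential", {
  f <- c(0.3, 0.2, 0.2, 0.3)
  kap <- 4
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j) {
    ts <- (i == 1 && j == 3) || (i == 3 && j == 1) ||
      (i == 2 && j == 4) || (i == 4 && j == 2)
    Q[i, j] <- f[j] * ifelse(ts, kap, 1)
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-f * diag(Q))  # normalise to one expected sub per unit t
  for (t in c(0, 0.05, 0.37, 2)) {
    P <- unname(hky_pmatrix(t, hky_params(kap, f)))
    expect_equal(P, as.matrix(Matrix::expm(Q * t)), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
  }
})

test_that("gene-tree topology frequencies follow the coalescent closed form", {
  tm <- default_taxon_map()
  set.seed(4001)
  n <- 10000
  for (tau in c(0, 0.25, 0.5, 1, 2)) {
    spec <- ils_benchmark_spec(tau = tau)
    labs <- vapply(seq_len(n), function(i)
      classify_topology(sample_gene_tree(spec), tm), "")
    p_each <- exp(-tau) / 3
    sigma <- sqrt(p_each * (1 - p_each) / n)
    expect_lt(abs(mean(labs == "ILS_HG") - p_each), 3 * sigma + 1e-9)
    expect_lt(abs(mean(labs == "ILS_PG") - p_each), 3 * sigma + 1e-9)
  }
})

test_that("huge ancestral Ne gap removes discordance entirely", {
  spec <- ils_benchmark_spec(tau = 20)
  set.seed(4002)
  labs <- vapply(1:300, function(i)
    classify_topology(sample_gene_tree(spec), default_taxon_map()), "")
  expect_true(all(labs == "concordant"))
})

test_that("fast quartet sampler agrees with the generic MSC sampler", {
  spec <- ils_benchmark_spec(tau = 0.5)
  proj <- fusionscape:::project_quartet(spec)
  set.seed(4003)
  fast <- fusionscape:::msc_sample_quartets(6000, proj)
  p_fast <- mean(fast$label != "concordant")
  p_exp <- expected_discordance(0.5)
  expect_lt(abs(p_fast - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 6000))
  # branch lengths are positive and trees are ultrametric in expectation
  expect_true(all(fast$elen[-1, ] >= 0))
})

test_that("sampler matches an independent coalescent simulator (msprime)", {
  spec <- ils_benchmark_spec(tau = 0.5)
  proj <- fusionscape:::project_quartet(spec)
  nrep <- 3000
  py <- sprintf(
    'import msprime
d = msprime.Demography()
for p in ["H","P","G"]:
    d.add_population(name=p, initial_size=1000)
d.add_population(name="HP", initial_size=%f)
d.add_population(name="HPG", initial_size=%f)
d.add_population_split(time=%f, derived=["H","P"], ancestral="HP")
d.add_population_split(time=%f, derived=["HP","G"], ancestral="HPG")
disc = 0
n = %d
for ts in msprime.sim_ancestry({"H":1,"P":1,"G":1}, demography=d,
                               ploidy=1, num_replicates=n, random_seed=7):
    t = ts.first()
    r = t.root
    for c in t.children(r):
        if t.num_samples(c) == 2:
            pair = sorted(t.population(u) for u in t.samples(c))
            if pair != [0, 1]:
                disc += 1
print(disc / n)',
    # msprime haploid coalescence rate is 1/N, ours is 1/(2 Ne diploid)
    2 * proj$ne_hp, 2 * proj$ne_hpg, proj$g1, proj$g2, nrep)
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  p_msprime <- as.numeric(tail(out, 1))
  set.seed(4004)
  mine <- fusionscape:::msc_sample_quartets(nrep, proj)
  p_mine <- mean(mine$label != "concordant")
  p0 <- expected_discordance(0.5)
  sigma <- sqrt(p0 * (1 - p0) / nrep)
  expect_lt(abs(p_msprime - p_mine), 4.5 * sigma)
  expect_lt(abs(p_msprime - p0), 3 * sigma)
})

test_that("gene trees are reproducible given a seed", {
  spec <- great_ape_tree_spec()
  t1 <- sample_gene_tree(spec, seed = 42)
  t2 <- sample_gene_tree(spec, seed = 42)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("simulated alignments match closed-form sequence divergence", {
  # two taxa, path length 0.1 under kappa=1/uniform: Jukes-Cantor
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  aln <- simulate_alignment(tr, hky_params(kappa = 1, rep(0.25, 4)),
                            length = 1e5, seed = 5)
  p_obs <- mean(strsplit(aln[1], "")[[1]] != strsplit(aln[2], "")[[1]])
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 1e5))
  # zero-length tree: identical sequences
  tr0 <- ape::read.tree(text = "(A:0,B:0);")
  aln0 <- simulate_alignment(tr0, length = 500, seed = 6)
  expect_identical(aln0[[1]], aln0[[2]])
  trneg <- ape::read.tree(text = "(A:-0.1,B:0.05);")
  expect_error(simulate_alignment(trneg, length = 10), "negative")
})

test_that("gamma heterogeneity limits behave correctly", {
  expect_null(hky_params(gamma_shape = Inf)$gamma_shape)
  r <- fusionscape:::discrete_gamma_rates(0.5, 4)
  expect_equal(mean(r), 1, tolerance = 1e-8)
  expect_gt(var(r), 0.5)
  r_big <- fusionscape:::discrete_gamma_rates(1e6, 4)
  expect_lt(var(r_big), 1e-5)  # shape -> Inf: rate variance -> 0
})

test_that("window panels tile the chromosome and hit target discordance", {
  spec <- ils_benchmark_spec(tau = 1)
  one <- simulate_window_panel(spec,
                               ils_gradient_spec(0, 0.3, 1), 1, seed = 7)
  expect_equal(nrow(one$windows), 1)
  expect_length(one$truth, 1)
  pan <- simulate_window_panel(spec, ils_gradient_spec(2e5, 0.365, 1.39,
                                                       flank_span = Inf),
                               n_windows = 5000, seed = 8,
                               as_matrix = TRUE)
  expect_equal(pan$windows$start, (0:4999) * 500)
  expect_equal(pan$windows$end, (1:5000) * 500)
  distal <- pan$windows$start >= 2e5
  p_hi <- 0.365 * 1.39
  expect_lt(abs(mean(pan$truth[distal] != "concordant") - p_hi),
            3 * sqrt(p_hi * (1 - p_hi) / sum(distal)))
  expect_error(ils_gradient_spec(0, 0.9, 1.2), "exceeds 1")
  expect_error(ils_gradient_spec(0, 0.5, 1.4), "2/3")
})

test_that("satellite chromosomes carry a consistent truth partition", {
  mono <- DEFAULT_SATELLITE_MONOMER
  pristine <- simulate_satellite_chromosome(
    satellite_spec(array_lengths = 320, divergence = 0), seed = 9)
  expect_identical(pristine$seq, strrep(mono, 10))
  expect_equal(nrow(pristine$truth), 1)
  expect_equal(interval_length(pristine$truth), 320)

  sim <- simulate_satellite_chromosome(
    satellite_spec(array_lengths = rep(20000, 4), spacer_mode = 3000,
                   spacer_spread = 200), seed = 10)
  tr <- sim$truth
  expect_equal(tr$start[-1], tr$end[-nrow(tr)])  # partition: no gaps
  expect_equal(tr$start[1], 0)
  expect_equal(tr$end[nrow(tr)], nchar(sim$seq))
  expect_error(satellite_spec(array_lengths = numeric(0)), "array")
})

test_that("spacer spacing is 287 kbp by construction at the Pan layout", {
  sim <- simulate_satellite_chromosome(
    satellite_spec(array_lengths = rep(255008, 4), spacer_mode = 32000,
                   spacer_spread = 0, divergence = 0.01), seed = 11)
  st <- spacer_stats(sim$truth)
  expect_equal(st$n_spacers, 3)
  expect_equal(st$mean_spacing, 287008, tolerance = 1e-6)
})

test_that("monomer divergence yields the expected consensus identity", {
  spec <- satellite_spec(array_lengths = 64000, divergence = 0.05)
  sim <- simulate_satellite_chromosome(spec, seed = 12)
  mono <- spec$monomer
  p <- nchar(mono)
  n <- floor(nchar(sim$seq) / p)
  ids <- vapply(seq_len(n), function(i) {
    m <- substr(sim$seq, (i - 1) * p + 1, i * p)
    mean(strsplit(m, "")[[1]] == strsplit(mono, "")[[1]])
  }, 0)
  expect_lt(abs(mean(ids) - 0.95), 0.01)
})

test_that("methylation tracks honour interval levels and noise", {
  truth <- data.frame(seqname = "chrCap", start = c(0, 5000, 8000),
                      end = c(5000, 8000, 12000),
                      name = c("satellite", "spacer", "satellite"))
  tk <- simulate_methylation_track(12000, truth, dip = NULL,
                                   levels = c(0.9, 0.2, 0.1),
                                   noise_sd = 0, seed = 13)
  mid <- (tk$start + tk$end) / 2
  expect_true(all(tk$frequency[mid < 5000] == 0.9))
  expect_true(all(tk$frequency[mid >= 5000 & mid < 8000] == 0.2))
  # dip window has the minimum windowed mean
  dip <- genomic_interval("chrCap", 5000, 10000)
  tk2 <- simulate_methylation_track(100000, truth = NULL, dip = dip,
                                    levels = c(0.85, 0.2, 0.1),
                                    noise_sd = 0.02, seed = 14)
  wm <- windowed_methylation(tk2, window = 5000, step = 5000)
  expect_true(which.min(wm$mean_frequency) %in% 2:3)
  # noise sd recovery on 1e4 sites
  tk3 <- simulate_methylation_track(2e5, levels = c(0.5, 0.2, 0.1),
                                    noise_sd = 0.05, seed = 15)
  expect_gt(nrow(tk3), 9999)
  expect_lt(abs(sd(tk3$frequency) - 0.05) / 0.05, 0.1)
  expect_error(simulate_methylation_track(
    1000, dip = genomic_interval("chrCap", 500, 2000),
    levels = c(0.9, 0.2, 0.1)), "dip")
  expect_error(simulate_methylation_track(1000, levels = c(1.2, 0, 0)),
               "level")
})

test_that("haplotype panels obey Watterson's expectation", {
  expect_equal(n_sites(simulate_haplotype_panel(5, 1e4, 0, seed = 16)), 0)
  vm2 <- simulate_haplotype_panel(2, 1e5, 1e-3, seed = 17)
  expect_true(all(colSums(vm2$mat) == 1))  # n=2: all singletons
  set.seed(18)
  a1 <- sum(1 / (1:9))
  S <- replicate(500, n_sites(simulate_haplotype_panel(10, 1e5, 1e-3)))
  exp_S <- 1e-3 * 1e5 * a1
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - exp_S), 3 * se)
  expect_error(simulate_haplotype_panel(1, 100, 1e-3), "2 haplotypes")
})

test_that("assembly sets plant SUNKs with the advertised multiplicity", {
  sim <- simulate_assembly_set(n_panel = 3, genome_len = 20000,
                               n_planted = 50, k = 21,
                               query_carries = 0.975, seed = 19)
  expect_length(sim$sunks, 50)
  expect_equal(sum(sim$carried), ceiling(0.975 * 50))
  for (g in sim$panel)
    expect_true(all(fusionscape:::census_counts(build_census(g, 21),
                                                sim$sunks) == 1L))
  none <- simulate_assembly_set(2, 5000, 10, k = 21, query_carries = 0,
                                seed = 20)
  qc <- build_census(none$query, 21)
  expect_true(all(fusionscape:::census_counts(qc, none$sunks) == 0L))
  expect_error(simulate_assembly_set(1, 100, 50, k = 31), "fit")
})

test_that("generators are bit-reproducible given a seed", {
  spec <- ils_benchmark_spec(tau = 0.5)
  g <- ils_gradient_spec(0, 0.3, 1)
  p1 <- simulate_window_panel(spec, g, 50, seed = 21)
  p2 <- simulate_window_panel(spec, g, 50, seed = 21)
  expect_identical(p1$alignments, p2$alignments)
  expect_identical(p1$truth, p2$truth)
  s1 <- simulate_satellite_chromosome(satellite_spec(
    array_lengths = rep(5000, 2)), seed = 22)
  s2 <- simulate_satellite_chromosome(satellite_spec(
    array_lengths = rep(5000, 2)), seed = 22)
  expect_identical(s1, s2)
  a1 <- simulate_assembly_set(2, 5000, 10, k = 21, seed = 23)
  a2 <- simulate_assembly_set(2, 5000, 10, k = 21, seed = 23)
  expect_identical(a1, a2)
})
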