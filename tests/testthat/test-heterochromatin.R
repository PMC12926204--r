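test_that("pristine tandem arrays are detected end to end", {
  mono <- DEFAULT_SATELLITE_MONOMER
  seq <- strrep(mono, 50)
  ann <- detect_satellite_arrays(seq)
  arr <- ann[ann$name == "satellite", ]
  expect_equal(nrow(arr), 1)
  expect_lte(arr$start, 32)
  expect_gte(arr$end, nchar(seq) - 32)
})

test_that("random sequence triggers almost no satellite calls", {
  set.seed(500)
  fp <- vapply(1:1000, function(i) {
    ann <- detect_satellite_arrays(random_dna(2000))
    any(ann$name == "satellite")
  }, TRUE)
  expect_lt(mean(fp), 0.01)
})

test_that("array boundaries land within one monomer of truth", {
  set.seed(501)
  sim <- simulate_satellite_chromosome(
    satellite_spec(array_lengths = c(6400, 4800, 8000),
                   spacer_mode = 3000, spacer_spread = 200,
                   divergence = 0.05), seed = 502)
  ann <- detect_satellite_arrays(sim$seq, max_divergence = 0.25)
  called <- ann[ann$name == "satellite", ]
  truth <- sim$truth[sim$truth$name == "satellite", ]
  expect_equal(nrow(called), nrow(truth))
  expect_true(all(abs(called$start - truth$start) <= 32))
  expect_true(all(abs(called$end - truth$end) <= 32))
})

test_that("spacer statistics follow their definitions", {
  ann <- data.frame(seqname = "s",
                    start = c(0, 100000, 132000, 200000, 232000, 300000),
                    end = c(100000, 132000, 200000, 232000, 300000, 340000),
                    name = c("satellite", "spacer", "satellite", "spacer",
                             "satellite", "spacer"))
  st <- spacer_stats(ann)
  expect_equal(st$n_spacers, 3)
  expect_equal(st$mean_spacing, mean(diff(c(116000, 216000, 320000))))
  # modal length: two spacers of 32 kbp, one of 40 kbp -> 32 kbp bin
  expect_equal(st$modal_length, 32500)
  expect_true(is.na(spacer_stats(ann[2, ])$mean_spacing))
  expect_equal(spacer_stats(ann[c(1, 3), ])$n_spacers, 0)
})

test_that("telomeric repeat runs are found on both strands", {
  set.seed(503)
  bg <- random_dna(100)
  seq <- paste0(bg, strrep("TTAGGG", 10), random_dna(150),
                strrep("CCCTAA", 5), random_dna(80))
  out <- detect_telomeric_repeats(seq)
  plus <- out[out$strand == "+", ]
  minus <- out[out$strand == "-", ]
  expect_equal(nrow(plus), 1)
  expect_equal(c(plus$start, plus$end), c(100, 160))
  expect_equal(plus$score, 10)
  expect_equal(nrow(minus), 1)
  expect_equal(minus$score, 5)
})

test_that("the per-unit mismatch budget is respected", {
  seq <- paste0(random_dna(60), strrep("TGAGGG", 8), random_dna(60))
  set.seed(504)
  hit <- detect_telomeric_repeats(seq, max_mismatch_per_unit = 1)
  expect_true(any(hit$score >= 8))
  none <- detect_telomeric_repeats(seq, max_mismatch_per_unit = 0)
  expect_true(nrow(none) == 0 || all(none$score < 3 | none$start > 108))
})

test_that("reverse-complementing a sequence mirrors telomeric intervals", {
  set.seed(505)
  seq <- paste0(random_dna(70), strrep("TTAGGG", 6), random_dna(40))
  L <- nchar(seq)
  fwd <- detect_telomeric_repeats(seq)
  rev <- detect_telomeric_repeats(revcomp(seq))
  expect_equal(nrow(fwd), nrow(rev))
  f <- fwd[order(fwd$start), ]
  r <- rev[order(-rev$end), ]
  expect_equal(r$start, L - f$end)
  expect_equal(r$end, L - f$start)
  expect_true(all(r$strand != f$strand))
})

test_that("windowed methylation matches the per-site grouping oracle", {
  tk <- data.frame(seqname = "s", start = seq(0, 999, 10),
                   end = seq(1, 1000, 10), coverage = 30, frequency = 0.9)
  wm <- windowed_methylation(tk, window = 100, step = 100)
  expect_true(all(wm$mean_frequency == 0.9))
  expect_equal(sum(wm$n_sites), nrow(tk))  # conservation at step = window
  set.seed(506)
  for (rep in 1:200) {
    n <- sample(20:200, 1)
    pos <- sort(sample.int(5000, n))
    tk <- data.frame(seqname = "s", start = pos, end = pos + 1,
                     coverage = rpois(n, 20), frequency = runif(n))
    w <- sample(c(250, 500, 1000), 1)
    s <- sample(c(125, 250, 500), 1)
    if (s > w) next
    reg <- genomic_interval("s", 0, 5000)
    mine <- windowed_methylation(tk, w, s, region = reg)
    expect_equal(mine$mean_frequency,
                 oracle_windowed_methylation(tk, w, s, reg))
  }
  expect_error(windowed_methylation(tk, window = 100, step = 200), "step")
})

test_that("coverage weighting changes the window mean accordingly", {
  tk <- data.frame(seqname = "s", start = c(10, 20), end = c(11, 21),
                   coverage = c(10, 30), frequency = c(0.2, 0.8))
  reg <- genomic_interval("s", 0, 100)
  expect_equal(windowed_methylation(tk, 100, 100, reg)$mean_frequency, 0.5)
  expect_equal(windowed_methylation(tk, 100, 100, reg,
                                    weighted = TRUE)$mean_frequency,
               (0.2 * 10 + 0.8 * 30) / 40)
})

test_that("CDR calls isolate planted dips", {
  hor <- genomic_interval("chrC", 0, 250000)
  dip <- genomic_interval("chrC", 100000, 105000)
  tk <- simulate_methylation_track(250000, dip = dip,
                                   levels = c(0.85, 0.2, 0.1),
                                   noise_sd = 0.02, seed = 507,
                                   seqname = "chrC")
  cc <- call_cdrs(hor, tk)
  expect_equal(nrow(cc$cdrs), 1)
  expect_equal(c(cc$cdrs$start, cc$cdrs$end), c(100000, 105000))
  # two separated dips -> two CDR intervals
  tk2 <- simulate_methylation_track(250000, dip = NULL,
                                    levels = c(0.85, 0.2, 0.1),
                                    noise_sd = 0.02, seed = 508,
                                    seqname = "chrC")
  for (d in list(c(50000, 60000), c(180000, 190000)))
    tk2$frequency[tk2$start >= d[1] & tk2$start < d[2]] <-
      pmax(0, 0.1 + rnorm(sum(tk2$start >= d[1] & tk2$start < d[2]),
                          0, 0.02))
  cc2 <- call_cdrs(hor, tk2)
  expect_equal(nrow(cc2$cdrs), 2)
  # flat track: flagged, no CDR
  tkf <- simulate_methylation_track(100000, levels = c(0.8, 0.8, 0.8),
                                    noise_sd = 0, seed = 509,
                                    seqname = "chrC")
  ccf <- call_cdrs(genomic_interval("chrC", 0, 100000), tkf)
  expect_true(ccf$flagged)
  expect_equal(nrow(ccf$cdrs), 0)
  expect_error(call_cdrs(genomic_interval("chrC", 0, 6000), tkf), "two")
})

test_that("CDR definitional invariants hold on random tracks", {
  set.seed(510)
  for (rep in 1:50) {
    L <- 150000
    hor <- genomic_interval("chrC", 0, L)
    nd <- sample(0:2, 1)
    tk <- simulate_methylation_track(L, levels = c(0.85, 0.2, 0.1),
                                     noise_sd = 0.03, seqname = "chrC")
    if (nd > 0) {
      ds <- sample.int(L / 5000 - 2, nd) * 5000
      for (s in ds)
        tk$frequency[tk$start >= s & tk$start < s + 5000] <-
          pmax(0, 0.1 + rnorm(sum(tk$start >= s & tk$start < s + 5000),
                              0, 0.03))
    }
    for (mode in c("deep", "q1")) {
      cc <- call_cdrs(hor, tk, mode = mode)
      if (cc$flagged || nrow(cc$cdrs) == 0) next
      means <- cc$window_means$mean_frequency
      gmin_w <- cc$window_means[which.min(means), ]
      in_cdr <- function(s, e) any(cc$cdrs$start <= s & cc$cdrs$end >= e)
      expect_true(in_cdr(gmin_w$start, gmin_w$end))
      for (i in seq_len(nrow(cc$cdrs))) {
        inw <- cc$window_means$start >= cc$cdrs$start[i] &
          cc$window_means$end <= cc$cdrs$end[i]
        expect_true(all(means[inw] < cc$q1))
      }
    }
  }
})

test_that("methylation group comparison behaves at the extremes", {
  set.seed(511)
  mk_track <- function(mu, sd, L = 6e5) {
    pos <- seq(0, L - 1, 20)
    data.frame(seqname = "s", start = pos, end = pos + 1, coverage = 30,
               frequency = pmin(1, pmax(0, rnorm(length(pos), mu, sd))))
  }
  a <- mk_track(0.9, 0.02)
  b <- mk_track(0.2, 0.02)
  sep <- compare_methylation_groups(a, b)
  expect_lt(sep$p, 1e-6)
  expect_gt(sep$mean_a, sep$mean_b)
  same <- compare_methylation_groups(a, a)
  expect_gt(same$p, 0.9)
  # U + U' identity
  ab <- compare_methylation_groups(a, b)
  ba <- compare_methylation_groups(b, a)
  expect_equal(ab$U + ba$U, ab$n_a * ab$n_b)
  # all-tied data
  ct <- data.frame(seqname = "s", start = seq(0, 99999, 20),
                   end = seq(1, 100000, 20), coverage = 1, frequency = 0.5)
  expect_equal(compare_methylation_groups(ct, ct)$p, 1)
})

test_that("normal-approximation p agrees with exact permutation at small n", {
  set.seed(512)
  x <- rnorm(6, 0.5, 0.1)
  y <- rnorm(6, 0.62, 0.1)
  U <- unname(wilcox.test(x, y, exact = FALSE)$statistic)
  approx_p <- wilcox.test(x, y, exact = FALSE)$p.value
  pool <- c(x, y)
  idx <- utils::combn(12, 6)
  stat <- apply(idx, 2, function(ii) {
    xs <- pool[ii]; ys <- pool[-ii]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  })
  exact_p <- mean(abs(stat - 18) >= abs(U - 18))
  expect_lt(abs(approx_p - exact_p), 0.05)
})

test_that("structural haplotypes are tuples of length classes", {
  one <- classify_structural_haplotypes(
    data.frame(arr1 = c(10000, 10000, 10000)))
  expect_equal(one$n_classes, 1)
  four <- classify_structural_haplotypes(
    data.frame(arr1 = c(10, 10, 50, 50) * 1000,
               arr2 = c(5, 20, 5, 20) * 1000))
  expect_equal(four$n_classes, 4)
  miss <- classify_structural_haplotypes(
    data.frame(arr1 = c(10000, NA, 50000)))
  expect_true(is.na(miss$haplotype[2]))
  expect_equal(miss$n_classes, 2)
})

test_that("planted five-class panels are recovered exactly", {
  set.seed(513)
  centers <- list(c(20, 5), c(20, 40), c(60, 5), c(60, 40), c(110, 40))
  rows <- do.call(rbind, lapply(rep(seq_along(centers), each = 10),
                                function(k)
    centers[[k]] * 1000 + rnorm(2, 0, 400)))
  out <- classify_structural_haplotypes(
    as.data.frame(setNames(as.data.frame(rows), c("arr1", "arr2"))))
  expect_equal(out$n_classes, 5)
  truth <- rep(seq_along(centers), each = 10)
  expect_equal(length(unique(paste(out$haplotype, truth))), 5)
})
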