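# Independent brute-force reference implementations used to validate the
# package's statistics.  These deliberately use the most literal O(n^2) /
# per-base formulations and share no code with the implementations they
# check.

# per-base complement of aligned intervals, filtered by length
oracle_nonsyntenic <- function(target_len, aligned, min_len) {
  covered <- rep(FALSE, target_len)
  for (i in seq_len(nrow(aligned)))
    if (aligned$end[i] > aligned$start[i])
      covered[(aligned$start[i] + 1):aligned$end[i]] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- !r$values
  regs <- cbind(starts[keep], ends[keep])
  list(total = sum(!covered),
       regions = regs[regs[, 2] - regs[, 1] >= min_len, , drop = FALSE])
}

# mean pairwise difference count over all C(n,2) haplotype pairs, per bp
oracle_pi <- function(vm, start, end) {
  inw <- vm$positions >= start & vm$positions < end
  m <- vm$mat[, inw, drop = FALSE]
  n <- nrow(m)
  tot <- 0
  npairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cmp <- !is.na(m[i, ]) & !is.na(m[j, ])
    tot <- tot + sum(m[i, cmp] != m[j, cmp])
    npairs <- npairs + 1
  }
  # per-site unbiased estimator sums 2 p q n/(n-1), equal to the mean
  # pairwise difference only with complete data; oracle assumes none
  tot / npairs / (end - start)
}

# Tajima's D evaluated from the literal formula with pairwise differences
oracle_tajima_d <- function(vm, start, end) {
  inw <- vm$positions >= start & vm$positions < end
  m <- vm$mat[, inw, drop = FALSE]
  n <- nrow(m)
  S <- 0
  for (j in seq_len(ncol(m))) {
    cnt <- sum(m[, j] == 1)
    if (cnt > 0 && cnt < n) S <- S + 1
  }
  if (S == 0) return(NaN)
  pihat <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    pihat <- pihat + sum(m[i, ] != m[j, ])
  pihat <- pihat / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pihat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# per-site grouping with tapply
oracle_windowed_methylation <- function(track, window, step, region) {
  starts <- seq(region$start, region$end - 1, by = step)
  starts <- starts[starts < region$end]
  mid <- (track$start + track$end) / 2
  vapply(starts, function(s) {
    inw <- mid >= s & mid < min(s + window, region$end)
    if (any(inw)) mean(track$frequency[inw]) else NA_real_
  }, 0)
}

# random variant matrix with optional missingness
random_vm <- function(n, L, nsites, miss = 0) {
  pos <- sort(sample.int(L, nsites)) - 1
  mat <- matrix(rbinom(n * nsites, 1, runif(1, 0.1, 0.9)), n, nsites)
  if (miss > 0) mat[runif(length(mat)) < miss] <- NA
  variant_matrix(mat, pos)
}

# filter + sort + sweep merge count, independent of IRanges
oracle_sd_count <- function(hits, min_identity, min_len, min_cov) {
  pass <- hits[hits$identity >= min_identity & hits$aligned_len >= min_len &
                 hits$query_coverage >= min_cov, , drop = FALSE]
  out <- integer(0)
  for (g in unique(hits$genome)) {
    cnt <- 0
    hg <- pass[pass$genome == g, , drop = FALSE]
    for (sq in unique(hg$target_seqname)) {
      h <- hg[hg$target_seqname == sq, , drop = FALSE]
      h <- h[order(h$target_start), , drop = FALSE]
      if (nrow(h) == 0) next
      cur_end <- -Inf
      for (i in seq_len(nrow(h))) {
        if (h$target_start[i] > cur_end) cnt <- cnt + 1
        cur_end <- max(cur_end, h$target_end[i])
      }
    }
    out[g] <- cnt
  }
  out
}

# brute-force SUNK identification by scanning raw k-mer lists
oracle_sunks <- function(target, panel, nhp, k) {
  canon <- function(s) {
    km <- substring(s, seq_len(nchar(s) - k + 1), k:nchar(s))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(km)))
    ifelse(km <= rc, km, rc)
  }
  cand <- unique(canon(target))
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    ok <- TRUE
    for (p in panel) if (sum(canon(p) == cand[i]) != 1) { ok <- FALSE; break }
    if (ok) for (q in nhp) if (any(canon(q) == cand[i])) { ok <- FALSE; break }
    keep[i] <- ok
  }
  sort(cand[keep])
}

random_interval_set <- function(target_len, n) {
  s <- sample.int(target_len - 1, n, replace = TRUE)
  e <- pmin(target_len, s + sample.int(round(target_len / 4), n,
                                       replace = TRUE))
  data.frame(start = s - 1, end = e)[e > s - 1, , drop = FALSE]
}

# mutate a fraction of bases, returning sequence and realised identity
mutate_seq <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  list(seq = paste(v, collapse = ""), identity = 1 - length(hit) / length(v))
}
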