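#' Detect tandem satellite arrays by periodicity
#'
#' Finds regions self-similar at lag `monomer_len` (autocorrelation of
#' base matches, smoothed over two monomer lengths), then snaps array
#' boundaries to the monomer grid by requiring boundary monomers to match
#' the array's phase consensus within `max_divergence`.
#'
#' @param seq character sequence.
#' @param monomer_len monomer period in bp.
#' @param min_array minimum array size in monomers.
#' @param max_divergence maximum per-base divergence of a monomer from
#'   the array consensus.
#' @param seqname sequence name for the annotation.
#' @return BED-style data.frame of `satellite` / `spacer` intervals
#'   partitioning the sequence (`spacer` denotes any non-array segment).
#' @export
detect_satellite_arrays <- function(seq, monomer_len = 32, min_array = 5,
                                    max_divergence = 0.2,
                                    seqname = "chrCap") {
  p <- monomer_len
  L <- nchar(seq)
  empty <- genomic_interval(seqname, 0, max(L, 1))
  empty$name <- "spacer"
  if (L < p * min_array) return(empty)
  v <- dna_to_int(seq)
  m <- as.numeric(v[seq_len(L - p)] == v[(p + 1):L])
  sm <- stats::filter(m, rep(1 / (2 * p), 2 * p), sides = 2)
  sm[is.na(sm)] <- 0
  # expected match fraction inside an array: both copies mutated
  thr <- 0.6
  run <- rle(as.numeric(sm >= thr))
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  cand <- which(run$values == 1 & run$lengths >= (min_array - 1) * p)
  if (length(cand) == 0) return(empty)
  ivs <- list()
  for (ci in cand) {
    a <- starts[ci]
    b <- min(ends[ci] + p, L)  # matches at lag p extend the array by p
    reg <- refine_array_bounds(v, a, b, p, max_divergence, min_array)
    if (!is.null(reg)) ivs[[length(ivs) + 1L]] <- reg
  }
  if (length(ivs) == 0) return(empty)
  arr <- do.call(rbind, ivs)
  arr <- reduce_intervals(genomic_interval(seqname, arr[, 1], arr[, 2]),
                          seqname)
  arr$name <- "satellite"
  sp <- nonsyntenic_segments(L, arr, min_len = 1, seqname = seqname)$non_syntenic
  sp$name <- if (nrow(sp) > 0) "spacer" else character(0)
  out <- rbind(arr[, c("seqname", "start", "end", "name")],
               sp[, c("seqname", "start", "end", "name")])
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

# snap a candidate region [a, b] (1-based) to monomer-grid boundaries
refine_array_bounds <- function(v, a, b, p, max_divergence, min_array) {
  # choose the phase that maximises internal self-match on the grid
  L <- length(v)
  a0 <- max(1, a - p)
  b0 <- min(L, b + p)
  seg <- v[a0:b0]
  n_mono <- floor(length(seg) / p)
  if (n_mono < min_array) return(NULL)
  best_phase <- 0
  best_score <- -1
  for (ph in 0:(p - 1)) {
    idx <- seq(1 + ph, by = p, length.out = floor((length(seg) - ph) / p))
    if (length(idx) < 3) next
    cols <- outer(idx, 0:(p - 1), `+`)
    cols <- cols[rowSums(cols > length(seg)) == 0, , drop = FALSE]
    if (nrow(cols) < 3) next
    mono <- matrix(seg[cols], nrow = nrow(cols))
    cons <- apply(mono, 2, function(col) {
      tb <- tabulate(col + 1L, nbins = 4)
      which.max(tb) - 1L
    })
    score <- mean(t(mono) == cons)
    if (score > best_score) {
      best_score <- score
      best_phase <- ph
      best_cons <- cons
      best_idx <- idx[rowSums(outer(idx, 0:(p - 1), `+`) >
                                length(seg)) == 0]
    }
  }
  if (best_score < 0) return(NULL)
  ident <- vapply(best_idx, function(i)
    mean(seg[i:(i + p - 1)] == best_cons), 0)
  ok <- ident >= 1 - max_divergence
  if (!any(ok)) return(NULL)
  first <- best_idx[which(ok)[1]]
  last <- best_idx[rev(which(ok))[1]]
  if ((last - first) / p + 1 < min_array) return(NULL)
  # convert to 0-based half-open on the full sequence
  c(a0 - 1 + first - 1, a0 - 1 + last + p - 1)
}

#' Satellite spacer spacing and length statistics
#'
#' @param annotation BED-style data.frame with a `name` column labelling
#'   `spacer` intervals (e.g. from [detect_satellite_arrays()] or a
#'   truth annotation).
#' @param mode_bin histogram bin width (bp) for the modal spacer length;
#'   the mode is reported as the midpoint of the fullest bin.
#' @return list with `mean_spacing` (bp between consecutive spacer
#'   midpoints; NA with < 2 spacers), `modal_length`, `n_spacers`.
#' @export
spacer_stats <- function(annotation, mode_bin = 1000) {
  sp <- annotation[annotation$name == "spacer", , drop = FALSE]
  n <- nrow(sp)
  if (n == 0)
    return(list(mean_spacing = NA_real_, modal_length = NA_real_,
                n_spacers = 0L))
  mids <- sort((sp$start + sp$end) / 2)
  lens <- interval_length(sp)
  bins <- floor(lens / mode_bin)
  tab <- table(bins)
  modal <- (as.numeric(names(tab)[which.max(tab)]) + 0.5) * mode_bin
  list(mean_spacing = if (n >= 2) mean(diff(mids)) else NA_real_,
       modal_length = modal, n_spacers = n)
}

#' Detect tandem telomeric repeat runs
#'
#' Scans for maximal tandem runs of at least `min_units` copies of each
#' motif, allowing up to `max_mismatch_per_unit` substitutions per copy;
#' reverse-complement runs (e.g. CCCTAA for TTAGGG) are reported on the
#' minus strand.  Interstitial telomeric repeats at fusion sites are the
#' classic use.
#'
#' @param seq character sequence.
#' @param motifs character vector of motifs (default canonical TTAGGG).
#' @param min_units minimum tandem copies.
#' @param max_mismatch_per_unit mismatch budget per unit.
#' @param both_strands also scan for reverse-complement runs.
#' @param seqname sequence name.
#' @return BED-style data.frame: `seqname`, `start`, `end`, `name`
#'   (motif), `score` (unit count), `strand`.
#' @export
detect_telomeric_repeats <- function(seq, motifs = "TTAGGG", min_units = 3,
                                     max_mismatch_per_unit = 1,
                                     both_strands = TRUE,
                                     seqname = "seq") {
  out <- list()
  for (motif in motifs) {
    if (nchar(motif) < 3) stop("motif length must be >= 3")
    out[[length(out) + 1L]] <-
      telomere_runs(seq, motif, min_units, max_mismatch_per_unit, "+",
                    seqname)
    if (both_strands) {
      rc <- revcomp(motif)
      if (rc != motif)
        out[[length(out) + 1L]] <-
          telomere_runs(seq, rc, min_units, max_mismatch_per_unit, "-",
                        seqname, label = motif)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

telomere_runs <- function(seq, motif, min_units, max_mm, strand, seqname,
                          label = motif) {
  u <- nchar(motif)
  v <- dna_to_int(seq)
  mv <- dna_to_int(motif)
  L <- length(v)
  empty <- data.frame(seqname = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      score = numeric(0), strand = character(0))
  if (L < u * min_units) return(empty)
  npos <- L - u + 1
  mism <- integer(npos)
  for (j in seq_len(u))
    mism <- mism + as.integer(v[j:(j + npos - 1)] != mv[j])
  ok <- mism <= max_mm
  res <- list()
  used_until <- 0
  for (s in which(ok)) {
    if (s <= used_until) next
    e <- s
    while (e + u <= npos && ok[e + u]) e <- e + u
    # e is the start of the last unit; count units
    units <- (e - s) / u + 1
    if (units >= min_units) {
      res[[length(res) + 1L]] <-
        data.frame(seqname = seqname, start = s - 1, end = e + u - 1,
                   name = label, score = units, strand = strand,
                   stringsAsFactors = FALSE)
      used_until <- e + u - 1
    }
  }
  if (length(res) == 0) return(empty)
  do.call(rbind, res)
}

#' Gap-based structural haplotype classification from array lengths
#'
#' Clusters each array's length distribution in one dimension, splitting
#' wherever consecutive sorted lengths differ by more than
#' `gap_frac * median(lengths)`; a sample's structural haplotype is the
#' tuple of its per-array length classes.  This mirrors how length
#' variation of the first satellite arrays partitions assemblies into a
#' small number of structural haplotypes.
#'
#' @param array_length_table data.frame (or matrix) of array lengths:
#'   one row per sample, one column per named array; `NA` marks a
#'   missing length.
#' @param gap_frac relative gap size that separates length classes.
#' @return list with `haplotype` (character label per sample, `NA` when
#'   unclassified), `n_classes`, and `class_matrix` of per-array class
#'   indices.
#' @export
classify_structural_haplotypes <- function(array_length_table,
                                           gap_frac = 0.25) {
  m <- as.matrix(array_length_table)
  if (ncol(m) < 1) stop("need at least one array column")
  cls <- matrix(NA_integer_, nrow(m), ncol(m),
                dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x)
    if (!any(ok)) next
    ord <- order(x[ok])
    sx <- x[ok][ord]
    gap <- gap_frac * median(sx)
    breaks <- c(0, cumsum(diff(sx) > gap))
    cl <- integer(sum(ok))
    cl[ord] <- breaks + 1L
    cls[ok, j] <- cl
  }
  complete <- rowSums(is.na(cls)) == 0
  hap <- rep(NA_character_, nrow(m))
  hap[complete] <- apply(cls[complete, , drop = FALSE], 1, paste,
                         collapse = "-")
  list(haplotype = hap, n_classes = length(unique(hap[complete])),
       class_matrix = cls)
}
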