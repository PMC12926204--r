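#' Non-syntenic segment detection
#'
#' Complements the union of aligned intervals over a target sequence:
#' reports unaligned regions of at least `min_len` bp, plus the total
#' unaligned bp regardless of length (the two are tracked separately, as
#' short gaps contribute to the total but not to the region list).
#'
#' @param target_len target sequence length in bp.
#' @param aligned data.frame of aligned intervals (`start`, `end`,
#'   0-based half-open) on the target; must lie within
#'   `[0, target_len]`.
#' @param min_len minimum reported region length in bp.
#' @param seqname target sequence name for the report.
#' @return list with `non_syntenic` (interval data.frame),
#'   `total_unaligned_bp` and `n_regions`.
#' @examples
#' aligned <- data.frame(start = c(0, 55000, 75000),
#'                       end = c(40000, 70000, 100000))
#' nonsyntenic_segments(100000, aligned)
#' @export
nonsyntenic_segments <- function(target_len, aligned, min_len = 10000,
                                 seqname = "target") {
  if (nrow(aligned) > 0) {
    if (any(aligned$start < 0 | aligned$end > target_len |
              aligned$start >= aligned$end))
      stop("aligned interval outside [0, target_len) or empty")
  }
  cov <- if (nrow(aligned) > 0) IRanges::reduce(to_iranges(aligned))
  else IRanges::IRanges()
  gaps <- IRanges::gaps(cov, start = 1L, end = as.integer(target_len))
  gapdf <- from_iranges(gaps, seqname)
  total <- sum(interval_length(gapdf))
  keep <- gapdf[interval_length(gapdf) >= min_len, , drop = FALSE]
  rownames(keep) <- NULL
  list(non_syntenic = keep, total_unaligned_bp = total,
       n_regions = nrow(keep))
}

#' Windowed k-mer identity matrix
#'
#' Splits each sequence into consecutive windows, collects canonical
#' k-mer sets per window, and estimates average nucleotide identity from
#' the containment `c = |A intersect B| / min(|A|, |B|)` of each window
#' pair as `c^(1/k)` (the Mash/FastANI containment transform).  With a
#' single input the matrix is a symmetric self-comparison, the form used
#' for satellite-architecture heatmaps.
#'
#' @param seq_a,seq_b character sequences; `seq_b` defaults to `seq_a`.
#' @param window window size in bp (>= k); sequences shorter than one
#'   window form a single window.
#' @param k k-mer size.
#' @return numeric matrix of identity estimates in `[0, 1]`, with window
#'   start coordinates as dimnames.
#' @export
windowed_identity_matrix <- function(seq_a, seq_b = NULL, window = 5000,
                                     k = 21) {
  if (window < k) stop("window must be >= k")
  self <- is.null(seq_b)
  if (self) seq_b <- seq_a
  split_windows <- function(s) {
    L <- nchar(s)
    starts <- seq(1, max(1, L - k + 1), by = window)
    lapply(starts, function(st)
      unique(canonical_kmers(seq_kmers(substr(s, st, min(L, st + window - 1)),
                                       k))))
  }
  ka <- split_windows(seq_a)
  kb <- if (self) ka else split_windows(seq_b)
  M <- matrix(0, length(ka), length(kb))
  for (i in seq_along(ka)) {
    jrange <- if (self) i:length(kb) else seq_along(kb)
    for (j in jrange) {
      na <- length(ka[[i]]); nb <- length(kb[[j]])
      if (na == 0 || nb == 0) next
      cont <- length(intersect(ka[[i]], kb[[j]])) / min(na, nb)
      M[i, j] <- cont^(1 / k)
      if (self) M[j, i] <- M[i, j]
    }
  }
  starts_a <- (seq_along(ka) - 1) * window
  starts_b <- (seq_along(kb) - 1) * window
  dimnames(M) <- list(starts_a, starts_b)
  M
}

#' Segmental-duplication copy counting
#'
#' Counts full-length homologous copies per genome: hits are filtered to
#' `identity >= min_identity`, `aligned_len >= min_len` and
#' `query_coverage >= min_query_cov`, then overlapping passing hits on
#' the same target sequence are merged before counting, so fragmented
#' alignments of one copy count once.
#'
#' @param hits data.frame with columns `genome`, `target_seqname`,
#'   `target_start`, `target_end`, `identity` (fraction),
#'   `aligned_len` (bp), `query_coverage` (fraction).
#' @param min_identity minimum alignment identity (default 0.98).
#' @param min_len minimum aligned length in bp (default 20 kbp).
#' @param min_query_cov minimum query coverage defining "full-length"
#'   (default 0.8).
#' @return named integer vector of copy counts per genome (0 for genomes
#'   whose hits all fail the filters).
#' @export
sd_copy_count <- function(hits, min_identity = 0.98, min_len = 20000,
                          min_query_cov = 0.8) {
  need <- c("genome", "target_seqname", "target_start", "target_end",
            "identity", "aligned_len", "query_coverage")
  if (!all(need %in% names(hits)))
    stop("hits must have columns: ", paste(need, collapse = ", "))
  genomes <- unique(hits$genome)
  pass <- hits$identity >= min_identity & hits$aligned_len >= min_len &
    hits$query_coverage >= min_query_cov
  hp <- hits[pass, , drop = FALSE]
  out <- setNames(integer(length(genomes)), genomes)
  if (nrow(hp) == 0) return(out)
  key <- interaction(hp$genome, hp$target_seqname, drop = TRUE)
  for (grp in split(hp, key)) {
    merged <- IRanges::reduce(IRanges::IRanges(
      start = as.integer(grp$target_start) + 1L,
      end = as.integer(grp$target_end)))
    g <- grp$genome[1]
    out[g] <- out[g] + length(merged)
  }
  out
}

#' Flank-synteny ortholog assignment for duplicated loci
#'
#' Two loci in different genomes are orthologous when both the upstream
#' and downstream flank of each maps co-linearly within `tol` bp of the
#' other locus, reciprocally.  Ortholog groups are the connected
#' components of the resulting graph.  Loci with a missing flank mapping
#' stay ungrouped and are flagged.
#'
#' @param loci data.frame with columns `locus_id`, `genome`, `seqname`,
#'   `start`, `end`.
#' @param flanks data.frame with columns `locus_id`, `side` (`"up"` /
#'   `"down"`), `target_genome`, `target_seqname`, `target_start`,
#'   `target_end`: where each locus's flanks align in other genomes.
#' @param tol distance tolerance in bp (default 100 kbp).
#' @return data.frame `locus_id`, `genome`, `group` (NA when ungrouped),
#'   `flagged`.
#' @export
assign_orthologs <- function(loci, flanks, tol = 100000) {
  stopifnot(all(c("locus_id", "genome", "seqname", "start", "end") %in%
                  names(loci)))
  mid <- function(s, e) (s + e) / 2
  supports <- function(a, b) {
    # flanks of locus a, mapped into b's genome, bracket locus b
    fa <- flanks[flanks$locus_id == a$locus_id &
                   flanks$target_genome == b$genome, , drop = FALSE]
    up <- fa[fa$side == "up", , drop = FALSE]
    dn <- fa[fa$side == "down", , drop = FALSE]
    if (nrow(up) == 0 || nrow(dn) == 0) return(NA)
    any(vapply(seq_len(nrow(up)), function(i) any(vapply(
      seq_len(nrow(dn)), function(j) {
        u <- up[i, ]; d <- dn[j, ]
        u$target_seqname == b$seqname && d$target_seqname == b$seqname &&
          mid(u$target_start, u$target_end) <
            mid(d$target_start, d$target_end) &&
          abs(mid(u$target_start, u$target_end) - b$start) <= tol &&
          abs(mid(d$target_start, d$target_end) - b$end) <= tol
      }, TRUE)), TRUE))
  }
  n <- nrow(loci)
  flagged <- rep(FALSE, n)
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    a <- loci[i, ]; b <- loci[j, ]
    if (a$genome == b$genome) next
    ab <- supports(a, b)
    ba <- supports(b, a)
    if (is.na(ab) || is.na(ba)) {
      if (is.na(ab)) flagged[i] <- TRUE
      if (is.na(ba)) flagged[j] <- TRUE
      next
    }
    if (ab && ba) edges <- rbind(edges, c(i, j))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  grouped <- tabulate(comp, nbins = max(comp)) > 1
  group <- ifelse(grouped[comp], comp, NA_integer_)
  data.frame(locus_id = loci$locus_id, genome = loci$genome,
             group = group, flagged = flagged & is.na(group),
             stringsAsFactors = FALSE)
}
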