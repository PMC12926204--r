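#' Canonical k-mer census of an assembly
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement) over all A/C/G/T windows of a sequence set;
#' windows containing other characters (N) are skipped.
#'
#' @param seqs named character vector of sequences, a single sequence, or
#'   a path to a FASTA(.gz) file.
#' @param k odd k-mer size in `[11, 63]`.
#' @return object of class `kmer_census`: a named integer table of counts
#'   with attributes `k` and `canonical`.
#' @examples
#' cen <- build_census(c(chr = "ACGTACGTACGTACG"), k = 11)
#' @export
build_census <- function(seqs, k = 31) {
  if (k %% 2 != 1 || k < 11 || k > 63)
    stop("k must be odd and within [11, 63]")
  if (length(seqs) == 1 && is.null(names(seqs)) && file.exists(seqs))
    seqs <- read_fasta(seqs)
  km <- unlist(lapply(seqs, seq_kmers, k = k), use.names = FALSE)
  counts <- table(canonical_kmers(km))
  structure(as.integer(counts), names = names(counts), k = k,
            canonical = TRUE, class = "kmer_census")
}

#' @export
print.kmer_census <- function(x, ...) {
  cat(sprintf("kmer_census: %d distinct canonical %d-mers, total mass %d\n",
              length(x), attr(x, "k"), sum(unclass(x))))
  invisible(x)
}

# counts for specific k-mers (0 when absent); kmers are canonicalised
census_counts <- function(census, kmers) {
  idx <- match(canonical_kmers(kmers), names(census))
  out <- unclass(census)[idx]
  out[is.na(out)] <- 0L
  unname(out)
}

#' Identify singly unique nucleotide k-mers (SUNKs)
#'
#' A SUNK is a k-mer of the target region whose canonical count is
#' exactly 1 in every panel census and (by default) 0 in every
#' non-target-lineage census, so that its presence elsewhere is an
#' unambiguous marker of the target haplotype.
#'
#' @param target sequence (character), named sequence vector or FASTA
#'   path for the target region.
#' @param panel_censuses list of [build_census()] results for the
#'   same-lineage assembly panel; all must share `k`.
#' @param nhp_censuses optional list of censuses for outgroup (e.g.
#'   nonhuman primate) assemblies.
#' @param require_absent_in_nhp require count 0 in every outgroup census.
#' @return character vector of canonical SUNK k-mers (sorted).
#' @export
identify_sunks <- function(target, panel_censuses, nhp_censuses = NULL,
                           require_absent_in_nhp = TRUE) {
  if (length(panel_censuses) == 0) stop("need at least one panel census")
  ks <- vapply(panel_censuses, attr, 0, which = "k")
  if (length(unique(ks)) != 1) stop("panel censuses disagree on k")
  k <- ks[[1]]
  if (length(target) == 1 && is.null(names(target)) && file.exists(target))
    target <- read_fasta(target)
  cand <- unique(canonical_kmers(unlist(lapply(target, seq_kmers, k = k),
                                        use.names = FALSE)))
  if (length(cand) == 0) return(character(0))
  keep <- rep(TRUE, length(cand))
  for (cen in panel_censuses)
    keep <- keep & census_counts(cen, cand) == 1L
  if (require_absent_in_nhp && !is.null(nhp_censuses))
    for (cen in nhp_censuses)
      keep <- keep & census_counts(cen, cand) == 0L
  sort(cand[keep])
}

#' SUNK presence in a query assembly
#'
#' @param sunks character vector of (canonical) SUNK k-mers.
#' @param query query sequence(s) or FASTA path.
#' @param k k-mer size; defaults to the SUNK length.
#' @return object of class `sunk_report`: list with `n_total`,
#'   `n_detected`, `fraction`, `percent` (rounded to one decimal, the
#'   convention used when reporting archaic-genome SUNK retention) and
#'   per-SUNK logical `present`.
#' @export
query_presence <- function(sunks, query, k = NULL) {
  if (length(sunks) == 0) stop("empty SUNK set")
  k <- k %||% nchar(sunks[1])
  if (length(query) == 1 && is.null(names(query)) && file.exists(query))
    query <- read_fasta(query)
  qcen <- build_census(query, k = k)
  present <- census_counts(qcen, sunks) >= 1L
  names(present) <- sunks
  structure(list(n_total = length(sunks), n_detected = sum(present),
                 fraction = mean(present),
                 percent = percent_detected(sum(present), length(sunks)),
                 present = present),
            class = "sunk_report")
}

#' @export
print.sunk_report <- function(x, ...) {
  cat(sprintf("sunk_report: %d/%d SUNKs detected (%.1f%%)\n",
              x$n_detected, x$n_total, x$percent))
  invisible(x)
}

#' Detected-SUNK percentage at one-decimal precision
#'
#' The reporting convention for SUNK retention: `100 * detected / total`
#' rounded to one decimal place (e.g. 8246/8460 -> 97.5).
#'
#' @param n_detected detected count.
#' @param n_total total count (> 0).
#' @return numeric percentage.
#' @export
percent_detected <- function(n_detected, n_total) {
  if (n_total <= 0) stop("undefined fraction: empty SUNK set")
  round(100 * n_detected / n_total, 1)
}
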