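#' Simulate an assembly panel with planted unique k-mers
#'
#' Builds `n_panel` random "assembly" sequences, each carrying every
#' planted k-mer exactly once, plus a query sequence carrying
#' `ceiling(query_carries * n_planted)` of them.  Planted k-mers are drawn
#' to be canonically absent from all background sequence (collisions are
#' re-drawn, up to `max_retries` each).  This is the truth-labelled test
#' harness for singly-unique-nucleotide-k-mer (SUNK) analysis.
#'
#' @param n_panel number of panel assemblies.
#' @param genome_len background length of each assembly in bp.
#' @param n_planted number of planted unique k-mers.
#' @param k k-mer size (odd).
#' @param query_carries fraction of planted k-mers present in the query.
#' @param seed optional integer seed.
#' @param target_span bp at the start of panel assembly 1 in which all
#'   planted k-mers are embedded; this is the "target region" whose SUNKs
#'   downstream analysis identifies.
#' @param max_retries rejection-sampling retries per k-mer.
#' @return list with `panel` (named list of sequences), `query`
#'   (sequence), `sunks` (character vector of planted canonical k-mers),
#'   `target_region` (interval on panel assembly 1) and `carried`
#'   (logical vector: planted k-mer present in query).
#' @export
simulate_assembly_set <- function(n_panel, genome_len, n_planted, k = 31,
                                  query_carries = 1, seed = NULL,
                                  target_span = NULL, max_retries = 100) {
  stopifnot(n_panel >= 1, k %% 2 == 1, query_carries >= 0,
            query_carries <= 1)
  if (n_planted * k > genome_len)
    stop("planted k-mers do not fit the genome length")
  if (!is.null(seed)) set.seed(seed)
  target_span <- target_span %||% min(genome_len,
                                      ceiling(1.5 * n_planted * k) + k)
  if (n_planted * k > target_span)
    stop("planted k-mers do not fit the target span")

  backgrounds <- lapply(seq_len(n_panel), function(i) random_dna(genome_len))
  query_bg <- random_dna(genome_len)
  occupied <- unique(canonical_kmers(unlist(
    lapply(c(backgrounds, list(query_bg)), seq_kmers, k = k))))
  occ <- new.env(hash = TRUE, parent = emptyenv())
  for (x in occupied) assign(x, TRUE, envir = occ)

  sunks <- character(n_planted)
  for (i in seq_len(n_planted)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      cand <- canonical_kmers(random_dna(k))
      if (!exists(cand, envir = occ, inherits = FALSE)) {
        assign(cand, TRUE, envir = occ)
        sunks[i] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not draw a collision-free k-mer after ",
                  max_retries, " retries")
  }

  # Place each k-mer once per sequence at non-overlapping slots (slot
  # spacing > k so planted copies cannot overlap).  Windows straddling a
  # planted copy and its flanking background ("junction shadows") would
  # match across genomes whenever the adjacent background bases agree by
  # chance, creating spurious singly-unique k-mers; forcing the bases
  # adjacent to each copy to differ from the reference genome's flanks
  # removes every such shadow.
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  plant <- function(seq, kmers, span = nchar(seq), ref_flanks = NULL) {
    n <- length(kmers)
    flanks <- matrix("", max(n, 1), 2)
    if (n == 0) return(list(seq = seq, flanks = flanks))
    slot <- floor(span / n)
    if (slot < k + 1) stop("planting span too small")
    offs <- (seq_len(n) - 1) * slot +
      sample.int(slot - k, n, replace = TRUE)
    for (j in seq_len(n)) {
      substr(seq, offs[j] + 1, offs[j] + k) <- kmers[j]
      lpos <- offs[j]
      rpos <- offs[j] + k + 1
      if (!is.null(ref_flanks)) {
        if (lpos >= 1 && substr(seq, lpos, lpos) == ref_flanks[j, 1])
          substr(seq, lpos, lpos) <- rot[[ref_flanks[j, 1]]]
        if (rpos <= nchar(seq) && substr(seq, rpos, rpos) == ref_flanks[j, 2])
          substr(seq, rpos, rpos) <- rot[[ref_flanks[j, 2]]]
      }
      flanks[j, ] <- c(if (lpos >= 1) substr(seq, lpos, lpos) else "",
                       if (rpos <= nchar(seq)) substr(seq, rpos, rpos)
                       else "")
    }
    list(seq = seq, flanks = flanks)
  }
  panel <- vector("list", n_panel)
  first <- plant(backgrounds[[1]], sunks, span = target_span)
  panel[[1]] <- first$seq
  if (n_panel > 1)
    for (i in 2:n_panel)
      panel[[i]] <- plant(backgrounds[[i]], sunks,
                          ref_flanks = first$flanks)$seq
  names(panel) <- sprintf("panel%d", seq_len(n_panel))

  n_carry <- ceiling(query_carries * n_planted)
  carried <- rep(FALSE, n_planted)
  if (n_carry > 0) carried[sample.int(n_planted, n_carry)] <- TRUE
  query <- plant(query_bg, sunks[carried])$seq

  # verify uniqueness after planting (junction k-mers could collide);
  # this is rare, so failure is an error rather than a silent redraw
  for (i in seq_len(n_panel)) {
    cen <- build_census(panel[[i]], k = k)
    cnt <- census_counts(cen, sunks)
    if (any(cnt != 1L))
      stop("planted k-mer not unique in panel assembly ", i,
           "; re-run with a different seed")
  }
  list(panel = panel, query = query, sunks = sunks,
       target_region = genomic_interval(names(panel)[1], 0, target_span),
       carried = carried)
}
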