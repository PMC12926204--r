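#' Default 32 bp AT-rich satellite monomer
#'
#' A synthetic AT-rich 32-mer standing in for the tandem subterminal
#' satellite unit of African great apes; it is not a published consensus.
#' @export
DEFAULT_SATELLITE_MONOMER <- "AATGGAATTCATCGAATGGAATTATCAAATGC"

#' Subterminal satellite chromosome specification
#'
#' Architecture of a satellite-and-spacer region: tandem arrays of a
#' short AT-rich monomer punctuated by unique "spacer" segments, the
#' layout seen in great-ape subterminal heterochromatic caps where large
#' pCht tracts are interrupted roughly every few hundred kbp by an SD
#' spacer.
#'
#' @param monomer monomer sequence (>= 2 bp); default 32 bp AT-rich unit.
#' @param array_lengths satellite array lengths in bp (one array per
#'   element, rounded down to whole monomers; all > 0).
#' @param spacer_mode modal spacer length in bp.
#' @param spacer_spread standard deviation of spacer lengths in bp.
#' @param divergence per-base substitution probability applied
#'   independently to every monomer copy (0.05 gives ~95% mean monomer
#'   identity to the consensus).
#' @return an object of class `satellite_spec`.
#' @export
satellite_spec <- function(monomer = DEFAULT_SATELLITE_MONOMER,
                           array_lengths = rep(255000, 5),
                           spacer_mode = 32000, spacer_spread = 3000,
                           divergence = 0.05) {
  if (nchar(monomer) < 2) stop("monomer length must be >= 2")
  if (length(array_lengths) == 0) stop("at least one array required")
  if (any(array_lengths <= 0)) stop("array lengths must be > 0")
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)")
  structure(list(monomer = toupper(monomer),
                 array_lengths = as.numeric(array_lengths),
                 spacer_mode = spacer_mode, spacer_spread = spacer_spread,
                 divergence = divergence),
            class = "satellite_spec")
}

mutate_bases <- function(seq, p) {
  if (p <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < p)
  for (i in hit) {
    v[i] <- sample(setdiff(DNA_BASES, v[i]), 1)
  }
  paste(v, collapse = "")
}

#' Simulate a satellite/spacer chromosome with truth annotation
#'
#' Concatenates mutated monomer arrays separated by random unique spacer
#' segments.  The truth annotation partitions the sequence into labelled
#' `satellite` and `spacer` intervals.
#'
#' @param spec a [satellite_spec()].
#' @param seed optional integer seed.
#' @param seqname name for the simulated sequence.
#' @return list with `seq` (character sequence) and `truth` (BED-style
#'   data.frame with columns `seqname`, `start`, `end`, `name`).
#' @export
simulate_satellite_chromosome <- function(spec, seed = NULL,
                                          seqname = "chrCap") {
  stopifnot(inherits(spec, "satellite_spec"))
  if (!is.null(seed)) set.seed(seed)
  p <- nchar(spec$monomer)
  pieces <- character(0)
  labels <- character(0)
  for (i in seq_along(spec$array_lengths)) {
    n_mono <- max(1L, floor(spec$array_lengths[i] / p))
    monos <- vapply(seq_len(n_mono), function(j)
      mutate_bases(spec$monomer, spec$divergence), "")
    pieces <- c(pieces, paste(monos, collapse = ""))
    labels <- c(labels, "satellite")
    if (i < length(spec$array_lengths)) {
      slen <- max(p, round(rnorm(1, spec$spacer_mode, spec$spacer_spread)))
      pieces <- c(pieces, random_dna(slen))
      labels <- c(labels, "spacer")
    }
  }
  lens <- nchar(pieces)
  ends <- cumsum(lens)
  starts <- ends - lens
  truth <- genomic_interval(seqname, starts, ends)
  truth$name <- labels
  list(seq = paste(pieces, collapse = ""), truth = truth)
}
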