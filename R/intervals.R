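#' Genomic intervals
#'
#' All coordinates handled by fusionscape are 0-based, half-open
#' (BED convention): `start` is the 0-based first base, `end` is one past
#' the last base, `length = end - start`.  User-facing region strings
#' (`"chr2:113940058-114049496"`) follow the 1-based inclusive convention
#' used in genome browsers and publications; [parse_region_string()] and
#' [format_region()] convert between the two, and the conversion is
#' involutive.
#'
#' @param seqname character vector of sequence names.
#' @param start 0-based inclusive start coordinates.
#' @param end exclusive end coordinates; must satisfy `start < end`.
#' @param strand strand, one of `"+"`, `"-"`, `"."`.
#' @return a `data.frame` with columns `seqname`, `start`, `end`, `strand`.
#' @examples
#' genomic_interval("chr2", 100, 200)
#' @export
genomic_interval <- function(seqname, start, end, strand = ".") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-numeric interval coordinates")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval requires start < end")
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  data.frame(seqname = as.character(seqname), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Interval length in bp
#'
#' @param x interval data.frame from [genomic_interval()].
#' @return numeric vector of lengths (`end - start`).
#' @export
interval_length <- function(x) x$end - x$start

#' Parse a 1-based inclusive region string
#'
#' Accepts `"name:start-end"` with either an ASCII hyphen or the en-dash
#' that print typography uses.  The returned interval is 0-based half-open,
#' so its length equals `end - start + 1` of the 1-based string.
#'
#' @param text region string, e.g. `"chr2:113940058-114049496"`.
#' @return one-row interval data.frame.
#' @examples
#' r <- parse_region_string("chr2:113940058-114049496")
#' interval_length(r)  # 109439 bp, the ~109 kbp fusion site
#' @export
parse_region_string <- function(text) {
  stopifnot(length(text) == 1, is.character(text))
  text <- gsub("–", "-", text)     # en-dash
  text <- gsub(",", "", text)
  m <- regmatches(text, regexec("^(.+):([0-9]+)-([0-9]+)$", text))[[1]]
  if (length(m) != 4)
    stop("cannot parse region string: ", text)
  s1 <- as.numeric(m[3])
  e1 <- as.numeric(m[4])
  if (s1 < 1) stop("1-based region start must be >= 1")
  if (s1 > e1) stop("region start exceeds end: ", text)
  genomic_interval(m[2], s1 - 1, e1)
}

#' Format an interval as a 1-based inclusive region string
#'
#' @param x one-row interval data.frame.
#' @return character region string.
#' @export
format_region <- function(x) {
  stopifnot(nrow(x) == 1)
  sprintf("%s:%d-%d", x$seqname, as.integer(x$start) + 1L, as.integer(x$end))
}

# intervals (single seqname) -> IRanges (1-based closed)
to_iranges <- function(x) {
  IRanges::IRanges(start = as.integer(x$start) + 1L, end = as.integer(x$end))
}

from_iranges <- function(ir, seqname = "seq") {
  if (length(ir) == 0)
    return(data.frame(seqname = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  genomic_interval(seqname, IRanges::start(ir) - 1L, IRanges::end(ir))
}

# union-reduce intervals on one seqname, returns 0-based half-open df
reduce_intervals <- function(x, seqname = "seq") {
  from_iranges(IRanges::reduce(to_iranges(x)), seqname)
}
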