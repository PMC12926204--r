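#' Read a FASTA file
#'
#' @param path path to a FASTA file, optionally gzip-compressed.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs)) seqs <- unlist(seqs)
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a BED file
#'
#' BED is 0-based half-open, which is also the internal convention, so
#' coordinates pass through unchanged.  Columns beyond the sixth are
#' ignored; missing optional columns are filled with defaults.  Unsorted
#' input is accepted but flagged with a warning.
#'
#' @param path path to a BED(.gz) file.
#' @return data.frame with columns `seqname`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  con <- file(path)
  lines <- readLines(con)
  close(con)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(seqname = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  start <- suppressWarnings(as.numeric(get(2, NA)))
  end <- suppressWarnings(as.numeric(get(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  out <- data.frame(seqname = get(1, NA), start = start, end = end,
                    name = get(4, "."),
                    score = suppressWarnings(as.numeric(get(5, "0"))),
                    strand = get(6, "."), stringsAsFactors = FALSE)
  ord <- order(out$seqname, out$start)
  if (!identical(ord, seq_len(nrow(out))))
    warning("BED file is not coordinate-sorted")
  out
}

#' Write a BED file
#'
#' @param x data.frame with at least `seqname`, `start`, `end`; optional
#'   `name`, `score`, `strand` columns are emitted when present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- data.frame(x$seqname, format(x$start, scientific = FALSE, trim = TRUE),
                     format(x$end, scientific = FALSE, trim = TRUE))
  for (opt in c("name", "score", "strand"))
    if (opt %in% names(x)) cols <- cbind(cols, x[[opt]])
  write.table(cols, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

PAF_CORE <- c("query_name", "query_len", "query_start", "query_end", "strand",
              "target_name", "target_len", "target_start", "target_end",
              "matches", "block_len", "mapq")

#' Read a PAF alignment file (core columns plus cg/dv tags)
#'
#' Only block-level fields are retained; the CIGAR (`cg`) and divergence
#' (`dv`) tags are kept as strings when present.
#'
#' @param path path to a PAF(.gz) file.
#' @return data.frame with the 12 standard PAF columns plus `cg` and `dv`.
#' @export
read_paf <- function(path) {
  con <- file(path)
  lines <- readLines(con)
  close(con)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop("malformed PAF line ", which(nf < 12)[1], ": fewer than 12 fields")
  core <- t(vapply(fields, function(f) f[1:12], character(12)))
  out <- data.frame(core, stringsAsFactors = FALSE)
  names(out) <- PAF_CORE
  num <- c(2, 3, 4, 7, 8, 9, 10, 11, 12)
  for (i in num) out[[i]] <- as.numeric(out[[i]])
  tagval <- function(f, tag) {
    hit <- grep(paste0("^", tag, ":"), f, value = TRUE)
    if (length(hit)) sub("^..:.:", "", hit[1]) else NA_character_
  }
  out$cg <- vapply(fields, tagval, "", tag = "cg")
  out$dv <- vapply(fields, tagval, "", tag = "dv")
  bad <- with(out, query_start >= query_end | target_start >= target_end |
                query_end > query_len | target_end > target_len |
                matches > block_len)
  if (any(bad))
    stop("malformed PAF line ", which(bad)[1], ": inconsistent coordinates")
  out
}

#' Write a PAF alignment file
#'
#' @param x data.frame as returned by [read_paf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(x, path) {
  lines <- apply(x[, PAF_CORE], 1, function(r)
    paste(trimws(format(r, scientific = FALSE)), collapse = "\t"))
  if ("cg" %in% names(x)) {
    has <- !is.na(x$cg)
    lines[has] <- paste0(lines[has], "\tcg:Z:", x$cg[has])
  }
  if ("dv" %in% names(x)) {
    has <- !is.na(x$dv)
    lines[has] <- paste0(lines[has], "\tdv:f:", x$dv[has])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedMethyl-style methylation track
#'
#' Five tab-separated columns: chrom, start (0-based), end, coverage,
#' methylation frequency in `[0, 1]`.
#'
#' @param path path to the track file.
#' @return data.frame with columns `seqname`, `start`, `end`, `coverage`,
#'   `frequency`.
#' @export
read_bedmethyl <- function(path) {
  out <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("seqname", "start", "end", "coverage",
                                  "frequency"),
                    colClasses = c("character", "numeric", "numeric",
                                   "numeric", "numeric"))
  if (any(out$frequency < 0 | out$frequency > 1))
    stop("methylation frequency outside [0, 1]")
  if (any(out$coverage < 0)) stop("negative coverage")
  out
}

#' Write a bedMethyl-style methylation track
#'
#' @param x data.frame as returned by [read_bedmethyl()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(x, path) {
  write.table(data.frame(x$seqname,
                         format(x$start, scientific = FALSE, trim = TRUE),
                         format(x$end, scientific = FALSE, trim = TRUE),
                         x$coverage, x$frequency),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a Newick tree file
#'
#' @param path path to a Newick file.
#' @return an `ape::phylo` object (or `multiPhylo` for several trees).
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write trees in Newick format
#'
#' Branch lengths are preserved to 10 significant digits.
#'
#' @param tree an `ape::phylo` or `multiPhylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
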