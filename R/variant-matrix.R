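#' Haplotype variant matrix
#'
#' Container for a panel of phased haplotypes at biallelic sites: a matrix
#' over `{0, 1, NA}` with one row per haplotype and one column per site,
#' strictly increasing 0-based site positions, and a sequence name.
#'
#' @param mat integer matrix of alleles (haplotypes x sites), values 0, 1
#'   or `NA` for missing.
#' @param positions 0-based site positions, strictly increasing, one per
#'   matrix column.
#' @param seqname name of the reference sequence the positions refer to.
#' @param samples haplotype names; defaults to `hap1..hapN`.
#' @return an object of class `variant_matrix`.
#' @export
variant_matrix <- function(mat, positions, seqname = "chr1", samples = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (ncol(mat) != length(positions))
    stop("one position per matrix column required")
  if (is.unsorted(positions, strictly = TRUE) && length(positions) > 1)
    stop("positions must be strictly increasing")
  if (!all(mat %in% c(0L, 1L, NA)))
    stop("alleles must be 0, 1 or NA")
  samples <- samples %||% sprintf("hap%d", seq_len(nrow(mat)))
  if (length(samples) != nrow(mat))
    stop("one sample name per haplotype required")
  rownames(mat) <- samples
  structure(list(mat = mat, positions = as.numeric(positions),
                 seqname = seqname, samples = samples),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("variant_matrix: %d haplotypes x %d sites on %s\n",
              nrow(x$mat), ncol(x$mat), x$seqname))
  invisible(x)
}

#' Number of haplotypes / sites in a variant matrix
#' @param vm a [variant_matrix()].
#' @return integer count.
#' @export
n_haplotypes <- function(vm) nrow(vm$mat)

#' @rdname n_haplotypes
#' @export
n_sites <- function(vm) ncol(vm$mat)

#' Read a minimal GT-only VCF into a variant matrix
#'
#' Only the GT field is used.  Phased diploid genotypes are split into two
#' haplotypes per sample; haploid genotypes give one.  Multiallelic sites
#' are skipped (default, logged) or split into one record per alternate
#' allele depending on `multiallelic`.
#'
#' @param path path to a VCF(.gz) file.
#' @param multiallelic `"skip"` (default) or `"split"`.
#' @return a [variant_matrix()].
#' @export
read_vcf <- function(path, multiallelic = c("skip", "split")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  gt <- vcfR::extract.gt(v, element = "GT")
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    if (multiallelic == "skip") {
      fs_log("skipping %d multiallelic sites", sum(multi))
      fix <- fix[!multi, , drop = FALSE]
      gt <- gt[!multi, , drop = FALSE]
    } else {
      stop("multiallelic = 'split' not supported for this reader; ",
           "normalise the VCF first")
    }
  }
  if (nrow(fix) == 0) stop("no biallelic sites in VCF")
  ploidy <- max(lengths(strsplit(gt[1, ], "[|/]")))
  split_gt <- function(col) {
    parts <- strsplit(col, "[|/]")
    parts <- lapply(parts, function(p) {
      p[p == "."] <- NA
      out <- suppressWarnings(as.integer(p))
      length(out) <- ploidy
      out
    })
    do.call(cbind, parts)  # ploidy x nsites
  }
  haps <- list()
  hnames <- character(0)
  for (s in colnames(gt)) {
    m <- split_gt(gt[, s])
    for (k in seq_len(nrow(m))) {
      haps[[length(haps) + 1L]] <- m[k, ]
      hnames <- c(hnames,
                  if (nrow(m) == 1) s else sprintf("%s_h%d", s, k))
    }
  }
  mat <- do.call(rbind, haps)
  keep <- !vapply(seq_len(nrow(mat)), function(i) all(is.na(mat[i, ])),
                  logical(1))
  variant_matrix(mat[keep, , drop = FALSE],
                 positions = as.numeric(fix[, "POS"]) - 1,
                 seqname = fix[1, "CHROM"], samples = hnames[keep])
}

#' Write a variant matrix as a minimal GT-only VCF
#'
#' Haplotypes are written as haploid samples by default; with
#' `diploid = TRUE` consecutive haplotype pairs are joined into phased
#' diploid genotypes.
#'
#' @param vm a [variant_matrix()].
#' @param path output path.
#' @param diploid join haplotype pairs into phased diploid samples.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vm, path, diploid = FALSE) {
  mat <- vm$mat
  pos1 <- format(vm$positions + 1, scientific = FALSE, trim = TRUE)
  gt <- apply(mat, 2, function(col) {
    col <- ifelse(is.na(col), ".", as.character(col))
    if (diploid) {
      if (length(col) %% 2 != 0)
        stop("diploid output needs an even number of haplotypes")
      paste(col[c(TRUE, FALSE)], col[c(FALSE, TRUE)], sep = "|")
    } else col
  })
  gt <- if (is.matrix(gt)) t(gt) else matrix(gt, ncol = 1)
  snames <- if (diploid)
    sprintf("sample%d", seq_len(nrow(mat) / 2)) else vm$samples
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", vm$seqname),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", snames), collapse = "\t"))
  body <- vapply(seq_along(vm$positions), function(j)
    paste(c(vm$seqname, pos1[j], ".", "A", "T", ".", "PASS", ".", "GT",
            gt[j, ]), collapse = "\t"), "")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(c(header, body), con)
  close(con)
  invisible(path)
}
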