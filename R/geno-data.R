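#' Genotype dataset container
#'
#' A `geno_data` object bundles the three tables every stage of the HRR
#' workflow consumes: the genotype matrix, the SNP map and the sample table.
#' Genotypes are coded by zygosity: `0` = homozygous for the SNP's first
#' allele, `1` = heterozygous, `2` = homozygous for the second allele and
#' `NA` = missing.  Heterozygosity analyses only use zygosity, so the
#' polarity of the 0/2 coding never affects run detection.
#'
#' @param geno integer matrix, individuals in rows and SNPs in columns, with
#'   values in `{0, 1, 2, NA}`.  Row names are sample ids, column names SNP
#'   ids.
#' @param map data frame with columns `snp_id`, `chrom`, `pos_bp` (1-based
#'   base-pair position) and optionally `allele1`, `allele2`.  One row per
#'   genotype column, in column order; positions must be sorted within
#'   chromosome.
#' @param samples data frame with columns `sample_id`, `breed` and optionally
#'   `group` (geographic group).  One row per genotype row, in row order.
#'
#' @return An object of class `geno_data`.
#' @export
geno_data <- function(geno, map, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(map$allele1)) map$allele1 <- NA_character_
  if (is.null(map$allele2)) map$allele2 <- NA_character_
  if (is.null(samples$group)) samples$group <- NA_character_
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.integer(map$pos_bp)
  rownames(geno) <- samples$sample_id
  colnames(geno) <- map$snp_id
  x <- structure(list(geno = geno, map = map, samples = samples),
                 class = "geno_data")
  validate_geno_data(x)
  x
}

validate_geno_data <- function(x) {
  stopifnot(inherits(x, "geno_data"))
  if (nrow(x$geno) != nrow(x$samples))
    stop("genotype rows (", nrow(x$geno), ") != sample table rows (",
         nrow(x$samples), ")")
  if (ncol(x$geno) != nrow(x$map))
    stop("genotype columns (", ncol(x$geno), ") != map rows (",
         nrow(x$map), ")")
  bad <- x$geno[!is.na(x$geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (anyDuplicated(x$map$snp_id))
    stop("duplicate snp_id in map")
  if (anyDuplicated(x$samples$sample_id))
    stop("duplicate sample_id in sample table")
  if (any(!nzchar(x$samples$breed) | is.na(x$samples$breed)))
    stop("every sample needs a nonempty breed code")
  # positions strictly increasing within chromosome blocks
  for (ch in unique(x$map$chrom)) {
    p <- x$map$pos_bp[x$map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  invisible(x)
}

#' @export
print.geno_data <- function(x, ...) {
  cat("geno_data:", nrow(x$geno), "individuals x", ncol(x$geno), "SNPs\n")
  cat("  chromosomes:", paste(unique(x$map$chrom), collapse = ", "), "\n")
  cat("  breeds:", length(unique(x$samples$breed)),
      " missing rate:", signif(mean(is.na(x$geno)), 3), "\n")
  invisible(x)
}

#' @export
summary.geno_data <- function(object, ...) {
  het <- colMeans(object$geno == 1L, na.rm = TRUE)
  out <- list(
    n_ind = nrow(object$geno),
    n_snp = ncol(object$geno),
    n_breed = length(unique(object$samples$breed)),
    missing_rate = mean(is.na(object$geno)),
    mean_het = mean(het, na.rm = TRUE))
  class(out) <- "summary.geno_data"
  out
}

#' @export
print.summary.geno_data <- function(x, ...) {
  cat("geno_data summary\n")
  cat("  individuals :", x$n_ind, "\n")
  cat("  SNPs        :", x$n_snp, "\n")
  cat("  breeds      :", x$n_breed, "\n")
  cat("  missing rate:", signif(x$missing_rate, 4), "\n")
  cat("  mean per-SNP heterozygosity:", signif(x$mean_het, 4), "\n")
  invisible(x)
}

#' Subset a genotype dataset
#'
#' @param x a [geno_data] object.
#' @param samples logical/integer/character index of individuals to keep.
#' @param snps logical/integer/character index of SNPs to keep.
#' @return the subsetted `geno_data`.
#' @export
subset_geno <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "geno_data"))
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, x$samples$sample_id)
    x$geno <- x$geno[samples, , drop = FALSE]
    x$samples <- x$samples[samples, , drop = FALSE]
    rownames(x$samples) <- NULL
  }
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, x$map$snp_id)
    x$geno <- x$geno[, snps, drop = FALSE]
    x$map <- x$map[snps, , drop = FALSE]
    rownames(x$map) <- NULL
  }
  x
}

#' Attach geographic groups to samples
#'
#' @param x a [geno_data] object.
#' @param groups data frame with columns `breed` and `group`, or a named
#'   character vector mapping breed code to group label.
#' @return `x` with `samples$group` filled in.
#' @export
set_groups <- function(x, groups) {
  stopifnot(inherits(x, "geno_data"))
  if (is.data.frame(groups)) {
    g <- stats::setNames(as.character(groups$group), groups$breed)
  } else {
    g <- groups
  }
  x$samples$group <- unname(g[x$samples$breed])
  x
}
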