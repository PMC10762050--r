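#' Merge genotype datasets on their common SNPs
#'
#' Takes two or more [geno_data] objects (for example, separate genotyping
#' cohorts), restricts to the intersection of SNP ids, harmonizes allele
#' coding (a SNP stored with `allele1`/`allele2` swapped in a later part has
#' its codes flipped `0 <-> 2` to match the first part), concatenates the
#' samples, and sorts SNPs by (chromosome, position).  SNPs whose allele sets
#' cannot be reconciled across parts are dropped, with the count reported as
#' attribute `"n_dropped_alleles"`.
#'
#' @param ... two or more `geno_data` objects, or a single list of them.
#' @return a merged `geno_data` object.
#' @export
merge_geno <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "geno_data"))
    parts <- parts[[1]]
  if (length(parts) < 2L) stop("need at least two datasets to merge")
  lapply(parts, validate_geno_data)

  common <- Reduce(intersect, lapply(parts, function(p) p$map$snp_id))
  if (length(common) == 0L) stop("no common markers across datasets")

  ids <- unlist(lapply(parts, function(p) p$samples$sample_id))
  if (anyDuplicated(ids))
    stop("duplicate sample_id across parts: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  ref <- parts[[1]]
  ref_idx <- match(common, ref$map$snp_id)
  ref_map <- ref$map[ref_idx, , drop = FALSE]

  keep <- rep(TRUE, length(common))
  genos <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    idx <- match(common, p$map$snp_id)
    g <- p$geno[, idx, drop = FALSE]
    if (k > 1L) {
      p1 <- p$map$allele1[idx]; p2 <- p$map$allele2[idx]
      r1 <- ref_map$allele1;    r2 <- ref_map$allele2
      eqna <- function(a, b) is.na(a) | is.na(b) | a == b  # compatible labels
      same    <- eqna(p1, r1) & eqna(p2, r2) & !(!is.na(p1) & !is.na(r2) & p1 == r2)
      swapped <- !is.na(p1) & !is.na(r2) & p1 == r2 & eqna(p2, r1)
      swapped[same] <- FALSE
      bad <- !(same | swapped)
      if (any(swapped))
        g[, swapped] <- 2L - g[, swapped, drop = FALSE]
      keep <- keep & !bad
    }
    genos[[k]] <- g
  }
  n_bad <- sum(!keep)
  if (all(!keep)) stop("no common markers with reconcilable alleles")

  geno <- do.call(rbind, lapply(genos, function(g) g[, keep, drop = FALSE]))
  map <- ref_map[keep, , drop = FALSE]
  samples <- do.call(rbind, lapply(parts, function(p) p$samples))
  ord <- order(suppressWarnings(as.numeric(map$chrom)), map$chrom, map$pos_bp)
  out <- geno_data(geno[, ord, drop = FALSE], map[ord, , drop = FALSE],
                   samples)
  attr(out, "n_dropped_alleles") <- n_bad
  out
}

#' Quality-control parameter set
#'
#' Defaults follow the conventional SNP-array filters for diversity studies:
#' minor allele frequency >= 0.05, SNP call rate >= 0.95 and individual call
#' rate >= 0.80, restricted to mapped autosomal markers.
#'
#' @param min_maf minimum minor allele frequency retained.
#' @param max_snp_missing maximum per-SNP missing fraction retained.
#' @param max_ind_missing maximum per-individual missing fraction retained.
#' @param autosomes_only drop unmapped and non-autosomal SNPs first?
#' @param autosomes chromosome labels regarded as autosomes (goat: 1..29).
#' @return an object of class `qc_params`.
#' @export
qc_params <- function(min_maf = 0.05, max_snp_missing = 0.05,
                      max_ind_missing = 0.20, autosomes_only = TRUE,
                      autosomes = as.character(1:29)) {
  stopifnot(min_maf >= 0, min_maf <= 1,
            max_snp_missing >= 0, max_snp_missing <= 1,
            max_ind_missing >= 0, max_ind_missing <= 1)
  structure(list(min_maf = min_maf, max_snp_missing = max_snp_missing,
                 max_ind_missing = max_ind_missing,
                 autosomes_only = autosomes_only, autosomes = autosomes),
            class = "qc_params")
}

#' Apply quality control to a genotype dataset
#'
#' Filters in a fixed order: (1) unmapped and non-autosomal SNPs, (2)
#' individuals exceeding the missing-genotype threshold, (3) SNPs exceeding
#' the missing threshold, (4) SNPs below the MAF threshold (MAF computed on
#' the remaining individuals).  The order matters because allele frequencies
#' shift when individuals are removed; it is therefore fixed and reported.
#'
#' @param x a [geno_data] object.
#' @param params a [qc_params] object.
#' @return a list with elements `data` (filtered `geno_data`) and `report`
#'   (data frame of per-step removal counts).
#' @export
apply_qc <- function(x, params = qc_params()) {
  stopifnot(inherits(x, "geno_data"), inherits(params, "qc_params"))
  n0 <- nrow(x$geno); m0 <- ncol(x$geno)

  # 1. unmapped / sex-chromosome SNPs
  if (params$autosomes_only) {
    keep_snp <- x$map$chrom %in% params$autosomes &
      !is.na(x$map$pos_bp) & x$map$pos_bp > 0
  } else {
    keep_snp <- !is.na(x$map$pos_bp) & x$map$pos_bp > 0
  }
  n_unmapped <- sum(!keep_snp)
  x <- subset_geno(x, snps = which(keep_snp))
  if (ncol(x$geno) == 0L) stop("all SNPs removed (autosome/mapping filter)")

  # 2. individuals by call rate
  ind_miss <- rowMeans(is.na(x$geno))
  keep_ind <- ind_miss <= params$max_ind_missing
  n_ind_rm <- sum(!keep_ind)
  x <- subset_geno(x, samples = which(keep_ind))
  if (nrow(x$geno) == 0L) stop("all individuals removed (call-rate filter)")

  # 3. SNPs by call rate
  snp_miss <- colMeans(is.na(x$geno))
  keep_snp <- snp_miss <= params$max_snp_missing
  n_snp_miss <- sum(!keep_snp)
  x <- subset_geno(x, snps = which(keep_snp))
  if (ncol(x$geno) == 0L) stop("all SNPs removed (call-rate filter)")

  # 4. SNPs by MAF on remaining individuals
  maf <- snp_maf(x$geno)
  keep_snp <- !is.na(maf) & maf >= params$min_maf
  n_snp_maf <- sum(!keep_snp)
  x <- subset_geno(x, snps = which(keep_snp))
  if (ncol(x$geno) == 0L) stop("all SNPs removed (MAF filter)")

  report <- data.frame(
    step = c("unmapped_or_sex_snps", "individuals_call_rate",
             "snps_call_rate", "snps_maf"),
    removed = c(n_unmapped, n_ind_rm, n_snp_miss, n_snp_maf),
    unit = c("snp", "individual", "snp", "snp"),
    stringsAsFactors = FALSE)
  attr(report, "n_in") <- c(individuals = n0, snps = m0)
  attr(report, "n_out") <- c(individuals = nrow(x$geno), snps = ncol(x$geno))
  list(data = x, report = report)
}

# pooled per-SNP minor allele frequency of a code matrix
snp_maf <- function(g) {
  ncall <- colSums(!is.na(g))
  p <- (2 * colSums(g == 0L, na.rm = TRUE) + colSums(g == 1L, na.rm = TRUE)) /
    (2 * ncall)
  p[ncall == 0L] <- NA_real_
  pmin(p, 1 - p)
}

#' Randomly subsample large breeds to a maximum size
#'
#' Breeds with at most `max_n` individuals are kept untouched; larger breeds
#' are reduced to exactly `max_n` by uniform sampling without replacement.
#' The within-breed sample order of the input is preserved.
#'
#' @param x a [geno_data] object.
#' @param max_n maximum number of individuals retained per breed.
#' @param seed integer seed driving the random selection.
#' @return the subsampled `geno_data`.
#' @export
subsample_breeds <- function(x, max_n = 30, seed) {
  stopifnot(inherits(x, "geno_data"), max_n >= 1)
  if (missing(seed)) stop("a seed is required for reproducible subsampling")
  keep <- with_seed(seed, {
    sel <- logical(nrow(x$samples))
    for (b in unique(x$samples$breed)) {
      idx <- which(x$samples$breed == b)
      if (length(idx) <= max_n) sel[idx] <- TRUE
      else sel[sort(sample(idx, max_n))] <- TRUE
    }
    sel
  })
  subset_geno(x, samples = which(keep))
}
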