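#' Per-breed per-SNP allele frequencies
#'
#' Computes, within each breed, the frequency `p` of each SNP's first allele
#' (`p = (2 n_hom1 + n_het) / (2 n_called)`) together with the number of
#' individuals called.  A SNP with no called genotypes in a breed gets `NA`.
#'
#' @param x a [geno_data] object.
#' @return a list with matrices `p` (breeds x SNPs, first-allele frequency)
#'   and `n_called` (breeds x SNPs, called individuals), breed codes as row
#'   names.
#' @export
breed_freqs <- function(x) {
  stopifnot(inherits(x, "geno_data"))
  breeds <- unique(x$samples$breed)
  m <- ncol(x$geno)
  p <- matrix(NA_real_, length(breeds), m,
              dimnames = list(breeds, colnames(x$geno)))
  nc <- matrix(0L, length(breeds), m, dimnames = dimnames(p))
  for (b in breeds) {
    g <- x$geno[x$samples$breed == b, , drop = FALSE]
    ncall <- colSums(!is.na(g))
    pj <- (2 * colSums(g == 0L, na.rm = TRUE) +
             colSums(g == 1L, na.rm = TRUE)) / (2 * ncall)
    pj[ncall == 0L] <- NA_real_
    p[b, ] <- pj
    nc[b, ] <- ncall
  }
  list(p = p, n_called = nc)
}

#' Per-breed genetic diversity indices
#'
#' For every breed, computes the mean observed heterozygosity `Ho` (per-SNP
#' fraction of heterozygous calls), the mean expected heterozygosity `He`
#' (per-SNP `2p(1-p)` from within-breed frequencies), the mean molecular
#' inbreeding coefficient `Fis` (mean over individuals of the
#' observed-vs-expected homozygosity excess, see [inbreeding_coef]) and the
#' mean minor allele frequency `MAF`.  Means over SNPs are unweighted and
#' skip SNPs with no calls in the breed.
#'
#' @param x a [geno_data] object.
#' @param pooled_freqs use whole-dataset allele frequencies inside the
#'   inbreeding expectation instead of within-breed frequencies.
#' @return data frame with columns `breed`, `n_ind`, `Ho`, `He`, `Fis`,
#'   `MAF`.
#' @export
breed_diversity <- function(x, pooled_freqs = FALSE) {
  stopifnot(inherits(x, "geno_data"))
  fr <- breed_freqs(x)
  breeds <- rownames(fr$p)
  Fi <- inbreeding_coef(x, pooled_freqs = pooled_freqs)
  out <- data.frame(breed = breeds, n_ind = NA_integer_, Ho = NA_real_,
                    He = NA_real_, Fis = NA_real_, MAF = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(breeds)) {
    b <- breeds[k]
    g <- x$geno[x$samples$breed == b, , drop = FALSE]
    ncall <- colSums(!is.na(g))
    hobs <- colSums(g == 1L, na.rm = TRUE) / ncall
    p <- fr$p[b, ]
    hexp <- 2 * p * (1 - p)
    ok <- ncall > 0L
    out$n_ind[k] <- nrow(g)
    out$Ho[k] <- mean(hobs[ok])
    out$He[k] <- mean(hexp[ok])
    out$MAF[k] <- mean(pmin(p[ok], 1 - p[ok]))
    out$Fis[k] <- mean(Fi$F[x$samples$breed == b], na.rm = TRUE)
  }
  out
}

#' Molecular inbreeding coefficient per individual
#'
#' Method-of-moments estimator of individual inbreeding from excess
#' homozygosity: `F = (O_hom - E_hom) / (L - E_hom)`, where `O_hom` is the
#' individual's observed homozygous count over its `L` called SNPs and
#' `E_hom` sums, over the same SNPs, `1 - 2p(1-p) * 2n/(2n-1)` with `p` the
#' within-breed allele frequency and `n` the breed's called-individual count
#' at the SNP (the `2n/(2n-1)` factor is the small-sample correction of the
#' expected heterozygosity).
#'
#' @param x a [geno_data] object.
#' @param pooled_freqs use whole-dataset frequencies/counts instead of
#'   within-breed ones.
#' @return a list with `F` (numeric vector, one value per individual, `NA`
#'   where undefined, i.e. `L - E_hom <= 0`) and the per-individual `O_hom`,
#'   `E_hom`, `L` used.
#' @export
inbreeding_coef <- function(x, pooled_freqs = FALSE) {
  stopifnot(inherits(x, "geno_data"))
  n_ind <- nrow(x$geno)
  ehom_mat <- function(g) {
    # per-SNP expected-homozygosity contribution for a group's matrix
    ncall <- colSums(!is.na(g))
    p <- (2 * colSums(g == 0L, na.rm = TRUE) +
            colSums(g == 1L, na.rm = TRUE)) / (2 * ncall)
    e <- 1 - 2 * p * (1 - p) * (2 * ncall) / (2 * ncall - 1)
    e[ncall == 0L] <- NA_real_
    e
  }
  O <- rowSums(x$geno == 0L | x$geno == 2L, na.rm = TRUE)
  L <- rowSums(!is.na(x$geno))
  E <- numeric(n_ind)
  if (pooled_freqs) {
    e <- ehom_mat(x$geno)
    e0 <- ifelse(is.na(e), 0, e)
    E <- as.numeric((!is.na(x$geno)) %*% e0)
  } else {
    for (b in unique(x$samples$breed)) {
      idx <- x$samples$breed == b
      g <- x$geno[idx, , drop = FALSE]
      e <- ehom_mat(g)
      e0 <- ifelse(is.na(e), 0, e)
      E[idx] <- as.numeric((!is.na(g)) %*% e0)
    }
  }
  denom <- unname(L - E)
  O <- unname(O); L <- unname(L); E <- unname(E)
  F <- ifelse(denom > 0, (O - E) / denom, NA_real_)
  if (anyNA(F))
    message(sum(is.na(F)), " individual(s) with undefined F excluded")
  list(F = F, O_hom = O, E_hom = E, L = L,
       sample_id = x$samples$sample_id)
}

#' Average diversity indices per geographic group
#'
#' @param div a data frame from [breed_diversity].
#' @param x the [geno_data] the table was computed from (provides the
#'   breed-to-group mapping), or a data frame with columns `breed`, `group`.
#' @return data frame of unweighted breed means per group.
#' @export
group_diversity <- function(div, x) {
  map <- if (inherits(x, "geno_data")) {
    unique(x$samples[, c("breed", "group")])
  } else unique(x[, c("breed", "group")])
  if (anyDuplicated(map$breed))
    stop("a breed maps to more than one group")
  grp <- map$group[match(div$breed, map$breed)]
  if (anyNA(grp)) stop("breed(s) without a group: ",
                       paste(div$breed[is.na(grp)], collapse = ", "))
  agg <- stats::aggregate(div[, c("Ho", "He", "Fis", "MAF")],
                          by = list(group = grp), FUN = mean)
  nb <- as.data.frame(table(group = grp), stringsAsFactors = FALSE)
  agg$n_breeds <- nb$Freq[match(agg$group, nb$group)]
  agg[, c("group", "n_breeds", "Ho", "He", "Fis", "MAF")]
}

#' Write a diversity table as TSV
#'
#' Fixed column order: breed, n, Ho, He, Fis, MAF.
#'
#' @param div a data frame from [breed_diversity].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_diversity <- function(div, path) {
  utils::write.table(div[, c("breed", "n_ind", "Ho", "He", "Fis", "MAF")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
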