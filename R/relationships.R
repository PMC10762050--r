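#' Pairwise identity-by-state distances between individuals
#'
#' For each pair of individuals, over the SNPs called in both, the allele
#' sharing of a genotype pair with codes `a`, `b` is `2 - |a - b|` (identical
#' genotypes - including het vs het - share 2 alleles, het vs hom shares 1,
#' opposite homozygotes share 0).  Similarity is total shared alleles over
#' `2 x` co-called SNPs; the IBS distance is `1 -` similarity.
#'
#' @param x a [geno_data] object.
#' @return a symmetric distance matrix with sample ids as dimnames.
#' @export
ibs_dist <- function(x) {
  stopifnot(inherits(x, "geno_data"))
  g <- x$geno
  n <- nrow(g)
  if (n < 2L) stop("need at least 2 individuals")
  d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1L)) {
    gi <- g[i, ]
    for (j in (i + 1L):n) {
      diffs <- abs(gi - g[j, ])
      ok <- !is.na(diffs)
      if (!any(ok))
        stop("no co-called SNPs for pair ", rownames(g)[i], " / ",
             rownames(g)[j])
      dij <- sum(diffs[ok]) / (2 * sum(ok))
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Classical (Torgerson) multidimensional scaling of a distance matrix
#'
#' Double-centers the squared distances, eigendecomposes, and returns the
#' top-`k` coordinates (eigenvectors scaled by the square root of their
#' eigenvalues).  The variance explained by component `i` is `lambda_i`
#' divided by the sum of the positive eigenvalues.  Component signs are
#' fixed so that each component's largest-magnitude loading is positive.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param k number of components to keep (`k <= n - 1`).
#' @return an object of class `mds_result`: list with `coords` (n x k),
#'   `var_explained` (length k) and `eig` (all eigenvalues).
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(k >= 1, k <= n - 1)
  if (all(d == 0)) stop("all distances are zero")
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  coords <- fit$points
  # cmdscale can return fewer columns than requested when eigenvalues <= 0
  if (ncol(coords) < k) {
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  for (j in seq_len(ncol(coords))) {
    s <- sign(coords[which.max(abs(coords[, j])), j])
    if (!is.na(s) && s < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("C", seq_len(ncol(coords)))
  pos <- fit$eig[fit$eig > 0]
  var_explained <- pmax(fit$eig[seq_len(k)], 0) / sum(pos)
  structure(list(coords = coords, var_explained = var_explained,
                 eig = fit$eig), class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat("classical MDS:", nrow(x$coords), "points,", ncol(x$coords),
      "components\n")
  cat("  variance explained:",
      paste0(sprintf("C%d=%.2f%%", seq_along(x$var_explained),
                     100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Reynolds' genetic distance between populations
#'
#' Least-squares coancestry estimate from biallelic allele frequencies: for
#' populations A and B,
#' `theta = sum_l (pA - pB)^2 / sum_l (pA + pB - 2 pA pB)`,
#' with sums over loci with non-missing frequencies in both populations.
#' The default applies no sample-size correction; `corrected = TRUE` uses
#' the unbiased Reynolds-Weir-Cockerham numerator/denominator corrections
#' (requires per-population called counts).
#'
#' @param freqs a list as returned by [breed_freqs] (matrices `p` and
#'   `n_called`), or a plain breeds x SNPs frequency matrix.
#' @param corrected apply the sample-size-corrected estimator.
#' @return a symmetric distance matrix over populations.
#' @export
reynolds_dist <- function(freqs, corrected = FALSE) {
  if (is.list(freqs) && !is.data.frame(freqs)) {
    p <- freqs$p; nc <- freqs$n_called
  } else {
    p <- as.matrix(freqs); nc <- NULL
  }
  B <- nrow(p)
  if (B < 2L) stop("need at least 2 populations")
  if (corrected && is.null(nc))
    stop("corrected estimator needs per-population called counts")
  d <- matrix(0, B, B, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(B - 1L)) {
    for (j in (i + 1L):B) {
      ok <- !is.na(p[i, ]) & !is.na(p[j, ])
      pa <- p[i, ok]; pb <- p[j, ok]
      if (corrected) {
        # subtract the binomial sampling variance of each frequency
        # (unbiased estimate p(1-p)/(2n-1) from 2n sampled alleles)
        na <- nc[i, ok]; nb <- nc[j, ok]
        ok2 <- na >= 1 & nb >= 1
        pa <- pa[ok2]; pb <- pb[ok2]; na <- na[ok2]; nb <- nb[ok2]
        num <- sum((pa - pb)^2 - pa * (1 - pa) / (2 * na - 1) -
                     pb * (1 - pb) / (2 * nb - 1))
        den <- sum(pa + pb - 2 * pa * pb)
        if (den <= 0) stop("zero denominator for pair ", rownames(p)[i],
                           " / ", rownames(p)[j])
        d[i, j] <- d[j, i] <- max(num / den, 0)
      } else {
        num <- sum((pa - pb)^2)
        den <- sum(pa + pb - 2 * pa * pb)
        if (den <= 0) stop("zero denominator for pair ", rownames(p)[i],
                           " / ", rownames(p)[j],
                           " (both populations monomorphic everywhere)")
        d[i, j] <- d[j, i] <- num / den
      }
    }
  }
  d
}

#' Export a distance matrix in PHYLIP or NEXUS format
#'
#' PHYLIP output is the square format with labels sanitized to the 10-column
#' rule (truncation plus numeric suffixes on collision); NEXUS output is a
#' `DISTANCES` block with a full matrix, usable by split-network software.
#'
#' @param d symmetric distance matrix with dimnames.
#' @param path output file.
#' @param format `"phylip"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_dist <- function(d, path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  d <- as.matrix(d)
  labs <- sanitize_labels(rownames(d),
                          width = if (format == "phylip") 10L else 30L)
  n <- nrow(d)
  if (format == "phylip") {
    rows <- vapply(seq_len(n), function(i) {
      paste0(formatC(labs[i], width = -10), " ",
             paste(sprintf("%.6f", d[i, ]), collapse = " "))
    }, character(1))
    writeLines(c(sprintf("%5d", n), rows), path)
  } else {
    rows <- vapply(seq_len(n), function(i) {
      paste0("    ", labs[i], "\t",
             paste(sprintf("%.6f", d[i, ]), collapse = " "))
    }, character(1))
    writeLines(c("#NEXUS", "", "BEGIN TAXA;",
                 sprintf("  DIMENSIONS NTAX=%d;", n),
                 paste0("  TAXLABELS ", paste(labs, collapse = " "), ";"),
                 "END;", "", "BEGIN DISTANCES;",
                 sprintf("  DIMENSIONS NTAX=%d;", n),
                 "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;",
                 "  MATRIX", rows, "  ;", "END;"), path)
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' @param path file written by [write_dist] (or any square PHYLIP matrix).
#' @return a symmetric matrix with labels as dimnames.
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  labs <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1]), "[ \t]+")[[1]]
    labs[i] <- f[1]
    d[i, ] <- as.numeric(f[-1])
  }
  dimnames(d) <- list(labs, labs)
  d
}

# truncate labels, replace whitespace, disambiguate collisions with suffixes
sanitize_labels <- function(labs, width = 10L) {
  labs <- gsub("[^A-Za-z0-9_.]", "_", labs)
  labs <- substr(labs, 1L, width)
  while (anyDuplicated(labs)) {
    dup <- which(duplicated(labs) | duplicated(labs, fromLast = TRUE))
    for (k in seq_along(dup)) {
      suff <- as.character(k)
      labs[dup[k]] <- paste0(substr(labs[dup[k]], 1L, width - nchar(suff)),
                             suff)
    }
  }
  labs
}

#' Export MDS coordinates as TSV
#'
#' @param mds an [classical_mds] result.
#' @param x the [geno_data] the distances came from (for breed/group labels).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mds <- function(mds, x, path) {
  df <- data.frame(sample_id = rownames(mds$coords),
                   breed = x$samples$breed[match(rownames(mds$coords),
                                                 x$samples$sample_id)],
                   group = x$samples$group[match(rownames(mds$coords),
                                                 x$samples$sample_id)],
                   mds$coords, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# var_explained: ",
                    paste(sprintf("%.4f", mds$var_explained),
                          collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
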