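#' Per-individual run summaries
#'
#' Counts and lengths of detected runs per individual.  Individuals present
#' in the sample table but without any run are retained with `n_runs = 0`,
#' `mean_length_mbp = NA` and `total_length_mbp = 0`, so that breed means
#' account for them.
#'
#' @param runs a `run_table` from [detect_runs] (a single method).
#' @param x the [geno_data] the runs came from (defines the full sample
#'   list), or a data frame with columns `sample_id`, `breed`.
#' @return data frame with columns `sample_id`, `breed`, `n_runs`,
#'   `mean_length_mbp`, `total_length_mbp`.
#' @export
individual_hrr <- function(runs, x) {
  samples <- if (inherits(x, "geno_data")) x$samples else x
  out <- data.frame(sample_id = samples$sample_id, breed = samples$breed,
                    n_runs = 0L, mean_length_mbp = NA_real_,
                    total_length_mbp = 0, stringsAsFactors = FALSE)
  if (nrow(runs)) {
    if (length(unique(runs$method)) > 1L)
      stop("run table mixes methods; summarize one method at a time")
    agg_n <- table(runs$sample_id)
    agg_sum <- tapply(runs$length_bp, runs$sample_id, sum)
    agg_mean <- tapply(runs$length_bp, runs$sample_id, mean)
    idx <- match(names(agg_n), out$sample_id)
    if (anyNA(idx))
      stop("runs for sample(s) absent from the sample table: ",
           paste(names(agg_n)[is.na(idx)], collapse = ", "))
    out$n_runs[idx] <- as.integer(agg_n)
    out$total_length_mbp[idx] <- as.numeric(agg_sum) / 1e6
    out$mean_length_mbp[idx] <- as.numeric(agg_mean) / 1e6
  }
  out
}

#' Breed-level descriptive run statistics
#'
#' The four standard HRR descriptors per breed:
#' `N_HRR` = mean number of runs per individual; `L_HRR` = mean over
#' individuals of their mean run length (Mbp; individuals without runs are
#' excluded from this mean only); `S_HRR` = mean per-individual total genome
#' length in runs (Mbp); `D_HRR` = mean per-individual covered fraction of
#' the array-covered autosomal genome.  Standard deviations are over
#' individuals.
#'
#' @param runs a single-method `run_table`.
#' @param x the [geno_data] the runs came from; also supplies the default
#'   genome length (sum over chromosomes of last-minus-first SNP position).
#' @param genome_bp denominator for `D_HRR` in bp; overrides the map-derived
#'   default (e.g. `2.4e9` for a caprine 50k array).
#' @param pool_lengths compute `L_HRR` from the pooled set of runs instead
#'   of averaging per-individual means.
#' @return data frame with one row per breed: means and sds of the four
#'   descriptors plus `n_ind`.
#' @export
breed_hrr <- function(runs, x, genome_bp = NULL, pool_lengths = FALSE) {
  stopifnot(inherits(x, "geno_data"))
  if (is.null(genome_bp)) genome_bp <- genome_length(x)
  ind <- individual_hrr(runs, x)
  method <- if (nrow(runs)) runs$method[1] else NA_character_
  breeds <- unique(x$samples$breed)
  rows <- lapply(breeds, function(b) {
    d <- ind[ind$breed == b, , drop = FALSE]
    if (nrow(d) == 0L) {
      warning("breed ", b, " absent from runs; zero row emitted")
      return(data.frame(breed = b, method = method, n_ind = 0L,
                        N_HRR = 0, N_sd = NA, L_HRR = NA, L_sd = NA,
                        S_HRR = 0, S_sd = NA, D_HRR = 0, D_sd = NA))
    }
    lm <- d$mean_length_mbp[!is.na(d$mean_length_mbp)]
    L <- if (pool_lengths) {
      rr <- runs[runs$breed == b, , drop = FALSE]
      if (nrow(rr)) mean(rr$length_bp) / 1e6 else NA_real_
    } else if (length(lm)) mean(lm) else NA_real_
    data.frame(breed = b, method = method, n_ind = nrow(d),
               N_HRR = mean(d$n_runs), N_sd = stats::sd(d$n_runs),
               L_HRR = L,
               L_sd = if (length(lm) > 1) stats::sd(lm) else NA_real_,
               S_HRR = mean(d$total_length_mbp),
               S_sd = stats::sd(d$total_length_mbp),
               D_HRR = mean(d$total_length_mbp * 1e6 / genome_bp),
               D_sd = stats::sd(d$total_length_mbp * 1e6 / genome_bp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "genome_bp") <- genome_bp
  out
}

#' Array-covered autosomal genome length from the SNP map
#'
#' @param x a [geno_data] object.
#' @return sum over chromosomes of (last SNP position - first SNP position),
#'   in bp.
#' @export
genome_length <- function(x) {
  sum(tapply(x$map$pos_bp, x$map$chrom, function(p) max(p) - min(p)))
}

#' Aggregate breed run statistics by geographic group
#'
#' Unweighted mean and sd over the breeds of each group (the `AN/AL/AS/AD`
#' aggregates).
#'
#' @param b a breed summary from [breed_hrr].
#' @param x the [geno_data] (breed-to-group mapping) or a data frame with
#'   columns `breed`, `group`.
#' @return data frame with one row per group.
#' @export
group_hrr <- function(b, x) {
  map <- if (inherits(x, "geno_data")) unique(x$samples[, c("breed", "group")])
  else unique(x[, c("breed", "group")])
  if (anyDuplicated(map$breed)) stop("a breed maps to more than one group")
  grp <- map$group[match(b$breed, map$breed)]
  if (anyNA(grp)) stop("breed(s) without group: ",
                       paste(b$breed[is.na(grp)], collapse = ", "))
  rows <- lapply(unique(grp), function(g) {
    d <- b[grp == g, , drop = FALSE]
    data.frame(group = g, n_breeds = nrow(d),
               AN_HRR = mean(d$N_HRR), AN_sd = stats::sd(d$N_HRR),
               AL_HRR = mean(d$L_HRR, na.rm = TRUE),
               AL_sd = stats::sd(d$L_HRR[!is.na(d$L_HRR)]),
               AS_HRR = mean(d$S_HRR), AS_sd = stats::sd(d$S_HRR),
               AD_HRR = mean(d$D_HRR), AD_sd = stats::sd(d$D_HRR))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-method agreement of breed run statistics
#'
#' Pearson correlation, over breeds, of each of the four descriptors
#' between two method-specific breed summaries (typically CR vs SW).
#'
#' @param b_cr,b_sw breed summaries from [breed_hrr] for the two methods,
#'   over the same breed set.
#' @return named numeric vector `c(N_HRR=, L_HRR=, S_HRR=, D_HRR=)`.
#' @export
method_correlation <- function(b_cr, b_sw) {
  if (!setequal(b_cr$breed, b_sw$breed))
    stop("breed sets differ between the two summaries")
  if (nrow(b_cr) < 3L) stop("need at least 3 breeds")
  b_sw <- b_sw[match(b_cr$breed, b_sw$breed), , drop = FALSE]
  out <- vapply(c(N = "N_HRR", L = "L_HRR", S = "S_HRR", D = "D_HRR"),
                function(v) {
                  a <- b_cr[[v]]; b <- b_sw[[v]]
                  ok <- !is.na(a) & !is.na(b)
                  if (sum(ok) < 3L || !isTRUE(stats::sd(a[ok]) > 0) ||
                      !isTRUE(stats::sd(b[ok]) > 0)) {
                    warning("zero variance for ", v, "; correlation NA")
                    return(NA_real_)
                  }
                  stats::cor(a[ok], b[ok])
                }, numeric(1))
  names(out) <- c("N_HRR", "L_HRR", "S_HRR", "D_HRR")
  out
}
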