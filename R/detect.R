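#' Run-detection parameter set
#'
#' Defaults are the standard parameterization for heterozygosity-rich-region
#' scans on ~50k SNP arrays: at least 10 SNPs per run, no missing or
#' opposite (homozygous) genotypes allowed, a maximum 1 Mb gap between
#' consecutive SNPs and a minimum run length of 250 kb.  The sliding-window
#' scanner additionally uses a 10-SNP window with the same zero allowances,
#' a minimum density of one SNP per 100 kb, and calls a SNP "in run" when
#' the fraction of compliant windows containing it exceeds 0.05.
#'
#' @param min_snp minimum number of SNPs spanned by a run.
#' @param max_miss maximum missing genotypes allowed inside a run (CR).
#' @param max_opp maximum opposite-zygosity genotypes allowed inside a run
#'   (CR).
#' @param max_gap_bp maximum gap (bp) between consecutive SNPs within a run.
#' @param min_length_bp minimum run length, defined as `end_bp - start_bp`.
#' @param window_size sliding-window width in SNPs (SW only).
#' @param max_opp_window,max_miss_window allowances inside a window (SW).
#' @param min_density minimum SNP density of a run, SNPs per bp (SW only).
#' @param snp_in_run_threshold a SNP joins a run when its compliant-window
#'   fraction is strictly greater than this (SW only).
#' @param zygosity `"heterozygous"` detects HRR; `"homozygous"` flips the
#'   matching genotype and detects classical ROH with the same machinery.
#' @param split_at_gaps split sliding-window candidate stretches at large
#'   gaps (default) instead of discarding them.
#' @return an object of class `hrr_params`.
#' @export
hrr_params <- function(min_snp = 10, max_miss = 0, max_opp = 0,
                       max_gap_bp = 1e6, min_length_bp = 250000,
                       window_size = 10, max_opp_window = 0,
                       max_miss_window = 0, min_density = 1 / 100000,
                       snp_in_run_threshold = 0.05,
                       zygosity = c("heterozygous", "homozygous"),
                       split_at_gaps = TRUE) {
  zygosity <- match.arg(zygosity)
  stopifnot(min_snp >= 1, max_miss >= 0, max_opp >= 0, max_gap_bp > 0,
            min_length_bp > 0, window_size >= 1, max_opp_window >= 0,
            max_miss_window >= 0, min_density > 0,
            snp_in_run_threshold > 0, snp_in_run_threshold < 1)
  structure(list(min_snp = as.integer(min_snp),
                 max_miss = as.integer(max_miss),
                 max_opp = as.integer(max_opp),
                 max_gap_bp = as.numeric(max_gap_bp),
                 min_length_bp = as.numeric(min_length_bp),
                 window_size = as.integer(window_size),
                 max_opp_window = as.integer(max_opp_window),
                 max_miss_window = as.integer(max_miss_window),
                 min_density = min_density,
                 snp_in_run_threshold = snp_in_run_threshold,
                 zygosity = zygosity, split_at_gaps = split_at_gaps),
            class = "hrr_params")
}

#' @export
print.hrr_params <- function(x, ...) {
  cat("hrr_params (", x$zygosity, " runs)\n", sep = "")
  cat(sprintf("  CR: min_snp=%d max_miss=%d max_opp=%d max_gap=%g bp min_length=%g bp\n",
              x$min_snp, x$max_miss, x$max_opp, x$max_gap_bp,
              x$min_length_bp))
  cat(sprintf("  SW: window=%d SNPs (opp<=%d, miss<=%d), density>=%g/bp, score>%g\n",
              x$window_size, x$max_opp_window, x$max_miss_window,
              x$min_density, x$snp_in_run_threshold))
  invisible(x)
}

#' Detect heterozygosity-rich regions per individual
#'
#' Scans every individual chromosome by chromosome, SNPs in map order, and
#' returns one row per detected run.  Two algorithms are available:
#'
#' * `"CR"` (consecutive runs): a run extends while the genotype matches the
#'   target zygosity; a missing call beyond `max_miss`, an opposite-zygosity
#'   call beyond `max_opp`, or an inter-SNP gap greater than `max_gap_bp`
#'   terminates the run before the offending SNP.  Emitted runs start and
#'   end on a matching genotype.
#' * `"SW"` (sliding window): every fully contained block of `window_size`
#'   consecutive SNPs is a window; a window is compliant when it contains at
#'   most `max_opp_window` opposite and `max_miss_window` missing genotypes.
#'   Each SNP is scored by the fraction of windows containing it that are
#'   compliant; SNPs whose score exceeds `snp_in_run_threshold` form maximal
#'   candidate stretches, which are split at large gaps and filtered by SNP
#'   count, length and density.
#'
#' Run length is `end_bp - start_bp` (positions of the first and last SNP).
#'
#' @param x a [geno_data] object.
#' @param method `"CR"` or `"SW"`.
#' @param params an [hrr_params] object.
#' @return a data frame of class `run_table` with columns `sample_id`,
#'   `breed`, `method`, `chrom`, `start_bp`, `end_bp`, `n_snp`, `length_bp`.
#' @export
detect_runs <- function(x, method = c("CR", "SW"), params = hrr_params()) {
  method <- match.arg(method)
  stopifnot(inherits(x, "geno_data"), inherits(params, "hrr_params"))
  chroms <- unique(x$map$chrom)
  res <- list()
  for (ch in chroms) {
    snp_idx <- which(x$map$chrom == ch)
    pos <- x$map$pos_bp[snp_idx]
    if (is.unsorted(pos, strictly = TRUE))
      stop("map not sorted on chromosome ", ch)
    if (length(snp_idx) == 0L) next
    if (method == "SW" && length(snp_idx) < params$window_size) next
    for (i in seq_len(nrow(x$geno))) {
      g <- x$geno[i, snp_idx]
      segs <- if (method == "CR") {
        cr_scan(g, pos, params)
      } else {
        sw_scan(g, pos, params)
      }
      if (is.null(segs) || nrow(segs) == 0L) next
      res[[length(res) + 1L]] <- data.frame(
        sample_id = x$samples$sample_id[i],
        breed = x$samples$breed[i],
        method = method, chrom = ch,
        start_bp = pos[segs$from], end_bp = pos[segs$to],
        n_snp = segs$to - segs$from + 1L,
        length_bp = pos[segs$to] - pos[segs$from],
        stringsAsFactors = FALSE)
    }
  }
  runs <- if (length(res)) do.call(rbind, res) else
    data.frame(sample_id = character(), breed = character(),
               method = character(), chrom = character(),
               start_bp = integer(), end_bp = integer(),
               n_snp = integer(), length_bp = numeric(),
               stringsAsFactors = FALSE)
  rownames(runs) <- NULL
  class(runs) <- c("run_table", "data.frame")
  runs
}

# zygosity state vector: 1 = match, 0 = opposite, NA = missing
zyg_state <- function(g, zygosity) {
  if (zygosity == "heterozygous") ifelse(g == 1L, 1L, 0L)
  else ifelse(g == 1L, 0L, 1L)
}

# consecutive-runs scanner on one individual's chromosome.
# Greedy left-to-right: miss/opp counters accumulate inside the current run
# and reset when a run closes; gap > max_gap_bp always closes.  A run is the
# index span from its first to its last matching genotype.
cr_scan <- function(g, pos, p) {
  st <- zyg_state(g, p$zygosity)
  L <- length(st)
  from <- integer(); to <- integer()
  first_match <- NA_integer_; last_match <- NA_integer_
  miss <- 0L; opp <- 0L
  close_run <- function() {
    if (!is.na(first_match)) {
      from <<- c(from, first_match); to <<- c(to, last_match)
    }
    first_match <<- NA_integer_; last_match <<- NA_integer_
    miss <<- 0L; opp <<- 0L
  }
  for (j in seq_len(L)) {
    if (!is.na(first_match) && pos[j] - pos[j - 1L] > p$max_gap_bp)
      close_run()
    s <- st[j]
    if (is.na(s)) {                 # missing genotype
      if (!is.na(first_match)) {
        miss <- miss + 1L
        if (miss > p$max_miss) close_run()
      }
    } else if (s == 1L) {           # matching zygosity
      if (is.na(first_match)) first_match <- j
      last_match <- j
    } else {                        # opposite zygosity
      if (!is.na(first_match)) {
        opp <- opp + 1L
        if (opp > p$max_opp) close_run()
      }
    }
  }
  close_run()
  keep_run_filter(from, to, pos, p, density = FALSE)
}

# sliding-window scanner on one individual's chromosome
sw_scan <- function(g, pos, p) {
  st <- zyg_state(g, p$zygosity)
  L <- length(st)
  w <- p$window_size
  nw <- L - w + 1L
  miss_ind <- as.integer(is.na(st))
  opp_ind <- as.integer(!is.na(st) & st == 0L)
  cm <- c(0L, cumsum(miss_ind))
  co <- c(0L, cumsum(opp_ind))
  wmiss <- cm[(w + 1L):(L + 1L)] - cm[1:nw]
  wopp <- co[(w + 1L):(L + 1L)] - co[1:nw]
  compliant <- as.integer(wmiss <= p$max_miss_window &
                            wopp <= p$max_opp_window)
  cc <- c(0L, cumsum(compliant))
  # SNP j is in windows max(1, j-w+1) .. min(j, nw)
  lo <- pmax(1L, seq_len(L) - w + 1L)
  hi <- pmin(seq_len(L), nw)
  n_win <- hi - lo + 1L
  n_comp <- cc[hi + 1L] - cc[lo]
  score <- n_comp / n_win
  inrun <- score > p$snp_in_run_threshold
  if (!any(inrun)) return(NULL)
  r <- rle(inrun)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  from <- starts[r$values]; to <- ends[r$values]
  # split stretches at large gaps (or discard them)
  sf <- integer(); stt <- integer()
  for (k in seq_along(from)) {
    idx <- from[k]:to[k]
    if (length(idx) > 1L) {
      gap_after <- which(diff(pos[idx]) > p$max_gap_bp)
    } else gap_after <- integer()
    if (length(gap_after) && !p$split_at_gaps) next
    cut <- c(0L, gap_after, length(idx))
    for (q in seq_len(length(cut) - 1L)) {
      sf <- c(sf, idx[cut[q] + 1L]); stt <- c(stt, idx[cut[q + 1L]])
    }
  }
  keep_run_filter(sf, stt, pos, p, density = TRUE)
}

# apply min_snp / min_length (/ density) filters to candidate index spans
keep_run_filter <- function(from, to, pos, p, density = FALSE) {
  if (!length(from)) return(NULL)
  n_snp <- to - from + 1L
  len <- pos[to] - pos[from]
  keep <- n_snp >= p$min_snp & len >= p$min_length_bp
  if (density) keep <- keep & (n_snp / pmax(len, 1) >= p$min_density)
  data.frame(from = from[keep], to = to[keep])
}

#' Parameter sweep over run-detection settings
#'
#' Runs [detect_runs] for every parameter set in a grid (for either or both
#' methods) and tabulates the total number of runs and their mean length —
#' the screening used to pick a final parameterization.
#'
#' @param x a [geno_data] object.
#' @param grid a list of [hrr_params] objects.
#' @param methods character vector of methods to sweep.
#' @return data frame with one row per (parameter set, method):
#'   `param_id`, `method`, `min_snp`, `max_miss`, `max_opp`,
#'   `min_length_bp`, `total_runs`, `mean_length_bp`.
#' @export
sweep_runs <- function(x, grid, methods = c("CR", "SW")) {
  stopifnot(length(grid) >= 1)
  rows <- list()
  for (k in seq_along(grid)) {
    p <- grid[[k]]
    for (m in methods) {
      runs <- detect_runs(x, method = m, params = p)
      rows[[length(rows) + 1L]] <- data.frame(
        param_id = k, method = m, min_snp = p$min_snp,
        max_miss = p$max_miss, max_opp = p$max_opp,
        min_length_bp = p$min_length_bp,
        total_runs = nrow(runs),
        mean_length_bp = if (nrow(runs)) mean(runs$length_bp) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a run table as TSV
#' @param runs a `run_table` from [detect_runs].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_runs <- function(runs, path) {
  utils::write.table(runs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
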