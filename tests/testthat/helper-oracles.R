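# brute-force reference implementations, deliberately naive and independent
# of the package's scanners

# consecutive-runs oracle for zero allowances: enumerate every maximal
# all-heterozygous index interval by direct pairwise checking, split at
# large gaps, then filter.  O(L^2); fine at test sizes.
oracle_cr <- function(g, pos, min_snp = 10, min_length = 250000,
                      max_gap = 1e6, zygosity = "heterozygous") {
  match_g <- if (zygosity == "heterozygous") !is.na(g) & g == 1L
  else !is.na(g) & g != 1L
  L <- length(g)
  segs <- list()
  for (i in seq_len(L)) {
    if (!match_g[i]) next
    if (i > 1 && match_g[i - 1]) next          # not maximal on the left
    j <- i
    while (j < L && match_g[j + 1]) j <- j + 1
    segs[[length(segs) + 1L]] <- c(i, j)
  }
  out <- list()
  for (s in segs) {
    idx <- s[1]:s[2]
    # split at gaps
    pieces <- split(idx, c(0, cumsum(diff(pos[idx]) > max_gap)))
    for (p in pieces) {
      n <- length(p)
      len <- pos[p[n]] - pos[p[1]]
      if (n >= min_snp && len >= min_length)
        out[[length(out) + 1L]] <- data.frame(from = p[1], to = p[n])
    }
  }
  if (length(out)) do.call(rbind, out) else data.frame(from = integer(),
                                                       to = integer())
}

# sliding-window oracle: literal loops over every window and every SNP
oracle_sw <- function(g, pos, w = 10, max_miss_w = 0, max_opp_w = 0,
                      thr = 0.05, min_snp = 10, min_length = 250000,
                      max_gap = 1e6, min_density = 1 / 100000,
                      zygosity = "heterozygous") {
  L <- length(g)
  if (L < w) return(data.frame(from = integer(), to = integer()))
  nw <- L - w + 1
  comp <- logical(nw)
  for (s in seq_len(nw)) {
    win <- g[s:(s + w - 1)]
    n_miss <- sum(is.na(win))
    n_opp <- if (zygosity == "heterozygous") sum(win != 1L, na.rm = TRUE)
    else sum(win == 1L, na.rm = TRUE)
    comp[s] <- n_miss <= max_miss_w && n_opp <= max_opp_w
  }
  inrun <- logical(L)
  for (j in seq_len(L)) {
    wins <- intersect(seq_len(nw), (j - w + 1):j)
    inrun[j] <- (sum(comp[wins]) / length(wins)) > thr
  }
  # group, split, filter
  out <- list()
  i <- 1
  while (i <= L) {
    if (!inrun[i]) { i <- i + 1; next }
    j <- i
    while (j < L && inrun[j + 1]) j <- j + 1
    idx <- i:j
    pieces <- split(idx, c(0, cumsum(diff(pos[idx]) > max_gap)))
    for (p in pieces) {
      n <- length(p)
      len <- pos[p[n]] - pos[p[1]]
      if (n >= min_snp && len >= min_length && n / max(len, 1) >= min_density)
        out[[length(out) + 1L]] <- data.frame(from = p[1], to = p[n])
    }
    i <- j + 1
  }
  if (length(out)) do.call(rbind, out) else data.frame(from = integer(),
                                                       to = integer())
}

# direct-summation inbreeding oracle for one breed's code matrix
oracle_inbreeding <- function(g) {
  n_ind <- nrow(g); m <- ncol(g)
  Fv <- numeric(n_ind)
  for (i in seq_len(n_ind)) {
    O <- 0; E <- 0; L <- 0
    for (j in seq_len(m)) {
      if (is.na(g[i, j])) next
      L <- L + 1
      if (g[i, j] != 1L) O <- O + 1
      gj <- g[!is.na(g[, j]), j]
      n <- length(gj)
      p <- (2 * sum(gj == 0L) + sum(gj == 1L)) / (2 * n)
      E <- E + (1 - 2 * p * (1 - p) * (2 * n) / (2 * n - 1))
    }
    Fv[i] <- if (L - E > 0) (O - E) / (L - E) else NA_real_
  }
  Fv
}

# interval-stabbing incidence oracle: per SNP, loop over all runs
oracle_incidence <- function(runs, x, breed) {
  map <- x$map
  ids <- x$samples$sample_id[x$samples$breed == breed]
  rr <- runs[runs$breed == breed, , drop = FALSE]
  inc <- numeric(nrow(map))
  for (j in seq_len(nrow(map))) {
    covered <- unique(rr$sample_id[rr$chrom == map$chrom[j] &
                                     rr$start_bp <= map$pos_bp[j] &
                                     rr$end_bp >= map$pos_bp[j]])
    inc[j] <- length(covered) / length(ids)
  }
  inc
}
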