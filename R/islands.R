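#' Per-breed SNP-in-run incidence, z-scores and p-values
#'
#' For one detection method, computes for every breed and SNP the fraction
#' of the breed's individuals whose runs cover the SNP (a SNP is covered
#' when `start_bp <= pos <= end_bp` of any run of that individual).  Within
#' each breed the incidences are standardized over all SNPs
#' (`z = (incidence - mean) / sd`) and converted to upper-tail standard
#' normal p-values: a high-incidence SNP gets a small p.
#'
#' @param runs a single-method `run_table` from [detect_runs].
#' @param x the [geno_data] the runs came from.
#' @return data frame with columns `breed`, `method`, `snp_id`, `chrom`,
#'   `pos_bp`, `incidence`, `z`, `p`, SNPs in map order within breed.
#' @export
snp_incidence <- function(runs, x) {
  stopifnot(inherits(x, "geno_data"))
  if (nrow(runs) && length(unique(runs$method)) > 1L)
    stop("run table mixes methods; compute one method at a time")
  method <- if (nrow(runs)) runs$method[1] else NA_character_
  map <- x$map
  breeds <- unique(x$samples$breed)
  chrom_idx <- split(seq_len(nrow(map)), map$chrom)
  out <- list()
  for (b in breeds) {
    n_b <- sum(x$samples$breed == b)
    cov <- integer(nrow(map))
    rr <- runs[runs$breed == b, , drop = FALSE]
    # runs of one individual/method never overlap, so summing run spans
    # counts each individual at most once per SNP
    for (k in seq_len(nrow(rr))) {
      idx <- chrom_idx[[rr$chrom[k]]]
      pos <- map$pos_bp[idx]
      j1 <- findInterval(rr$start_bp[k] - 1L, pos) + 1L
      j2 <- findInterval(rr$end_bp[k], pos)
      if (j1 <= j2) cov[idx[j1:j2]] <- cov[idx[j1:j2]] + 1L
    }
    inc <- cov / n_b
    mu <- mean(inc); sg <- stats::sd(inc)
    z <- if (isTRUE(sg > 0)) (inc - mu) / sg else rep(NA_real_, length(inc))
    out[[b]] <- data.frame(breed = b, method = method,
                           snp_id = map$snp_id, chrom = map$chrom,
                           pos_bp = map$pos_bp, incidence = inc, z = z,
                           p = stats::pnorm(z, lower.tail = FALSE),
                           stringsAsFactors = FALSE)
  }
  inc_tab <- do.call(rbind, out)
  rownames(inc_tab) <- NULL
  inc_tab
}

#' Select the extreme top fraction of SNPs per breed
#'
#' Within each breed, the selection threshold is the `top_frac` quantile of
#' the empirical distribution of the upper-tail p-values; every SNP with
#' `p <=` threshold is selected, so ties at the cut are all included and the
#' selection can exceed `top_frac * n_snp`.  Breeds with zero incidence
#' variance yield an empty selection with a warning.
#'
#' @param inc an incidence table from [snp_incidence].
#' @param top_frac fraction of SNPs targeted (default 0.001, i.e. top 0.1%).
#' @return named list, one character vector of selected `snp_id`s per breed.
#' @export
top_hrr_snps <- function(inc, top_frac = 0.001) {
  stopifnot(top_frac > 0, top_frac < 1)
  sel <- list()
  for (b in unique(inc$breed)) {
    d <- inc[inc$breed == b, , drop = FALSE]
    if (all(is.na(d$z))) {
      warning("breed ", b, ": constant incidence, empty selection")
      sel[[b]] <- character(0)
      next
    }
    thr <- stats::quantile(d$p, probs = top_frac, type = 1, names = FALSE)
    sel[[b]] <- d$snp_id[d$p <= thr]
  }
  sel
}

#' Intersect per-breed SNP selections across methods
#'
#' Keeps, per breed, only the SNPs selected by both detection methods.
#'
#' @param sel_cr,sel_sw named lists from [top_hrr_snps] for the two methods.
#' @return named list of per-breed intersections (breeds present in either
#'   input; a breed missing from one side yields an empty set).
#' @export
intersect_methods <- function(sel_cr, sel_sw) {
  breeds <- union(names(sel_cr), names(sel_sw))
  out <- lapply(breeds, function(b)
    intersect(sel_cr[[b]] %||% character(0), sel_sw[[b]] %||% character(0)))
  names(out) <- breeds
  out
}

#' Call HRR islands per breed from selected SNPs
#'
#' Candidate regions are maximal stretches of selected SNPs that are
#' consecutive on the (post-QC) map: same chromosome, no unselected SNP in
#' between.  Each region's frequency is the mean incidence of its member
#' SNPs in the reference incidence table (conventionally the CR table).
#' Regions with at least `min_snp` SNPs and frequency of at least
#' `min_freq` are retained, and retained regions closer than `merge_gap_bp`
#' are merged into final islands.  The attribute `"n_candidate_runs"`
#' reports, per breed, how many individual-level runs contain at least one
#' selected SNP (a diagnostic of how much raw run material backs the
#' islands), and `"n_regions_passing"` how many candidate regions passed the
#' thresholds before merging.
#'
#' @param selected named list of per-breed selected SNP ids (from
#'   [intersect_methods] or [top_hrr_snps]).
#' @param inc reference incidence table from [snp_incidence].
#' @param x the [geno_data] (supplies the map).
#' @param min_snp minimum member SNPs per island.
#' @param min_freq minimum within-breed frequency per island.
#' @param merge_gap_bp retained regions separated by less than this are
#'   merged.
#' @param runs optional `run_table` used for the diagnostic run count.
#' @param freq_fun how a region's frequency summarizes member incidences:
#'   `"mean"` (default) or `"max"`.
#' @return data frame of islands: `breed`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snp`, `freq`, `snp_ids` (comma-separated member ids).
#' @export
call_islands <- function(selected, inc, x, min_snp = 4, min_freq = 0.20,
                         merge_gap_bp = 1e6, runs = NULL,
                         freq_fun = c("mean", "max")) {
  stopifnot(inherits(x, "geno_data"))
  freq_fun <- match.arg(freq_fun)
  ffun <- if (freq_fun == "mean") mean else max
  map <- x$map
  out <- list()
  n_cand_runs <- integer(0)
  n_pass <- integer(0)
  for (b in names(selected)) {
    ids <- selected[[b]]
    inc_b <- inc[inc$breed == b, , drop = FALSE]
    inc_of <- stats::setNames(inc_b$incidence, inc_b$snp_id)
    if (!is.null(runs)) {
      rr <- runs[runs$breed == b, , drop = FALSE]
      hit <- 0L
      sel_map <- map[map$snp_id %in% ids, , drop = FALSE]
      for (k in seq_len(nrow(rr))) {
        pos_sel <- sel_map$pos_bp[sel_map$chrom == rr$chrom[k]]
        if (any(pos_sel >= rr$start_bp[k] & pos_sel <= rr$end_bp[k]))
          hit <- hit + 1L
      }
      n_cand_runs[b] <- hit
    }
    if (!length(ids)) { n_pass[b] <- 0L; next }
    j <- sort(match(ids, map$snp_id))
    # maximal stretches of consecutive map indices on one chromosome
    brk <- c(0L, which(diff(j) != 1L |
                         map$chrom[j[-1]] != map$chrom[j[-length(j)]]),
             length(j))
    regions <- list()
    for (q in seq_len(length(brk) - 1L)) {
      jj <- j[(brk[q] + 1L):brk[q + 1L]]
      regions[[q]] <- jj
    }
    keep <- Filter(function(jj) {
      length(jj) >= min_snp && ffun(inc_of[map$snp_id[jj]]) >= min_freq
    }, regions)
    n_pass[b] <- length(keep)
    if (!length(keep)) next
    # merge retained regions separated by < merge_gap_bp on one chromosome
    ord <- order(vapply(keep, function(jj) map$pos_bp[jj[1]], numeric(1)))
    ord <- ord[order(vapply(keep[ord], function(jj) map$chrom[jj[1]],
                            character(1)))]
    keep <- keep[ord]
    merged <- list(keep[[1]])
    for (r in keep[-1]) {
      last <- merged[[length(merged)]]
      same_chr <- map$chrom[r[1]] == map$chrom[last[length(last)]]
      gap <- map$pos_bp[r[1]] - map$pos_bp[last[length(last)]]
      if (same_chr && gap < merge_gap_bp) {
        merged[[length(merged)]] <- c(last, r)
      } else merged[[length(merged) + 1L]] <- r
    }
    for (jj in merged) {
      out[[length(out) + 1L]] <- data.frame(
        breed = b, chrom = map$chrom[jj[1]],
        start_bp = map$pos_bp[jj[1]], end_bp = map$pos_bp[jj[length(jj)]],
        n_snp = length(jj),
        freq = ffun(inc_of[map$snp_id[jj]]),
        snp_ids = paste(map$snp_id[jj], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  isl <- if (length(out)) do.call(rbind, out) else
    data.frame(breed = character(), chrom = character(),
               start_bp = integer(), end_bp = integer(), n_snp = integer(),
               freq = numeric(), snp_ids = character(),
               stringsAsFactors = FALSE)
  rownames(isl) <- NULL
  if (!is.null(runs)) attr(isl, "n_candidate_runs") <- n_cand_runs
  attr(isl, "n_regions_passing") <- n_pass
  isl
}

#' Merge islands shared across breeds and tally per chromosome
#'
#' Islands on the same chromosome whose base-pair intervals overlap by at
#' least 1 bp are merged transitively into shared islands with the union
#' span and the union of carrying breeds.  Codes are assigned per
#' chromosome as `CHI<chrom>-<A, B, ...>` in descending breed-count order,
#' ties broken by start position.
#'
#' @param islands an island table from [call_islands].
#' @return list with `shared` (data frame `code`, `chrom`, `start_bp`,
#'   `end_bp`, `n_breeds`, `breeds`) and `tally` (per chromosome the summed
#'   breed-island count and the unique shared-island count).
#' @export
merge_islands <- function(islands) {
  if (!nrow(islands))
    return(list(shared = data.frame(code = character(), chrom = character(),
                                    start_bp = integer(), end_bp = integer(),
                                    n_breeds = integer(), breeds = character(),
                                    stringsAsFactors = FALSE),
                tally = data.frame(chrom = character(), n_breed_islands = integer(),
                                   n_shared_islands = integer(),
                                   stringsAsFactors = FALSE)))
  shared_rows <- list()
  tally_rows <- list()
  for (ch in unique(islands$chrom)) {
    d <- islands[islands$chrom == ch, , drop = FALSE]
    d <- d[order(d$start_bp), , drop = FALSE]
    # transitive 1-bp-overlap merge of sorted intervals
    comp <- integer(nrow(d)); comp[1] <- 1L
    cur_end <- d$end_bp[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start_bp[i] <= cur_end) {
        comp[i] <- comp[i - 1L]
        cur_end <- max(cur_end, d$end_bp[i])
      } else {
        comp[i] <- comp[i - 1L] + 1L
        cur_end <- d$end_bp[i]
      }
    }
    grp <- split(seq_len(nrow(d)), comp)
    sh <- lapply(grp, function(ii) {
      data.frame(chrom = ch, start_bp = min(d$start_bp[ii]),
                 end_bp = max(d$end_bp[ii]),
                 n_breeds = length(unique(d$breed[ii])),
                 breeds = paste(unique(d$breed[ii]), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    sh <- do.call(rbind, sh)
    sh <- sh[order(-sh$n_breeds, sh$start_bp), , drop = FALSE]
    sh <- cbind(code = paste0("CHI", ch, "-", LETTERS[seq_len(nrow(sh))]),
                sh, stringsAsFactors = FALSE)
    shared_rows[[ch]] <- sh
    tally_rows[[ch]] <- data.frame(chrom = ch, n_breed_islands = nrow(d),
                                   n_shared_islands = nrow(sh),
                                   stringsAsFactors = FALSE)
  }
  shared <- do.call(rbind, shared_rows)
  tally <- do.call(rbind, tally_rows)
  rownames(shared) <- rownames(tally) <- NULL
  list(shared = shared, tally = tally)
}

#' Export islands as a BED file
#'
#' BED uses 0-based half-open coordinates: a 1-based inclusive island
#' `[start_bp, end_bp]` becomes `start_bp - 1`, `end_bp`.  The name column
#' is `<breed>:<chrom>:<n>` (or the shared-island code), the score
#' `round(1000 * freq)` capped at 1000.
#'
#' @param islands an island table from [call_islands].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_islands_bed <- function(islands, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore", con)
  if (nrow(islands)) {
    name <- if (!is.null(islands$code)) islands$code else
      paste0(islands$breed, ":", islands$chrom, ":",
             stats::ave(seq_len(nrow(islands)), islands$breed,
                        islands$chrom, FUN = seq_along))
    score <- if (!is.null(islands$freq))
      pmin(1000L, as.integer(round(1000 * islands$freq))) else 0L
    writeLines(paste(islands$chrom, islands$start_bp - 1L, islands$end_bp,
                     name, score, sep = "\t"), con)
  }
  invisible(path)
}

#' Read back a BED export of islands
#'
#' Inverse of [write_islands_bed] for round-trip checks: converts the
#' 0-based half-open BED intervals back to 1-based inclusive coordinates.
#'
#' @param path a BED file written by [write_islands_bed].
#' @return data frame with `chrom`, `start_bp`, `end_bp`, `name`, `score`.
#' @export
read_islands_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), name = character(),
                      score = integer(), stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(lines, "\t"))
  data.frame(chrom = f[, 1], start_bp = as.integer(f[, 2]) + 1L,
             end_bp = as.integer(f[, 3]), name = f[, 4],
             score = as.integer(f[, 5]), stringsAsFactors = FALSE)
}
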