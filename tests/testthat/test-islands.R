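test_that("SNP incidence counts covered individuals per breed", {
  x <- make_geno(matrix(1L, 10, 30), breed = rep("A", 10))
  # no runs -> all incidences zero
  empty <- detect_runs(subset_geno(x, snps = 1:30), "CR",
                       hrr_params(min_snp = 100))
  inc0 <- snp_incidence(empty, x)
  expect_true(all(inc0$incidence == 0))

  # one run covering SNPs 5..20 in a 10-individual breed
  runs <- data.frame(sample_id = "s01", breed = "A", method = "CR",
                     chrom = "1", start_bp = x$map$pos_bp[5],
                     end_bp = x$map$pos_bp[20], n_snp = 16L,
                     length_bp = x$map$pos_bp[20] - x$map$pos_bp[5])
  inc <- snp_incidence(runs, x)
  expect_equal(inc$incidence[5:20], rep(0.1, 16))
  expect_equal(inc$incidence[-(5:20)], rep(0, 14))
})

test_that("incidence equals the interval-stabbing oracle on random runs", {
  set.seed(77)
  pop <- simulate_population(sim_config(n_breeds = 3, n_ind = 8,
                                        chrom_lengths_bp = c(8e6, 8e6),
                                        snp_spacing_bp = 40000,
                                        missing_rate = 0.02, seed = 99))
  x <- pop$data
  p <- hrr_params(min_snp = 5, min_length_bp = 100000)
  runs <- detect_runs(x, "CR", p)
  inc <- snp_incidence(runs, x)
  for (b in unique(x$samples$breed)) {
    expect_equal(inc$incidence[inc$breed == b], oracle_incidence(runs, x, b))
  }
})

test_that("top-SNP selection keeps extreme incidences with ties included", {
  x <- make_geno(matrix(1L, 10, 1000), breed = rep("A", 10))
  inc <- data.frame(breed = "A", method = "CR", snp_id = x$map$snp_id,
                    chrom = "1", pos_bp = x$map$pos_bp,
                    incidence = c(rep(0.6, 50), rep(0.05, 950)))
  inc$z <- (inc$incidence - mean(inc$incidence)) / sd(inc$incidence)
  inc$p <- pnorm(inc$z, lower.tail = FALSE)
  sel <- top_hrr_snps(inc, top_frac = 0.001)
  # sort oracle: the 50 planted SNPs are exactly the smallest p-values,
  # and ties at the threshold pull all of them in
  expect_setequal(sel$A, inc$snp_id[1:50])

  # constant incidence -> empty selection with a warning
  inc0 <- inc; inc0$incidence <- 0.3
  inc0$z <- NA_real_; inc0$p <- NA_real_
  expect_warning(sel0 <- top_hrr_snps(inc0), "constant")
  expect_length(sel0$A, 0)
})

test_that("method intersection is a per-breed set intersection", {
  a <- list(A = c("m1", "m2", "m3"), B = c("m4"))
  b <- list(A = c("m2", "m3", "m5"), B = character(0))
  out <- intersect_methods(a, b)
  expect_setequal(out$A, c("m2", "m3"))
  expect_length(out$B, 0)
  # identical sets unchanged; disjoint sets empty
  expect_setequal(intersect_methods(a, a)$A, a$A)
  expect_length(intersect_methods(list(A = "m1"), list(A = "m9"))$A, 0)
  # random sets equal a membership-test oracle
  set.seed(78)
  u <- paste0("m", 1:100)
  s1 <- list(X = sample(u, 30)); s2 <- list(X = sample(u, 40))
  expect_setequal(intersect_methods(s1, s2)$X,
                  u[u %in% s1$X & u %in% s2$X])
})

test_that("island calling enforces count and frequency thresholds", {
  x <- make_geno(matrix(1L, 10, 40), breed = rep("A", 10))
  inc <- data.frame(breed = "A", method = "CR", snp_id = x$map$snp_id,
                    chrom = "1", pos_bp = x$map$pos_bp, incidence = 0.3,
                    z = 1, p = 0.1)
  # stretch of 3 selected SNPs -> rejected (min_snp = 4)
  isl3 <- call_islands(list(A = x$map$snp_id[5:7]), inc, x)
  expect_equal(nrow(isl3), 0)
  # frequency 0.15 -> rejected
  inc15 <- inc; inc15$incidence <- 0.15
  isl15 <- call_islands(list(A = x$map$snp_id[5:10]), inc15, x)
  expect_equal(nrow(isl15), 0)
  # 6 consecutive SNPs at 0.3 -> one island with the right span
  isl <- call_islands(list(A = x$map$snp_id[5:10]), inc, x)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start_bp, x$map$pos_bp[5])
  expect_equal(isl$end_bp, x$map$pos_bp[10])
  expect_equal(isl$n_snp, 6)
  # non-consecutive selections beyond the merge gap stay separate islands
  far <- call_islands(list(A = x$map$snp_id[c(1:5, 30:35)]), inc, x,
                      merge_gap_bp = 100000)
  expect_equal(nrow(far), 2)
  # ... but merge into one island when within the merge gap
  near <- call_islands(list(A = x$map$snp_id[c(1:5, 8:12)]), inc, x,
                       merge_gap_bp = 1e6)
  expect_equal(nrow(near), 1)
  expect_equal(near$n_snp, 10)
})

test_that("lowering thresholds never decreases the island count", {
  set.seed(79)
  x <- make_geno(matrix(1L, 10, 60), breed = rep("A", 10))
  inc <- data.frame(breed = "A", method = "CR", snp_id = x$map$snp_id,
                    chrom = "1", pos_bp = x$map$pos_bp,
                    incidence = round(runif(60, 0.1, 0.5), 2), z = 1, p = .1)
  sel <- list(A = x$map$snp_id[sort(sample(60, 35))])
  n_isl <- function(ms, mf) nrow(call_islands(sel, inc, x, min_snp = ms,
                                              min_freq = mf,
                                              merge_gap_bp = 1))
  expect_true(n_isl(3, 0.2) >= n_isl(4, 0.2))
  expect_true(n_isl(4, 0.1) >= n_isl(4, 0.3))
})

test_that("planted islands are recovered end to end", {
  pop <- example_population(seed = 4242)
  x <- pop$data
  runs_cr <- detect_runs(x, "CR")
  runs_sw <- detect_runs(x, "SW")
  sel <- intersect_methods(
    suppressWarnings(top_hrr_snps(snp_incidence(runs_cr, x))),
    suppressWarnings(top_hrr_snps(snp_incidence(runs_sw, x))))
  isl <- call_islands(sel, snp_incidence(runs_cr, x), x, runs = runs_cr)
  truth <- pop$truth$islands
  # recall 1: every planted window is hit by a called island of its breed
  for (q in seq_len(nrow(truth))) {
    hit <- isl$breed == truth$breed[q] & isl$chrom == truth$chrom[q] &
      isl$start_bp <= truth$end_bp[q] & isl$end_bp >= truth$start_bp[q]
    expect_true(any(hit))
  }
  # every member SNP of every island has positive z (incidence above mean)
  inc_cr <- snp_incidence(runs_cr, x)
  for (q in seq_len(nrow(isl))) {
    ids <- strsplit(isl$snp_ids[q], ",")[[1]]
    zz <- inc_cr$z[inc_cr$breed == isl$breed[q] & inc_cr$snp_id %in% ids]
    expect_true(all(zz > 0))
  }
  # diagnostic run count present and positive for carrier breeds
  expect_true(all(attr(isl, "n_candidate_runs")[unique(truth$breed)] > 0))
})

test_that("cross-breed merging unions overlapping spans and tallies", {
  isl <- data.frame(
    breed = c("A", "B", "C", "A", "D"),
    chrom = c("1", "1", "1", "2", "1"),
    start_bp = c(100, 180, 260, 50, 1000),
    end_bp = c(200, 300, 380, 90, 1100),
    n_snp = 5L, freq = 0.3,
    snp_ids = "m", stringsAsFactors = FALSE)
  out <- merge_islands(isl)
  sh <- out$shared
  # three mutually chained intervals merge to the union span
  big <- sh[sh$n_breeds == 3, ]
  expect_equal(nrow(big), 1)
  expect_equal(big$start_bp, 100)
  expect_equal(big$end_bp, 380)
  expect_setequal(strsplit(big$breeds, ",")[[1]], c("A", "B", "C"))
  # codes are per chromosome, breed-count descending
  expect_equal(sh$code[sh$chrom == "1"], c("CHI1-A", "CHI1-B"))
  expect_equal(sh$code[sh$chrom == "2"], "CHI2-A")
  # disjoint islands from different breeds stay separate
  expect_equal(sh$n_breeds[sh$code == "CHI1-B"], 1)
  # tallies: summed breed islands and unique shared islands
  tal <- out$tally
  expect_equal(tal$n_breed_islands[tal$chrom == "1"], 4)
  expect_equal(tal$n_shared_islands[tal$chrom == "1"], 2)
})

test_that("BED export uses 0-based half-open coordinates and round-trips", {
  isl <- data.frame(breed = "A", chrom = "1", start_bp = 100L,
                    end_bp = 200L, n_snp = 5L, freq = 0.25,
                    snp_ids = "m1", stringsAsFactors = FALSE)
  f <- file.path(tmpdir(), "isl.bed")
  write_islands_bed(isl, f)
  lines <- readLines(f)
  expect_equal(strsplit(lines[2], "\t")[[1]][2:3], c("99", "200"))
  back <- read_islands_bed(f)
  expect_equal(back$start_bp, 100L)
  expect_equal(back$end_bp, 200L)
  expect_equal(back$score, 250L)
  # empty table -> header-only file
  f0 <- file.path(tmpdir(), "empty.bed")
  write_islands_bed(isl[0, ], f0)
  expect_equal(length(readLines(f0)), 1)
  expect_equal(nrow(read_islands_bed(f0)), 0)
})
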