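# assemble a run_table by hand
mk_runs <- function(sample_id, breed, start, end, chrom = "1",
                    method = "CR") {
  data.frame(sample_id = sample_id, breed = breed, method = method,
             chrom = chrom, start_bp = start, end_bp = end,
             n_snp = 10L, length_bp = end - start, stringsAsFactors = FALSE)
}

test_that("individual summaries follow the run arithmetic", {
  x <- make_geno(matrix(1L, 2, 5), breed = c("A", "A"))
  runs <- mk_runs(c("s01", "s01"), "A", c(1e6, 5e6), c(1.3e6, 5.5e6))
  ind <- individual_hrr(runs, x)
  r1 <- ind[ind$sample_id == "s01", ]
  expect_equal(r1$n_runs, 2)
  expect_equal(r1$mean_length_mbp, 0.4)
  expect_equal(r1$total_length_mbp, 0.8)
  # zero-run individual retained with (0, NA, 0)
  r2 <- ind[ind$sample_id == "s02", ]
  expect_equal(r2$n_runs, 0)
  expect_true(is.na(r2$mean_length_mbp))
  expect_equal(r2$total_length_mbp, 0)
})

test_that("individual totals equal a group-and-sum oracle on random runs", {
  set.seed(55)
  n_ind <- 12
  x <- make_geno(matrix(1L, n_ind, 5),
                 breed = rep(c("A", "B"), each = 6))
  ids <- sample(x$samples$sample_id, 40, replace = TRUE)
  start <- round(runif(40, 1e6, 9e6))
  len <- round(runif(40, 2.5e5, 8e5))
  runs <- mk_runs(ids, x$samples$breed[match(ids, x$samples$sample_id)],
                  start, start + len)
  ind <- individual_hrr(runs, x)
  for (id in x$samples$sample_id) {
    sub <- runs[runs$sample_id == id, ]
    expect_equal(ind$n_runs[ind$sample_id == id], nrow(sub))
    expect_equal(ind$total_length_mbp[ind$sample_id == id],
                 sum(sub$length_bp) / 1e6)
  }
})

test_that("breed summary reproduces the single-run worked example", {
  x <- make_geno(matrix(1L, 1, 5), breed = "A")
  runs <- mk_runs("s01", "A", 1e6, 1.5e6)
  b <- breed_hrr(runs, x, genome_bp = 2.4e9)
  expect_equal(b$N_HRR, 1)
  expect_equal(b$L_HRR, 0.5)
  expect_equal(b$S_HRR, 0.5)
  expect_equal(b$D_HRR, 0.5e6 / 2.4e9, tolerance = 1e-9)
})

test_that("breed summary equals a per-breed loop oracle", {
  set.seed(56)
  x <- make_geno(matrix(1L, 9, 5), breed = rep(c("A", "B", "C"), each = 3))
  ids <- sample(x$samples$sample_id, 30, replace = TRUE)
  start <- round(runif(30, 1e6, 9e6))
  len <- round(runif(30, 2.5e5, 9e5))
  runs <- mk_runs(ids, x$samples$breed[match(ids, x$samples$sample_id)],
                  start, start + len)
  gbp <- genome_length(x)
  b <- breed_hrr(runs, x)
  for (br in c("A", "B", "C")) {
    members <- x$samples$sample_id[x$samples$breed == br]
    nr <- ml <- tl <- numeric(length(members))
    for (k in seq_along(members)) {
      sub <- runs[runs$sample_id == members[k], ]
      nr[k] <- nrow(sub)
      ml[k] <- if (nrow(sub)) mean(sub$length_bp) / 1e6 else NA
      tl[k] <- sum(sub$length_bp) / 1e6
    }
    expect_equal(b$N_HRR[b$breed == br], mean(nr))
    expect_equal(b$L_HRR[b$breed == br], mean(ml, na.rm = TRUE))
    expect_equal(b$S_HRR[b$breed == br], mean(tl))
    expect_equal(b$D_HRR[b$breed == br], mean(tl * 1e6 / gbp))
  }
  # D_HRR = S_HRR / genome(Mbp) exactly when genome_bp is constant
  expect_equal(b$D_HRR, b$S_HRR * 1e6 / gbp)
})

test_that("group aggregation is an unweighted mean over breeds", {
  x <- make_geno(matrix(1L, 4, 5), breed = c("A", "B", "C", "D"),
                 group = c("G1", "G1", "G2", "G2"))
  runs <- rbind(mk_runs(c("s01", "s01"), "A", c(1e6, 2e6), c(1.4e6, 2.4e6)),
                mk_runs("s02", "B", 1e6, 1.26e6),
                mk_runs("s03", "C", 1e6, 1.3e6),
                mk_runs("s04", "D", 1e6, 1.5e6))
  b <- breed_hrr(runs, x, genome_bp = 2.4e9)
  g <- group_hrr(b, x)
  # two breeds with N 2/1 -> AN 1.5
  expect_equal(g$AN_HRR[g$group == "G1"], 1.5)
  # one-breed-like identity on means: G2 breeds each with one run
  expect_equal(g$AS_HRR[g$group == "G2"],
               mean(b$S_HRR[b$breed %in% c("C", "D")]))
  # invariant to breed ordering
  g2 <- group_hrr(b[4:1, ], x)
  expect_equal(g$AN_HRR, g2$AN_HRR[match(g$group, g2$group)])
})

test_that("cross-method correlation matches the closed form", {
  x <- make_geno(matrix(1L, 4, 5), breed = c("A", "B", "C", "D"))
  b_cr <- data.frame(breed = c("A", "B", "C", "D"),
                     N_HRR = c(10, 12, 8, 14), L_HRR = c(.5, .52, .49, .55),
                     S_HRR = c(5, 6, 4, 7), D_HRR = c(.002, .0025, .0017, .003))
  b_sw <- data.frame(breed = c("A", "B", "C", "D"),
                     N_HRR = c(10, 11, 8, 15), L_HRR = c(.5, .51, .5, .54),
                     S_HRR = c(5, 5.9, 4.1, 7.2),
                     D_HRR = c(.002, .0024, .0018, .0031))
  r <- method_correlation(b_cr, b_sw)
  cf <- function(a, b) {   # closed-form Pearson r
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_equal(unname(r["N_HRR"]), cf(b_cr$N_HRR, b_sw$N_HRR))
  expect_equal(unname(r["L_HRR"]), cf(b_cr$L_HRR, b_sw$L_HRR))
  # identical summaries give r = 1 for all four parameters
  r1 <- method_correlation(b_cr, b_cr)
  expect_equal(unname(r1), rep(1, 4))
  # zero variance yields NA with a warning
  b0 <- b_cr; b0$N_HRR <- 5
  expect_warning(r0 <- method_correlation(b0, b_sw), "zero variance")
  expect_true(is.na(r0["N_HRR"]))
})

test_that("genome length is the map-derived array span", {
  map <- data.frame(snp_id = paste0("m", 1:4), chrom = c("1", "1", "2", "2"),
                    pos_bp = c(100, 1100, 500, 4500),
                    allele1 = "A", allele2 = "B")
  x <- geno_data(matrix(1L, 1, 4), map,
                 data.frame(sample_id = "s", breed = "B"))
  expect_equal(genome_length(x), 1000 + 4000)
})
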