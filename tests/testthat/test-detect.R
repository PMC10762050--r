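test_that("CR detects a clean run and respects the SNP-count boundary", {
  # 12 consecutive hets at 25 kb spacing inside homozygous flanks
  g <- c(rep(0L, 5), rep(1L, 12), rep(0L, 5))
  pos <- 1e6 + 25000 * (seq_along(g) - 1)
  x <- one_ind_geno(g, pos)
  runs <- detect_runs(x, "CR")
  expect_equal(nrow(runs), 1)
  expect_equal(runs$n_snp, 12)
  expect_equal(runs$length_bp, 275000)
  expect_equal(runs$start_bp, pos[6])
  expect_equal(runs$end_bp, pos[17])

  # 9 hets fail min_snp = 10
  g9 <- c(rep(0L, 5), rep(1L, 9), rep(0L, 5))
  x9 <- one_ind_geno(g9, 1e6 + 30000 * (seq_along(g9) - 1))
  expect_equal(nrow(detect_runs(x9, "CR")), 0)
})

test_that("a large gap splits a CR run before the offending SNP", {
  # 20 hets with a 1.2 Mb gap after the 8th: segments of 8 and 12
  pos <- c(1e6 + 30000 * (0:7), 1e6 + 30000 * 7 + 1.2e6 + 30000 * (0:11))
  g <- rep(1L, 20)
  x <- one_ind_geno(g, pos)
  runs <- detect_runs(x, "CR")
  expect_equal(nrow(runs), 1)           # only the 12-SNP segment qualifies
  expect_equal(runs$n_snp, 12)
  expect_equal(runs$start_bp, pos[9])
})

test_that("CR equals the brute-force maximal-substring oracle", {
  set.seed(101)
  for (rep in 1:10) {
    rc <- rand_chrom(400)
    x <- one_ind_geno(rc$g, rc$pos)
    runs <- detect_runs(x, "CR")
    orc <- oracle_cr(rc$g, rc$pos)
    expect_equal(runs$start_bp, rc$pos[orc$from])
    expect_equal(runs$end_bp, rc$pos[orc$to])
    expect_equal(runs$n_snp, orc$to - orc$from + 1L)
  }
})

test_that("SW equals the literal window-enumeration oracle", {
  set.seed(102)
  for (rep in 1:10) {
    rc <- rand_chrom(200)
    x <- one_ind_geno(rc$g, rc$pos)
    runs <- detect_runs(x, "SW")
    orc <- oracle_sw(rc$g, rc$pos)
    expect_equal(runs$start_bp, rc$pos[orc$from])
    expect_equal(runs$end_bp, rc$pos[orc$to])
  }
})

test_that("SW agrees with CR on clean input and applies the density filter", {
  g <- c(rep(0L, 6), rep(1L, 12), rep(0L, 6))
  pos <- 1e6 + 25000 * (seq_along(g) - 1)
  x <- one_ind_geno(g, pos)
  expect_identical(run_key(detect_runs(x, "SW")),
                   run_key(detect_runs(x, "CR")))

  # 12 in-run SNPs spanning 1.3 Mb: density 1/108 kb < 1/100 kb -> rejected
  pos2 <- round(seq(1e6, 2.3e6, length.out = 12))
  g2 <- rep(1L, 12)
  x2 <- one_ind_geno(g2, pos2)
  expect_equal(nrow(detect_runs(x2, "SW")), 0)
  # same span passes CR, which has no density criterion
  expect_equal(nrow(detect_runs(x2, "CR")), 1)
})

test_that("homozygous mode detects ROH segments bounded by gaps", {
  g <- rep(0L, 30)
  pos <- c(1e6 + 40000 * (0:14), 1e6 + 40000 * 14 + 1.5e6 + 40000 * (1:15))
  x <- one_ind_geno(g, pos)
  runs <- detect_runs(x, "CR", hrr_params(zygosity = "homozygous"))
  expect_equal(nrow(runs), 2)
  expect_equal(runs$n_snp, c(15, 15))
  # heterozygous mode finds nothing on the same data
  expect_equal(nrow(detect_runs(x, "CR")), 0)
})

test_that("CR allowances admit interior opposite/missing genotypes", {
  p1 <- hrr_params(max_opp = 1, max_miss = 1, min_snp = 10,
                   min_length_bp = 100000)
  g <- c(rep(1L, 5), 0L, rep(1L, 4), NA, rep(1L, 3), rep(0L, 4))
  pos <- 1e6 + 30000 * (seq_along(g) - 1)
  x <- one_ind_geno(g, pos)
  runs <- detect_runs(x, "CR", p1)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$n_snp, 14)          # trailing hom flank excluded
  expect_equal(runs$start_bp, pos[1])
  expect_equal(runs$end_bp, pos[14])
  # zero allowances split the same sequence into sub-threshold pieces
  expect_equal(nrow(detect_runs(x, "CR",
                                hrr_params(min_snp = 10,
                                           min_length_bp = 100000))), 0)
})

test_that("emitted runs always satisfy their structural invariants", {
  set.seed(103)
  for (rep in 1:5) {
    rc1 <- rand_chrom(300)
    rc2 <- rand_chrom(300)
    map <- data.frame(snp_id = sprintf("m%04d", 1:600),
                      chrom = rep(c("1", "2"), each = 300),
                      pos_bp = c(rc1$pos, rc2$pos),
                      allele1 = "A", allele2 = "B")
    gmat <- rbind(c(rc1$g, rc2$g),
                  sample(c(0:2, NA), 600, replace = TRUE,
                         prob = c(.2, .55, .2, .05)))
    x <- geno_data(gmat, map,
                   data.frame(sample_id = c("a", "b"), breed = "BR1"))
    for (m in c("CR", "SW")) {
      runs <- detect_runs(x, m)
      if (!nrow(runs)) next
      expect_true(all(runs$start_bp <= runs$end_bp))
      expect_true(all(runs$n_snp >= 10))
      expect_true(all(runs$length_bp >= 250000))
      expect_equal(runs$length_bp, runs$end_bp - runs$start_bp)
      # no two runs of one individual overlap on a chromosome
      for (id in unique(runs$sample_id)) {
        for (ch in unique(runs$chrom)) {
          rr <- runs[runs$sample_id == id & runs$chrom == ch, ]
          if (nrow(rr) < 2) next
          rr <- rr[order(rr$start_bp), ]
          expect_true(all(rr$start_bp[-1] > rr$end_bp[-nrow(rr)]))
        }
      }
    }
  }
})

test_that("parameter sweep is consistent and directionally monotone", {
  set.seed(104)
  rc <- rand_chrom(500, het_p = 0.55)
  x <- one_ind_geno(rc$g, rc$pos)
  base <- hrr_params(min_snp = 10, min_length_bp = 50000)
  grid <- list(base,
               hrr_params(min_snp = 15, min_length_bp = 50000),
               hrr_params(min_snp = 20, min_length_bp = 50000))
  sw <- sweep_runs(x, grid, methods = "CR")
  expect_equal(sw$total_runs[1], nrow(detect_runs(x, "CR", base)))
  # raising min_snp never increases the number of runs
  expect_true(all(diff(sw$total_runs) <= 0))

  grid2 <- list(base,
                hrr_params(min_snp = 10, max_opp = 1, min_length_bp = 50000),
                hrr_params(min_snp = 10, max_opp = 2, min_length_bp = 50000))
  sw2 <- sweep_runs(x, grid2, methods = "CR")
  # on this fixture, allowing opposite genotypes only adds runs
  expect_true(all(diff(sw2$total_runs) >= 0))
})

test_that("detection rejects an unsorted map", {
  g <- rep(1L, 12)
  map <- data.frame(snp_id = sprintf("m%02d", 1:12), chrom = "1",
                    pos_bp = c(2:12 * 1e5, 1e5), allele1 = "A", allele2 = "B")
  expect_error(geno_data(matrix(g, 1), map,
                         data.frame(sample_id = "s", breed = "B")),
               "increasing")
})
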