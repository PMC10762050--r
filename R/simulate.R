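#' Configuration for the synthetic genotype simulator
#'
#' Describes a multi-breed SNP-array dataset: per-breed sample sizes,
#' chromosome lengths, average marker spacing, a Beta prior on per-breed
#' allele frequencies, per-breed inbreeding, a missing-call rate and a list
#' of planted heterozygosity hotspots.  The `Beta(0.5, 0.5)` default
#' frequency prior gives the U-shaped allele-frequency spectrum typical of
#' ascertained SNP arrays; the default 50 kb spacing matches a ~50k chip
#' over a ~2.5 Gb genome.
#'
#' @param n_breeds number of breeds (labelled `B01`, `B02`, ...).
#' @param n_ind individuals per breed (scalar or vector of length
#'   `n_breeds`).
#' @param chrom_lengths_bp numeric vector of chromosome lengths in bp
#'   (chromosome labels are `1, 2, ...`).
#' @param snp_spacing_bp mean inter-SNP distance in bp.
#' @param freq_beta length-2 shape parameters of the Beta prior from which
#'   each breed draws its per-SNP allele frequency.
#' @param F_inbreeding per-breed inbreeding coefficient in `[0, 1)` (scalar
#'   or vector); inflates homozygosity relative to Hardy-Weinberg.
#' @param missing_rate fraction of genotype calls masked at random.
#' @param islands data frame with columns `breed`, `chrom`, `start_bp`,
#'   `end_bp`, `carrier_frac`: inside each window, a random
#'   `carrier_frac` of the breed is made heterozygous at every member SNP
#'   (and never masked), planting a detectable hotspot.
#' @param seed mandatory integer seed; all randomness derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 6, n_ind = 20,
                       chrom_lengths_bp = c(5e7, 5e7),
                       snp_spacing_bp = 50000,
                       freq_beta = c(0.5, 0.5),
                       F_inbreeding = 0, missing_rate = 0.01,
                       islands = NULL, seed) {
  if (missing(seed)) stop("sim_config requires a seed")
  n_ind <- rep_len(n_ind, n_breeds)
  F_inbreeding <- rep_len(F_inbreeding, n_breeds)
  stopifnot(all(F_inbreeding >= 0), all(F_inbreeding < 1),
            missing_rate >= 0, missing_rate < 1, snp_spacing_bp > 0,
            all(chrom_lengths_bp > 0))
  if (!is.null(islands)) {
    stopifnot(all(c("breed", "chrom", "start_bp", "end_bp",
                    "carrier_frac") %in% names(islands)))
    stopifnot(all(islands$carrier_frac > 0), all(islands$carrier_frac <= 1))
    lens <- chrom_lengths_bp[as.integer(islands$chrom)]
    if (any(islands$start_bp < 1 | islands$end_bp > lens))
      stop("island window outside chromosome bounds")
  }
  structure(list(n_breeds = n_breeds, n_ind = n_ind,
                 chrom_lengths_bp = chrom_lengths_bp,
                 snp_spacing_bp = snp_spacing_bp, freq_beta = freq_beta,
                 F_inbreeding = F_inbreeding, missing_rate = missing_rate,
                 islands = islands, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-breed SNP genotype dataset with planted hotspots
#'
#' SNP positions are sorted uniform draws at the configured density.  For
#' each breed and SNP an allele frequency `p` is drawn from the Beta prior;
#' genotypes follow the inbreeding-adjusted Hardy-Weinberg law
#' `P(het) = 2p(1-p)(1-F)`, with the excess homozygosity `F p (1-p)` split
#' between the two homozygote classes.  Calls are masked at the missing
#' rate.  Finally, for every planted island a random `carrier_frac` of the
#' breed's individuals is forced heterozygous (and unmasked) at every SNP
#' inside the window — the observable signature of locally elevated
#' heterozygote incidence, without modelling the selective process itself.
#'
#' @param config a [sim_config] object.
#' @return list with `data` (a [geno_data]) and `truth` (list with
#'   `islands`: planted windows with member-SNP indices and carrier ids;
#'   `F`: named per-breed true inbreeding).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(cfg) {
  # map
  maps <- lapply(seq_along(cfg$chrom_lengths_bp), function(ch) {
    len <- cfg$chrom_lengths_bp[ch]
    m <- max(2L, round(len / cfg$snp_spacing_bp))
    pos <- sort(sample.int(len, m, replace = FALSE))
    data.frame(snp_id = sprintf("snp%d_%d", ch, seq_len(m)),
               chrom = as.character(ch), pos_bp = pos,
               allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  m <- nrow(map)

  breeds <- sprintf("B%02d", seq_len(cfg$n_breeds))
  samples <- data.frame(
    sample_id = unlist(lapply(seq_len(cfg$n_breeds), function(k)
      sprintf("%s_i%02d", breeds[k], seq_len(cfg$n_ind[k])))),
    breed = rep(breeds, cfg$n_ind), stringsAsFactors = FALSE)
  n <- nrow(samples)

  geno <- matrix(NA_integer_, n, m)
  for (k in seq_len(cfg$n_breeds)) {
    rows <- which(samples$breed == breeds[k])
    p <- stats::rbeta(m, cfg$freq_beta[1], cfg$freq_beta[2])
    F <- cfg$F_inbreeding[k]
    # p is the allele1 frequency; code counts allele2 copies:
    # P(hom1) = p^2 + F p(1-p), P(het) = 2p(1-p)(1-F), rest hom2
    phom1 <- p^2 + F * p * (1 - p)
    phet <- 2 * p * (1 - p) * (1 - F)
    probs <- rbind(phom1, phet, 1 - phom1 - phet)
    u <- matrix(stats::runif(length(rows) * m), length(rows), m)
    c1 <- matrix(probs[1, ], length(rows), m, byrow = TRUE)
    c2 <- matrix(probs[1, ] + probs[2, ], length(rows), m, byrow = TRUE)
    g <- ifelse(u < c1, 0L, ifelse(u < c2, 1L, 2L))
    geno[rows, ] <- g
  }
  # missingness
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(geno)) < cfg$missing_rate
    geno[mask] <- NA_integer_
  }
  # planted islands
  truth_islands <- NULL
  if (!is.null(cfg$islands)) {
    ti <- vector("list", nrow(cfg$islands))
    for (q in seq_len(nrow(cfg$islands))) {
      isl <- cfg$islands[q, ]
      jj <- which(map$chrom == as.character(isl$chrom) &
                    map$pos_bp >= isl$start_bp & map$pos_bp <= isl$end_bp)
      if (!length(jj))
        stop("planted island ", q, " contains no SNPs")
      rows <- which(samples$breed == isl$breed)
      n_car <- max(1L, round(isl$carrier_frac * length(rows)))
      carriers <- sort(sample(rows, n_car))
      geno[carriers, jj] <- 1L
      ti[[q]] <- data.frame(
        breed = isl$breed, chrom = as.character(isl$chrom),
        start_bp = map$pos_bp[jj[1]], end_bp = map$pos_bp[jj[length(jj)]],
        first_snp = map$snp_id[jj[1]], last_snp = map$snp_id[jj[length(jj)]],
        n_snp = length(jj), n_carriers = n_car,
        carrier_frac = n_car / length(rows),
        carriers = paste(samples$sample_id[carriers], collapse = ","),
        stringsAsFactors = FALSE)
    }
    truth_islands <- do.call(rbind, ti)
  }
  list(data = geno_data(geno, map, samples),
       truth = list(islands = truth_islands,
                    F = stats::setNames(cfg$F_inbreeding, breeds)))
}

#' Canned study-scale demonstration fixture
#'
#' A frozen-seed synthetic panel used by the documentation and tests: 6
#' breeds of 20 individuals, 2 chromosomes of 50 Mb at ~50 kb spacing
#' (~2,000 SNPs), an inbreeding ladder `0, 0, 0.1, 0.1, 0.4, 0.4` across
#' breeds, 1% missing calls and 3 planted heterozygosity hotspots (30-SNP
#' scale windows carried by half of the breed).
#'
#' @param seed integer seed (default fixed, so the fixture is stable).
#' @return as [simulate_population].
#' @export
example_population <- function(seed = 20240102) {
  islands <- data.frame(
    breed = c("B01", "B03", "B05"), chrom = c("1", "2", "1"),
    start_bp = c(10e6, 25e6, 30e6), end_bp = c(11.5e6, 26.5e6, 31.5e6),
    carrier_frac = 0.5, stringsAsFactors = FALSE)
  cfg <- sim_config(n_breeds = 6, n_ind = 20,
                    chrom_lengths_bp = c(5e7, 5e7), snp_spacing_bp = 50000,
                    F_inbreeding = c(0, 0, 0.1, 0.1, 0.4, 0.4),
                    missing_rate = 0.01, islands = islands, seed = seed)
  simulate_population(cfg)
}
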