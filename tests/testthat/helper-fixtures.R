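# small in-code fixtures shared across test files

tmpdir <- function() {
  d <- tempfile("hrrscan-test-")
  dir.create(d)
  d
}

# build a geno_data from a plain code matrix with evenly spaced positions
make_geno <- function(codes, breed = NULL, spacing = 50000L, chrom = "1",
                      start = 1e6, group = NULL) {
  codes <- as.matrix(codes)
  n <- nrow(codes); m <- ncol(codes)
  if (is.null(breed)) breed <- rep("BR1", n)
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                        breed = breed, stringsAsFactors = FALSE)
  if (!is.null(group)) samples$group <- group
  map <- data.frame(snp_id = sprintf("m%03d", seq_len(m)), chrom = chrom,
                    pos_bp = as.integer(start + spacing * (seq_len(m) - 1L)),
                    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  geno_data(codes, map, samples)
}

# random single-chromosome genotypes for the detector oracle tests:
# returns list(g = codes, pos = positions) with occasional large gaps
rand_chrom <- function(n_snp, het_p = 0.6, miss_p = 0.03, big_gap_p = 0.01,
                       spacing = 30000) {
  g <- sample(c(1L, 0L, 2L, NA_integer_), n_snp, replace = TRUE,
              prob = c(het_p, (1 - het_p - miss_p) / 2,
                       (1 - het_p - miss_p) / 2, miss_p))
  steps <- pmax(1, round(stats::rexp(n_snp, 1 / spacing)))
  big <- stats::runif(n_snp) < big_gap_p
  steps[big] <- steps[big] + 1.4e6
  list(g = g, pos = cumsum(steps))
}

# wrap a single individual's chromosome into a geno_data
one_ind_geno <- function(g, pos, chrom = "1", breed = "BR1") {
  map <- data.frame(snp_id = sprintf("m%05d", seq_along(g)), chrom = chrom,
                    pos_bp = as.integer(pos), allele1 = "A", allele2 = "B",
                    stringsAsFactors = FALSE)
  geno_data(matrix(g, nrow = 1), map,
            data.frame(sample_id = "s01", breed = breed,
                       stringsAsFactors = FALSE))
}

# canonical run-table key for exact set comparisons
run_key <- function(runs) {
  if (!nrow(runs)) return(character(0))
  sort(paste(runs$sample_id, runs$chrom, runs$start_bp, runs$end_bp,
             runs$n_snp, sep = ":"))
}
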