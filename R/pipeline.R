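#' Run the full HRR characterization pipeline
#'
#' Orchestrates every stage from genotype input to island export:
#' optional breed subsampling, quality control, per-breed diversity
#' indices with group averages, IBS distances + classical MDS, Reynolds
#' distances (PHYLIP export), CR and SW run detection, breed/group run
#' statistics with cross-method correlations, island calling with
#' cross-breed merging, and BED/TSV exports.  All outputs are written under
#' `out_dir`; a provenance log records the configuration, seed and
#' per-stage counts.  Given the same config and seed the outputs are
#' byte-identical.
#'
#' @param config either a path to a YAML configuration file (see
#'   [read_run_config]) or a config list.  Recognized entries: `ped`,
#'   `map` (input paths; alternatively `data`, an in-memory [geno_data]),
#'   `groups` (optional TSV path or data frame with breed/group columns),
#'   `max_per_breed` (default 30), `seed` (default 1), `qc` (list of
#'   [qc_params] arguments), `detect` (list of [hrr_params] arguments),
#'   `islands` (list: `top_frac` 0.001, `min_freq` 0.20, `min_snp` 4,
#'   `merge_gap_bp` 1e6), `genome_bp` (optional D_HRR denominator
#'   override), `mds_k` (default 2).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the main in-memory results: `qc`,
#'   `diversity`, `group_diversity`, `mds`, `reynolds`, `runs_cr`,
#'   `runs_sw`, `breed_cr`, `breed_sw`, `group_cr`, `correlations`,
#'   `islands`, `shared`, `tally`.
#' @export
run_hrr_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(..., "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  seed <- config$seed %||% 1L
  logf("hrrscan pipeline, package version ",
       as.character(utils::packageVersion("hrrscan")))
  logf("seed: ", seed)

  # --- input ---------------------------------------------------------
  if (!is.null(config$data)) {
    x <- config$data
    stopifnot(inherits(x, "geno_data"))
  } else {
    if (is.null(config$ped) || is.null(config$map))
      stop("config must provide either `data` or `ped` + `map` paths")
    if (!file.exists(config$ped)) stop("input not found: ", config$ped)
    if (!file.exists(config$map)) stop("input not found: ", config$map)
    x <- read_ped_map(config$ped, config$map)
  }
  if (!is.null(config$groups)) {
    g <- config$groups
    if (is.character(g)) g <- utils::read.table(g, header = TRUE, sep = "\t",
                                                stringsAsFactors = FALSE)
    x <- set_groups(x, g)
  }
  if (all(is.na(x$samples$group))) x$samples$group <- "all"
  logf("input: ", nrow(x$geno), " individuals x ", ncol(x$geno), " SNPs, ",
       length(unique(x$samples$breed)), " breeds")

  # --- subsample, QC -------------------------------------------------
  max_n <- config$max_per_breed %||% 30L
  x <- subsample_breeds(x, max_n = max_n, seed = seed)
  logf("after subsampling (max ", max_n, "/breed): ", nrow(x$geno),
       " individuals")
  qp <- do.call(qc_params, config$qc %||% list())
  qc <- apply_qc(x, qp)
  x <- qc$data
  utils::write.table(qc$report, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("after QC: ", nrow(x$geno), " individuals x ", ncol(x$geno), " SNPs")

  # --- diversity -----------------------------------------------------
  div <- breed_diversity(x)
  write_diversity(div, file.path(out_dir, "diversity_breeds.tsv"))
  gdiv <- group_diversity(div, x)
  utils::write.table(gdiv, file.path(out_dir, "diversity_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- relationships -------------------------------------------------
  k <- config$mds_k %||% 2L
  mds <- classical_mds(ibs_dist(x), k = min(k, nrow(x$geno) - 1L))
  write_mds(mds, x, file.path(out_dir, "mds_coords.tsv"))
  rey <- reynolds_dist(breed_freqs(x))
  write_dist(rey, file.path(out_dir, "reynolds.phy"), format = "phylip")
  write_dist(rey, file.path(out_dir, "reynolds.nex"), format = "nexus")

  # --- run detection -------------------------------------------------
  dp <- do.call(hrr_params, config$detect %||% list())
  runs_cr <- detect_runs(x, "CR", dp)
  runs_sw <- detect_runs(x, "SW", dp)
  write_runs(runs_cr, file.path(out_dir, "runs_cr.tsv"))
  write_runs(runs_sw, file.path(out_dir, "runs_sw.tsv"))
  logf("runs: CR ", nrow(runs_cr), ", SW ", nrow(runs_sw))

  # --- statistics ----------------------------------------------------
  genome_bp <- config$genome_bp %||% NULL
  b_cr <- breed_hrr(runs_cr, x, genome_bp = genome_bp)
  b_sw <- breed_hrr(runs_sw, x, genome_bp = genome_bp)
  utils::write.table(b_cr, file.path(out_dir, "hrr_breeds_cr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(b_sw, file.path(out_dir, "hrr_breeds_sw.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  g_cr <- group_hrr(b_cr, x)
  utils::write.table(g_cr, file.path(out_dir, "hrr_groups_cr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  corr <- if (length(unique(b_cr$breed)) >= 3L) {
    method_correlation(b_cr, b_sw)
  } else {
    warning("fewer than 3 breeds; cross-method correlations not estimable")
    c(N_HRR = NA_real_, L_HRR = NA_real_, S_HRR = NA_real_, D_HRR = NA_real_)
  }
  utils::write.table(data.frame(parameter = names(corr), r = corr),
                     file.path(out_dir, "method_correlation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- islands -------------------------------------------------------
  ip <- config$islands %||% list()
  inc_cr <- snp_incidence(runs_cr, x)
  inc_sw <- snp_incidence(runs_sw, x)
  sel <- intersect_methods(
    top_hrr_snps(inc_cr, top_frac = ip$top_frac %||% 0.001),
    top_hrr_snps(inc_sw, top_frac = ip$top_frac %||% 0.001))
  isl <- call_islands(sel, inc_cr, x,
                      min_snp = ip$min_snp %||% 4,
                      min_freq = ip$min_freq %||% 0.20,
                      merge_gap_bp = ip$merge_gap_bp %||% 1e6,
                      runs = runs_cr)
  utils::write.table(isl[, setdiff(names(isl), "snp_ids")],
                     file.path(out_dir, "islands_breeds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_islands_bed(isl, file.path(out_dir, "islands.bed"))
  mi <- merge_islands(isl)
  utils::write.table(mi$shared, file.path(out_dir, "islands_shared.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mi$tally, file.path(out_dir, "islands_tally.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("islands: ", nrow(isl), " breed-level, ",
       nrow(mi$shared), " shared, over ",
       length(unique(isl$chrom)), " chromosome(s)")

  invisible(list(qc = qc$report, data = x, diversity = div,
                 group_diversity = gdiv, mds = mds, reynolds = rey,
                 runs_cr = runs_cr, runs_sw = runs_sw,
                 breed_cr = b_cr, breed_sw = b_sw, group_cr = g_cr,
                 correlations = corr, islands = isl,
                 shared = mi$shared, tally = mi$tally))
}

#' Read a pipeline configuration from YAML
#'
#' @param path a YAML file whose top-level keys match the `config` entries
#'   of [run_hrr_pipeline].
#' @return a config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
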