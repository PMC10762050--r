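#' Read PLINK-format PED/MAP genotype files
#'
#' Parses a text PED/MAP pair into a [geno_data] object.  The PED family-id
#' column is used as the breed code.  Each SNP's two allele labels are learnt
#' from the file: `allele1` is the first non-missing allele encountered
#' scanning the SNP's column top-down, unless a reference labelling is
#' supplied via `alleles` (required for a bit-identical code round trip when
#' the first-observed allele differs from the writer's `allele1`).  A `0 0`
#' genotype field is read as missing.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param alleles optional data frame with columns `snp_id`, `allele1`,
#'   `allele2` fixing the code polarity per SNP.
#' @return a [geno_data] object.
#' @export
read_ped_map <- function(ped_path, map_path, alleles = NULL) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) < 4)
    stop("MAP file must have 4 columns (chrom, id, cM, bp)")
  map <- data.frame(snp_id = map_raw[[2]], chrom = map_raw[[1]],
                    pos_bp = as.integer(map_raw[[4]]),
                    stringsAsFactors = FALSE)
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) stop("PED file is empty: ", ped_path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  len <- lengths(fields)
  if (any(len != want))
    stop("ragged PED row(s) ", paste(which(len != want), collapse = ", "),
         ": expected ", want, " fields (6 + 2 x ", m, " SNPs), got ",
         paste(unique(len[len != want]), collapse = "/"))
  ped <- matrix(unlist(fields), nrow = n, byrow = TRUE)
  samples <- data.frame(sample_id = ped[, 2], breed = ped[, 1],
                        stringsAsFactors = FALSE)

  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_

  ref1 <- ref2 <- rep(NA_character_, m)
  if (!is.null(alleles)) {
    idx <- match(map$snp_id, alleles$snp_id)
    ref1 <- as.character(alleles$allele1)[idx]
    ref2 <- as.character(alleles$allele2)[idx]
  }
  geno <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- as.vector(rbind(a1[, j], a2[, j]))  # file order: row by row
    obs <- obs[!is.na(obs)]
    u <- unique(c(ref1[j], ref2[j], obs))
    u <- u[!is.na(u)]
    if (length(u) > 2)
      stop("SNP ", map$snp_id[j], " has >2 alleles: ",
           paste(u, collapse = ","))
    A <- if (length(u) >= 1) u[1] else NA_character_
    B <- if (length(u) == 2) u[2] else NA_character_
    ref1[j] <- A; ref2[j] <- B
    g1 <- a1[, j]; g2 <- a2[, j]
    code <- (g1 != A) + (g2 != A)   # count of non-first alleles
    geno[, j] <- as.integer(code)
  }
  map$allele1 <- ref1
  map$allele2 <- ref2
  geno_data(geno, map, samples)
}

#' Write a genotype dataset as PLINK PED/MAP text files
#'
#' @param x a [geno_data] object.
#' @param prefix output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return the two file paths, invisibly.
#' @export
write_ped_map <- function(x, prefix) {
  stopifnot(inherits(x, "geno_data"))
  map <- x$map
  cm <- rep("0", nrow(map))
  utils::write.table(data.frame(map$chrom, map$snp_id, cm, map$pos_bp),
                     paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  a1 <- ifelse(is.na(map$allele1), "A", map$allele1)
  a2 <- ifelse(is.na(map$allele2), "B", map$allele2)
  n <- nrow(x$geno); m <- ncol(x$geno)
  out <- character(n)
  for (i in seq_len(n)) {
    g <- x$geno[i, ]
    f1 <- ifelse(is.na(g), "0", ifelse(g == 0L, a1, ifelse(g == 1L, a1, a2)))
    f2 <- ifelse(is.na(g), "0", ifelse(g == 0L, a1, a2))
    pair <- character(2L * m)
    pair[seq(1L, 2L * m, 2L)] <- f1
    pair[seq(2L, 2L * m, 2L)] <- f2
    out[i] <- paste(c(x$samples$breed[i], x$samples$sample_id[i],
                      "0", "0", "0", "-9", pair), collapse = " ")
  }
  writeLines(out, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}
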