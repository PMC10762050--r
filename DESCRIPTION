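Package: hrrscan
Title: Detection and Characterization of Heterozygosity-Rich Regions from
    SNP Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize heterozygosity-rich regions (HRR, also
    called runs of heterozygosity) in diploid populations genotyped with
    medium-density SNP arrays.  The package reads PLINK-format PED/MAP
    genotypes, merges and quality-controls multi-cohort datasets, computes
    per-breed diversity indices (observed and expected heterozygosity,
    molecular inbreeding, minor allele frequency), inter-individual
    identity-by-state distances with classical multidimensional scaling and
    inter-breed Reynolds distances, detects HRR per individual by both the
    consecutive-runs and sliding-window algorithms, summarizes runs per
    breed and geographic group, and calls within-breed HRR islands from
    z-scores of SNP-in-run incidence with cross-breed merging.  A
    synthetic-genotype simulator with planted heterozygosity hotspots
    provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
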