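#' Per-SNP quality statistics
#'
#' For each marker: missing-call rate, heterozygosity rate among non-missing
#' calls, and minor allele frequency over non-missing calls (two alleles per
#' diploid). A SNP with every call missing gets `maf = 0` and is flagged.
#'
#' @param G a [genotype_matrix()].
#' @return A tibble: `snp_id`, `chrom`, `pos`, `missing_rate`, `het_rate`,
#'   `maf`, `all_missing`.
#' @export
snp_stats <- function(G) {
  geno <- G$geno
  n <- nrow(geno)
  n_miss <- colSums(is.na(geno))
  n_ok <- n - n_miss
  het <- colSums(geno == 1, na.rm = TRUE)
  f <- colSums(geno, na.rm = TRUE) / (2 * pmax(n_ok, 1))
  maf <- pmin(f, 1 - f)
  all_missing <- n_ok == 0
  maf[all_missing] <- 0
  het_rate <- ifelse(n_ok > 0, het / n_ok, 0)
  tibble(
    snp_id = G$map$snp_id, chrom = G$map$chrom, pos = G$map$pos,
    missing_rate = unname(n_miss / n), het_rate = unname(het_rate),
    maf = unname(maf), all_missing = unname(all_missing)
  )
}

#' Filter SNPs on missingness, heterozygosity and MAF
#'
#' A SNP is removed iff `missing_rate > max_missing` OR
#' `het_rate > max_het` OR `maf < min_maf` (strict inequalities; a SNP at
#' exactly a threshold is kept). All statistics are computed on the input
#' matrix before any removal, so the filter is idempotent. The removal log
#' attributes each dropped SNP to the first matching reason in the order
#' missing, heterozygosity, MAF.
#'
#' Per-accession missingness is computed and reported in the log but no
#' accessions are dropped.
#'
#' @param G a [genotype_matrix()].
#' @param max_missing,max_het,min_maf thresholds in `[0, 1]`.
#' @return A list with `genotypes` (filtered [genotype_matrix()]), `stats`
#'   (the [snp_stats()] table with `pass` and `reason` columns), and `log`
#'   (counts per removal reason plus per-accession missingness).
#' @export
filter_snps <- function(G, max_missing = 0.20, max_het = 0.20, min_maf = 0.01) {
  stopifnot(max_missing >= 0, max_missing <= 1, max_het >= 0, max_het <= 1,
            min_maf >= 0, min_maf <= 1)
  st <- snp_stats(G)
  reason <- rep(NA_character_, nrow(st))
  reason[st$maf < min_maf] <- "maf"
  reason[st$het_rate > max_het] <- "het"
  reason[st$missing_rate > max_missing] <- "missing"
  pass <- is.na(reason)
  st$pass <- pass
  st$reason <- reason
  acc_missing <- tibble(
    accession_id = rownames(G$geno),
    missing_rate = rowMeans(is.na(G$geno))
  )
  list(
    genotypes = G[, which(pass)],
    stats = st,
    log = list(
      n_input = nrow(st), n_retained = sum(pass),
      n_removed_missing = sum(reason == "missing", na.rm = TRUE),
      n_removed_het = sum(reason == "het", na.rm = TRUE),
      n_removed_maf = sum(reason == "maf", na.rm = TRUE),
      accession_missing = acc_missing
    )
  )
}

#' SNP density per chromosome and overall
#'
#' @param map marker map tibble (`snp_id`, `chrom`, `pos`).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   every chromosome in `map` must be present.
#' @return A tibble with one row per chromosome plus an `overall` row:
#'   `chrom`, `n_snps`, `length_mb`, `snps_per_mb`.
#' @export
snp_density <- function(map, chrom_lengths) {
  if (any(chrom_lengths <= 0)) abort("zero-length chromosome")
  missing_chr <- setdiff(unique(map$chrom), names(chrom_lengths))
  if (length(missing_chr)) {
    abort(paste0("no length given for chromosome(s): ",
                 paste(missing_chr, collapse = ", ")))
  }
  counts <- table(factor(map$chrom, levels = names(chrom_lengths)))
  per <- tibble(
    chrom = names(chrom_lengths),
    n_snps = as.integer(counts),
    length_mb = as.numeric(chrom_lengths) / 1e6
  ) |>
    mutate(snps_per_mb = .data$n_snps / .data$length_mb)
  overall <- tibble(
    chrom = "overall", n_snps = sum(per$n_snps),
    length_mb = sum(per$length_mb),
    snps_per_mb = sum(per$n_snps) / sum(per$length_mb)
  )
  bind_rows(per, overall)
}

#' Sensitivity of the association scan to the heterozygosity filter
#'
#' Re-runs the QC filter at a ladder of maximum-heterozygosity rates
#' (missingness and MAF thresholds held at their defaults) followed by the
#' full kinship mixed-model scan, recording how many markers survive QC and
#' how many reach significance at FDR 0.05 and at raw p < 1e-4.
#'
#' @param G a [genotype_matrix()] (unfiltered).
#' @param phenotypes tibble with `accession_id`, `aspect_ratio`.
#' @param rates ascending heterozygosity-rate ladder; the default is 5%,
#'   10%, then every 10% up to 100%.
#' @param max_missing,min_maf fixed companion thresholds.
#' @param mode scan mode, see [mlm_scan()].
#' @return A tibble: `rate`, `n_snps_retained`, `n_significant_fdr05`,
#'   `n_significant_p1e4`, `error` (NA unless that rate's scan failed).
#' @export
het_sensitivity_sweep <- function(G, phenotypes,
                                  rates = c(0.05, seq(0.10, 1.0, by = 0.10)),
                                  max_missing = 0.20, min_maf = 0.01,
                                  mode = "p3d") {
  if (is.unsorted(rates)) abort("rates must be sorted ascending")
  purrr::map_dfr(rates, function(r) {
    flt <- filter_snps(G, max_missing = max_missing, max_het = r, min_maf = min_maf)
    res <- tryCatch({
      K <- kinship(flt$genotypes)
      scan <- mlm_scan(flt$genotypes, phenotypes, K, mode = mode)
      tibble(rate = r, n_snps_retained = n_snps(flt$genotypes),
             n_significant_fdr05 = sum(scan$fdr_adjusted_p < 0.05),
             n_significant_p1e4 = sum(scan$p_value < 1e-4),
             error = NA_character_)
    }, error = function(e) {
      tibble(rate = r, n_snps_retained = n_snps(flt$genotypes),
             n_significant_fdr05 = NA_integer_, n_significant_p1e4 = NA_integer_,
             error = conditionMessage(e))
    })
    res
  })
}
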