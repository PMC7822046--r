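#' Genotype matrix container
#'
#' Bundles a numeric accession-by-SNP matrix of minor-allele dosage codes
#' (0/1/2, `NA` = missing) with its marker map. The map is a tibble with one
#' row per SNP, sorted by (chromosome, position), carrying `snp_id`,
#' `chrom`, `pos` (1-based bp) and the allele pair where known. Columns of
#' the genotype matrix follow map order; row names are accession ids.
#'
#' @param geno numeric matrix, accessions in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param map data frame with columns `snp_id`, `chrom`, `pos` and optional
#'   `allele_minor`, `allele_major`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, map) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  map <- as_tibble(map)
  stopifnot(is.numeric(geno))
  if (!all(c("snp_id", "chrom", "pos") %in% names(map))) {
    abort("map must have columns snp_id, chrom, pos")
  }
  if (anyDuplicated(map$snp_id)) {
    abort(paste0("duplicate snp_id in marker map: ",
                 paste(unique(map$snp_id[duplicated(map$snp_id)]), collapse = ", ")))
  }
  if (ncol(geno) != nrow(map)) {
    abort("geno has one column per map row; dimensions disagree")
  }
  if (any(map$pos < 1)) abort("positions are 1-based; pos >= 1 required")
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    abort("genotype codes must be 0, 1, 2 or NA")
  }
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  colnames(geno) <- map$snp_id
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("acc%03d", seq_len(nrow(geno)))
  }
  structure(list(geno = geno, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d accessions x %d SNPs on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  cat(sprintf("  missing: %.1f%%  heterozygous: %.1f%% of non-missing calls\n",
              100 * mean(is.na(x$geno)),
              100 * mean(x$geno == 1, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

n_accessions <- function(g) nrow(g$geno)
n_snps <- function(g) ncol(g$geno)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i accession index (rows).
#' @param j SNP index (columns or snp_id character vector).
#' @param ... ignored.
#' @return A `genotype_matrix` restricted to the selected entries.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  if (is.character(j)) j <- match(j, x$map$snp_id)
  genotype_matrix(x$geno[i, j, drop = FALSE], x$map[j, , drop = FALSE])
}

#' Flip genotype codes at selected SNPs
#'
#' Exchanges the coded allele (`code -> 2 - code`) at the given SNPs and swaps
#' the recorded allele pair. Applying the same flip twice restores the input.
#'
#' @param g a [genotype_matrix()].
#' @param snps logical or integer index of SNPs to flip.
#' @return A `genotype_matrix`.
#' @export
flip_codes <- function(g, snps) {
  if (is.logical(snps)) snps <- which(snps)
  if (length(snps)) {
    g$geno[, snps] <- 2 - g$geno[, snps]
    if (all(c("allele_minor", "allele_major") %in% names(g$map))) {
      tmp <- g$map$allele_minor[snps]
      g$map$allele_minor[snps] <- g$map$allele_major[snps]
      g$map$allele_major[snps] <- tmp
    }
  }
  g
}

#' Recode so the counted allele is the minor allele
#'
#' Flips every SNP whose coded-allele frequency (over non-missing calls,
#' two alleles per diploid) exceeds 0.5. Idempotent.
#'
#' @param g a [genotype_matrix()].
#' @return A `genotype_matrix` in minor-allele coding.
#' @export
recode_to_minor <- function(g) {
  f <- colMeans(g$geno, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  flip_codes(g, f > 0.5)
}

coded_allele_freq <- function(g) {
  f <- colMeans(g$geno, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  f
}
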