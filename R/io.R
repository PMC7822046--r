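#' Read a genotype panel
#'
#' Reads diploid biallelic genotypes into a [genotype_matrix()] in
#' minor-allele dosage coding (0/1/2, `NA` missing). Multi-allelic sites are
#' skipped with a message. Three dialects are supported:
#'
#' * `"vcf"` — VCF 4.x, GT field only (phased or unphased separators).
#' * `"hapmap"` — tab-separated with `rs#`, `alleles`, `chrom`, `pos`
#'   columns followed by one column per accession holding two-letter
#'   genotypes (`AA`, `AG`, ...; `NN` or `--` missing). A heterozygote is
#'   any two distinct letters in either order.
#' * `"matrix_tsv"` — tab-separated with `snp_id`, `chrom`, `pos` columns
#'   followed by one column per accession holding dosage codes 0/1/2
#'   (`NA` or `.` missing).
#'
#' @param path file path.
#' @param format one of `"vcf"`, `"hapmap"`, `"matrix_tsv"`.
#' @return A [genotype_matrix()]; sites recoded so 0/1/2 counts the minor
#'   allele and the map sorted by (chromosome, position).
#' @export
read_genotypes <- function(path, format = c("vcf", "hapmap", "matrix_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  g <- switch(format,
    vcf = read_genotypes_vcf(path),
    hapmap = read_genotypes_hapmap(path),
    matrix_tsv = read_genotypes_matrix(path)
  )
  recode_to_minor(g)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    inform(sprintf("skipping %d multi-allelic site(s)", sum(multi)))
  }
  keep <- !multi
  if (!any(keep)) abort("no biallelic sites in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix$ID
  if (anyNA(ids) || any(ids == ".")) {
    auto <- is.na(ids) | ids == "."
    ids[auto] <- paste0(fix$CHROM[auto], "_", fix$POS[auto])
  }
  if (anyDuplicated(ids)) abort("duplicate snp_id in VCF")
  codes <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", gt)
  codes[clean %in% c("0/0")] <- 0
  codes[clean %in% c("0/1", "1/0")] <- 1
  codes[clean %in% c("1/1")] <- 2
  geno <- t(codes)
  rownames(geno) <- colnames(gt)
  map <- tibble(
    snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    allele_minor = fix$ALT, allele_major = fix$REF
  )
  genotype_matrix(geno, map)
}

read_genotypes_hapmap <- function(path) {
  dat <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("rs", "alleles", "chrom", "pos")
  hdr <- tolower(sub("#$", "", sub("^rs#$", "rs", names(dat))))
  if (!all(need %in% hdr[1:4])) {
    abort("malformed HapMap header (line 1): expected rs#/alleles/chrom/pos")
  }
  names(dat)[1:4] <- need
  if (anyDuplicated(dat$rs)) abort("duplicate snp_id in HapMap file")
  alleles <- strsplit(dat$alleles, "/", fixed = TRUE)
  if (any(lengths(alleles) != 2)) {
    inform(sprintf("skipping %d multi-allelic site(s)", sum(lengths(alleles) != 2)))
  }
  keep <- lengths(alleles) == 2
  dat <- dat[keep, , drop = FALSE]
  alleles <- alleles[keep]
  a1 <- vapply(alleles, `[`, "", 1)
  samp <- as.matrix(dat[, -(1:4), drop = FALSE])
  code_one <- function(gt, ref) {
    if (is.na(gt) || gt %in% c("NN", "--", "N", "-", "")) return(NA_real_)
    ch <- strsplit(gt, "")[[1]]
    if (length(ch) != 2) return(NA_real_)
    sum(ch == ref)
  }
  geno <- matrix(NA_real_, nrow = ncol(samp), ncol = nrow(samp))
  for (j in seq_len(nrow(samp))) {
    geno[, j] <- vapply(samp[j, ], code_one, 0, ref = a1[j])
  }
  rownames(geno) <- colnames(samp)
  map <- tibble(
    snp_id = dat$rs, chrom = dat$chrom, pos = as.integer(dat$pos),
    allele_minor = a1, allele_major = vapply(alleles, `[`, "", 2)
  )
  genotype_matrix(geno, map)
}

read_genotypes_matrix <- function(path) {
  dat <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), .default = readr::col_character()
  ), progress = FALSE, na = c("NA", "."))
  if (!all(c("snp_id", "chrom", "pos") %in% names(dat))) {
    abort("malformed matrix TSV header (line 1): need snp_id, chrom, pos")
  }
  if (anyDuplicated(dat$snp_id)) abort("duplicate snp_id in matrix TSV")
  body <- as.matrix(dat[, setdiff(names(dat), c("snp_id", "chrom", "pos")), drop = FALSE])
  storage.mode(body) <- "double"
  geno <- t(body)
  map <- tibble(snp_id = dat$snp_id, chrom = dat$chrom, pos = dat$pos)
  genotype_matrix(geno, map)
}

#' Write a genotype panel as matrix TSV
#'
#' Inverse of `read_genotypes(format = "matrix_tsv")`.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  out <- cbind(g$map[, c("snp_id", "chrom", "pos")],
               as.data.frame(t(g$geno), check.names = FALSE))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an accession phenotype table
#'
#' @param path CSV with columns `accession_id`, `aspect_ratio` and optional
#'   `n_seeds`.
#' @return A tibble with one row per accession; `n_seeds` is `NA` when not
#'   recorded.
#' @export
read_phenotypes <- function(path) {
  dat <- readr::read_csv(path, col_types = readr::cols(
    accession_id = readr::col_character(),
    aspect_ratio = readr::col_double(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!all(c("accession_id", "aspect_ratio") %in% names(dat))) {
    abort("phenotype CSV must have columns accession_id, aspect_ratio")
  }
  if (anyDuplicated(dat$accession_id)) {
    abort(paste0("duplicate accession: ",
                 paste(unique(dat$accession_id[duplicated(dat$accession_id)]), collapse = ", ")))
  }
  if (any(dat$aspect_ratio < 1, na.rm = TRUE)) {
    abort("aspect_ratio < 1 found; the ratio is major/minor >= 1 - did the axes get swapped?")
  }
  if (!"n_seeds" %in% names(dat)) dat$n_seeds <- NA_integer_
  dat[, c("accession_id", "aspect_ratio", "n_seeds")]
}

#' Read gene models from GFF3
#'
#' Retains rows of type `gene` only; 1-based inclusive coordinates are kept
#' exactly as written.
#'
#' @param path GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff <- function(path) {
  empty <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character())
  lines <- readLines(path, warn = FALSE)
  body_lines <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body_lines)) return(empty)
  gff <- ape::read.gff(path, GFF3 = TRUE)
  bad <- which(gff$end < gff$start)
  if (length(bad)) {
    abort(sprintf("end < start at line %d of %s", body_lines[bad[1]], path))
  }
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (!nrow(genes)) return(empty)
  id <- sub(".*?ID=([^;]+).*", "\\1", genes$attributes)
  noid <- !grepl("ID=", genes$attributes)
  id[noid] <- paste0("gene_", which(noid))
  tibble(
    gene_id = id,
    chrom = as.character(genes$seqid),
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = as.character(genes$strand)
  )
}

#' Write a result table as TSV
#'
#' Tab-separated, one header line, floating point at 8 significant digits.
#' [read_results()] round-trips the file.
#'
#' @param results a data frame (association results, LD pair statistics,
#'   selection profiles, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- as.data.frame(results)
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 8, format = "g"))
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE),
    error = function(e) abort(paste0("cannot write ", path, ": ", conditionMessage(e)))
  )
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                  na = c("NA", ""))
}
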