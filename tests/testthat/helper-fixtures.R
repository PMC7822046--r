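# Small deterministic builders used across the suite.

# A genotype_matrix from a plain code matrix (rows = accessions).
toy_genotypes <- function(codes, chrom = NULL, pos = NULL) {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  cn <- colnames(codes)
  if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn))) {
    cn <- sprintf("snp%02d", seq_len(m))
  }
  genotype_matrix(
    codes,
    tibble::tibble(
      snp_id = cn,
      chrom = chrom %||% rep("chr01", m),
      pos = pos %||% seq(1000, by = 1000, length.out = m)
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The five printed top p-values of the published seed-aspect-ratio scan,
# used as an arithmetic fixture for the FDR machinery.
table1_fixture <- function() {
  tibble::tibble(
    snp_id = c("AX-177640219", "AX-147235444", "AX-176807953",
               "AX-176822392", "AX-147262340"),
    chrom = c("Araip.B08", "Aradu.A10", "Aradu.A09", "Araip.B08", "Araip.B09"),
    pos = c(12829161, 8911644, 113907685, 121783058, 143554366),
    p_value = c(2.31e-6, 5.91e-5, 6.95e-5, 9.55e-5, 9.80e-5)
  )
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Haplotype-level r2 between two dosage vectors, for LD sanity checks.
dosage_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  suppressWarnings(cor(a[ok], b[ok])^2)
}

# Direct likelihood oracle: with allele margins fixed at their sample
# frequencies (which the EM preserves), the two-locus likelihood is a 1-D
# function of the AB haplotype frequency; maximize it on a fine grid.
em_grid_oracle <- function(ga, gb, step = 1e-5) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  cnt <- tabulate(3 * ga + gb + 1, nbins = 9)
  pA <- mean(ga) / 2
  pB <- mean(gb) / 2
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(fAB) {
    fAb <- pA - fAB; faB <- pB - fAB; fab <- 1 - pA - pB + fAB
    probs <- c(fab^2, 2 * fab * faB, faB^2,
               2 * fab * fAb, 2 * (fAB * fab + fAb * faB),
               2 * faB * fAB, fAb^2, 2 * fAb * fAB, fAB^2)
    sum(cnt[cnt > 0] * log(pmax(probs[cnt > 0], 1e-300)))
  }, 0)
  grid[which.max(ll)]
}

sim_unphased_pair <- function(n, pA, pB, d, seed) {
  # phased haplotypes with disequilibrium d, then phase stripped
  set.seed(seed)
  fAB <- pA * pB + d
  probs <- c(AB = fAB, Ab = pA - fAB, aB = pB - fAB, ab = 1 - pA - pB + fAB)
  stopifnot(all(probs >= 0))
  hap <- function() sample(1:4, n, replace = TRUE, prob = probs)
  h1 <- hap(); h2 <- hap()
  a_of <- c(1, 1, 0, 0); b_of <- c(1, 0, 1, 0)
  list(ga = a_of[h1] + a_of[h2], gb = b_of[h1] + b_of[h2])
}
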