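# Seeded evaluation: run code under a private RNG stream so generators are
# pure functions of their arguments and never disturb the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a structured diversity-panel genotype matrix
#'
#' Generates a diploid panel with subpopulation differentiation and blockwise
#' linkage disequilibrium, the shape of a crop array dataset: `n_accessions`
#' accessions split evenly over `n_subpops` subpopulations, `n_snps` biallelic
#' SNPs spread over `n_chromosomes` chromosomes.
#'
#' Ancestral allele frequencies are drawn uniformly in `maf_range`;
#' subpopulation frequencies follow a Balding-Nichols draw
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst`. Along each chromosome,
#' haplotypes follow a latent-uniform copying process: the latent uniform
#' deciding the allele is copied from the previous SNP with probability
#' `exp(-d / ld_block_bp)` (d = inter-SNP distance), giving allelic
#' correlation `r(d) ~ exp(-d / ld_block_bp)` so that mean r-squared falls
#' below 0.1 at roughly `1.15 * ld_block_bp`. Copying acts on the latent
#' uniform, not the allele, so per-SNP marginal frequencies are exact.
#'
#' Accessions are modelled as fully inbred lines (one haplotype, doubled),
#' the realistic state of a selfing crop's germplasm collection; observed
#' heterozygous calls are array-calling artifacts. Contamination is
#' heterogeneous across markers, as on real arrays: each SNP draws its own
#' missingness and heterozygosity injection probability from a right-skewed
#' `Beta(1, (1 - rate)/rate)` distribution with the stated mean rate, so a
#' minority of "bad" markers carries most of the contamination and the
#' standard QC filter has something real to remove. Chromosome length
#' defaults to `n_snps_per_chrom / 5.91` Mb so marker density matches a
#' typical mid-density array.
#'
#' @param n_accessions,n_snps,n_chromosomes panel dimensions.
#' @param n_subpops number of subpopulations (even split).
#' @param fst differentiation among subpopulations, in `[0, 1)`.
#' @param ld_block_bp LD decay scale in bp.
#' @param maf_range ancestral allele-frequency range, within `(0, 0.5]`.
#' @param missing_rate,het_rate contamination rates in `[0, 1)`.
#' @param seed integer seed; same seed, same panel.
#' @return A list with `genotypes` (a [genotype_matrix()], minor-allele
#'   coded) and `truth` (subpopulation assignment, chromosome lengths,
#'   ancestral frequencies, parameters).
#' @export
simulate_panel <- function(n_accessions = 384, n_snps = 14030,
                           n_chromosomes = 20, n_subpops = 2, fst = 0.15,
                           ld_block_bp = 150000, maf_range = c(0.05, 0.5),
                           missing_rate = 0.05, het_rate = 0.10,
                           seed = 1) {
  stopifnot(n_accessions >= 2, n_snps >= n_chromosomes, n_subpops >= 1)
  if (fst < 0 || fst >= 1) abort("fst must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1 || het_rate < 0 || het_rate >= 1) {
    abort("missing_rate and het_rate must be in [0, 1)")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("maf_range must lie within (0, 0.5]")
  }
  with_seed(seed, {
    per_chrom <- rep(n_snps %/% n_chromosomes, n_chromosomes)
    extra <- n_snps %% n_chromosomes
    if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1
    chrom_names <- sprintf("chr%02d", seq_len(n_chromosomes))
    chrom_len <- pmax(round(per_chrom * 1e6 / 5.91), ld_block_bp * 2L)

    subpop <- rep(seq_len(n_subpops), length.out = n_accessions)
    n_hap <- n_accessions  # one haplotype per fully inbred accession
    hap_subpop <- subpop

    geno <- matrix(0, nrow = n_accessions, ncol = n_snps)
    map_list <- vector("list", n_chromosomes)
    p_anc_all <- numeric(n_snps)
    offset <- 0L
    # AR(1) latent Gaussian along a chromosome, correlation exp(-d / scale)
    ar1_latent <- function(pos, scale) {
      m <- length(pos)
      z <- numeric(m)
      z[1] <- rnorm(1)
      if (m > 1) {
        rho <- exp(-diff(pos) / scale)
        eps <- rnorm(m - 1)
        for (j in 2:m) z[j] <- rho[j - 1] * z[j - 1] + sqrt(1 - rho[j - 1]^2) * eps[j - 1]
      }
      z
    }
    for (ch in seq_len(n_chromosomes)) {
      m <- per_chrom[ch]
      pos <- sort(sample.int(chrom_len[ch], m, replace = FALSE))
      # ancestral frequencies vary smoothly along the chromosome (shared
      # descent correlates local frequencies as well as alleles), uniform
      # in maf_range marginally; the frequency field moves on a slower
      # scale than haplotype copying so that the r2 decay length is set by
      # ld_block_bp rather than by frequency mismatch between neighbours
      freq_scale <- 4 * ld_block_bp
      p_anc <- maf_range[1] +
        (maf_range[2] - maf_range[1]) * pnorm(ar1_latent(pos, freq_scale))
      p_sub <- matrix(p_anc, nrow = n_subpops, ncol = m, byrow = TRUE)
      if (fst > 0 && n_subpops > 1) {
        shape_scale <- (1 - fst) / fst
        for (s in seq_len(n_subpops)) {
          # Balding-Nichols drift, spatially correlated via a Gaussian copula
          q <- pnorm(ar1_latent(pos, freq_scale))
          p_sub[s, ] <- qbeta(q, p_anc * shape_scale, (1 - p_anc) * shape_scale)
        }
        # keep every subpopulation polymorphic-capable
        p_sub <- pmin(pmax(p_sub, 1e-4), 1 - 1e-4)
      }
      copy_p <- c(0, exp(-diff(pos) / ld_block_bp))
      u <- runif(n_hap)
      hap_block <- matrix(0L, nrow = n_hap, ncol = m)
      for (j in seq_len(m)) {
        if (j > 1L) {
          fresh <- runif(n_hap) >= copy_p[j]
          u[fresh] <- runif(sum(fresh))
        }
        hap_block[, j] <- (u < p_sub[hap_subpop, j]) + 0L
      }
      geno[, (offset + 1L):(offset + m)] <- 2 * hap_block
      map_list[[ch]] <- tibble(
        snp_id = sprintf("S%02d_%07d", ch, pos),
        chrom = chrom_names[ch], pos = pos
      )
      p_anc_all[(offset + 1L):(offset + m)] <- p_anc
      offset <- offset + m
    }

    per_snp_rate <- function(mean_rate) {
      if (mean_rate <= 0) return(rep(0, n_snps))
      rbeta(n_snps, 1, (1 - mean_rate) / mean_rate)
    }
    het_p <- per_snp_rate(het_rate)
    if (het_rate > 0) {
      flip <- which(geno != 1 &
                      matrix(runif(length(geno)), nrow(geno)) <
                      matrix(het_p, nrow(geno), n_snps, byrow = TRUE))
      geno[flip] <- 1
    }
    miss_p <- per_snp_rate(missing_rate)
    if (missing_rate > 0) {
      drop_idx <- matrix(runif(length(geno)), nrow(geno)) <
        matrix(miss_p, nrow(geno), n_snps, byrow = TRUE)
      geno[drop_idx] <- NA_real_
    }
    rownames(geno) <- sprintf("acc%03d", seq_len(n_accessions))
    map <- dplyr::bind_rows(map_list)
    g <- recode_to_minor(genotype_matrix(geno, map))

    truth <- list(
      subpop_assignment = tibble(accession_id = rownames(geno), subpop = subpop),
      chrom_lengths = setNames(chrom_len, chrom_names),
      ancestral_freq = setNames(p_anc_all, map$snp_id),
      params = list(
        n_accessions = n_accessions, n_snps = n_snps,
        n_chromosomes = n_chromosomes, n_subpops = n_subpops, fst = fst,
        ld_block_bp = ld_block_bp, maf_range = maf_range,
        missing_rate = missing_rate, het_rate = het_rate, seed = seed
      )
    )
    list(genotypes = g, truth = truth)
  })
}

#' Simulate an aspect-ratio phenotype on a genotype panel
#'
#' Phenotype model: `baseline + sum(effect * code) + polygenic + noise`.
#' The polygenic term is drawn from `MVN(0, K)` (K the VanRaden kinship of
#' the panel) and rescaled so its empirical variance equals
#' `h2_polygenic * (v_causal + noise_sd^2) / (1 - h2_polygenic)`, i.e.
#' `h2_polygenic` is the fraction of total phenotypic variance explained by
#' the polygenic background. Missing genotype codes are mean-imputed per SNP
#' for the causal contribution. Values below 1 (the geometric floor of an
#' aspect ratio) are truncated to 1 with a message.
#'
#' @param G a [genotype_matrix()].
#' @param causal data frame with columns `snp_id`, `effect` (aspect-ratio
#'   units per minor-allele copy); may have zero rows.
#' @param h2_polygenic polygenic variance fraction in `[0, 1)`.
#' @param noise_sd residual standard deviation (aspect-ratio units).
#' @param baseline intercept, `>= 1`.
#' @param seed integer seed.
#' @return A list with `phenotypes` (tibble `accession_id`, `aspect_ratio`,
#'   `n_seeds`) and `truth` (causal table, variance components, seed).
#' @export
simulate_phenotype <- function(G, causal = tibble(snp_id = character(), effect = numeric()),
                               h2_polygenic = 0, noise_sd = 0.05,
                               baseline = 1.63, seed = 1) {
  causal <- as_tibble(causal)
  if (baseline < 1) abort("baseline must be >= 1 (aspect ratios are >= 1)")
  if (h2_polygenic < 0 || h2_polygenic >= 1) abort("h2_polygenic must be in [0, 1)")
  miss <- setdiff(causal$snp_id, G$map$snp_id)
  if (length(miss)) {
    abort(paste0("unknown causal snp_id: ", paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(causal$effect %||% numeric()))) abort("causal effects must be finite")
  with_seed(seed, {
    n <- n_accessions(G)
    g_causal <- numeric(n)
    if (nrow(causal)) {
      X <- G$geno[, causal$snp_id, drop = FALSE]
      X <- impute_mean(X)
      g_causal <- drop(X %*% causal$effect)
    }
    v_causal <- if (n > 1) var(g_causal) else 0
    polygenic <- numeric(n)
    v_poly <- 0
    if (h2_polygenic > 0) {
      K <- kinship(G)
      L <- chol(K + diag(1e-8, n))
      u <- drop(t(L) %*% rnorm(n))
      v_poly <- h2_polygenic * (v_causal + noise_sd^2) / (1 - h2_polygenic)
      su <- sd(u)
      if (su > 0) polygenic <- u / su * sqrt(v_poly)
    }
    noise <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
    y <- baseline + g_causal + polygenic + noise
    n_trunc <- sum(y < 1)
    if (n_trunc > 0) {
      inform(sprintf("%d phenotype value(s) below 1 truncated to 1", n_trunc))
      y[y < 1] <- 1
    }
    genetic_value <- g_causal + polygenic
    list(
      phenotypes = tibble(accession_id = rownames(G$geno), aspect_ratio = y,
                          n_seeds = NA_integer_),
      truth = list(causal = causal, baseline = baseline,
                   h2_polygenic = h2_polygenic, noise_sd = noise_sd,
                   v_causal = v_causal, v_polygenic = v_poly,
                   genetic_value = setNames(genetic_value, rownames(G$geno)),
                   n_truncated = n_trunc, seed = seed)
    )
  })
}

raster_ellipse <- function(size, cx, cy, a, b, theta = 0) {
  xs <- matrix(seq_len(size), nrow = size, ncol = size, byrow = TRUE)
  ys <- matrix(seq_len(size), nrow = size, ncol = size)
  dx <- xs - cx
  dy <- ys - cy
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Simulate binary seed-scan images
#'
#' Each image holds one filled ellipse; semi-axes are drawn around the target
#' aspect ratio with coefficient of variation `axis_noise_cv`, at random
#' orientation, centred with a small jitter.
#'
#' @param true_ratio target aspect ratio, `>= 1`.
#' @param n_seeds number of images.
#' @param axis_noise_cv coefficient of variation of both semi-axes.
#' @param image_size canvas side in pixels.
#' @param semi_minor_px nominal semi-minor axis in pixels.
#' @param seed integer seed.
#' @return A list with `images` (list of logical matrices) and `truth`
#'   (tibble of exact semi-axes, orientation, and ratio per seed).
#' @export
simulate_seed_images <- function(true_ratio, n_seeds = 10, axis_noise_cv = 0.05,
                                 image_size = 128, semi_minor_px = image_size / 6,
                                 seed = 1) {
  if (true_ratio < 1) abort("true_ratio must be >= 1")
  with_seed(seed, {
    images <- vector("list", n_seeds)
    truth <- vector("list", n_seeds)
    cx0 <- (image_size + 1) / 2
    for (i in seq_len(n_seeds)) {
      b <- semi_minor_px * (1 + axis_noise_cv * rnorm(1))
      a <- true_ratio * semi_minor_px * (1 + axis_noise_cv * rnorm(1))
      if (a < b) { tmp <- a; a <- b; b <- tmp }
      theta <- runif(1, 0, pi)
      jitter <- runif(2, -2, 2)
      cx <- cx0 + jitter[1]
      cy <- cx0 + jitter[2]
      if (cx - a < 2 || cx + a > image_size - 1 ||
          cy - a < 2 || cy + a > image_size - 1) {
        abort("ellipse does not fit inside the canvas; increase image_size")
      }
      images[[i]] <- raster_ellipse(image_size, cx, cy, a, b, theta)
      truth[[i]] <- tibble(seed_index = i, semi_major = a, semi_minor = b,
                           theta = theta, ratio = a / b)
    }
    list(images = images, truth = dplyr::bind_rows(truth))
  })
}

impute_mean <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  X
}
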