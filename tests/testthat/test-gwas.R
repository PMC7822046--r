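test_that("kinship matches a brute-force VanRaden evaluation", {
  codes <- rbind(
    c(0, 1, 2, 0, 2, 1),
    c(2, 1, 0, 0, 2, 0),
    c(0, 0, 2, 2, 0, 1),
    c(1, 2, 0, 0, 1, 2)
  )
  g <- toy_genotypes(codes)
  K <- kinship(g)
  f <- colMeans(codes) / 2
  W <- sweep(codes, 2, 2 * f)
  K_oracle <- tcrossprod(W) / (2 * sum(f * (1 - f)))
  K_oracle <- K_oracle + diag(1e-6 * mean(diag(K_oracle)), 4)
  expect_equal(unname(K), unname(K_oracle), tolerance = 1e-12)
})

test_that("identical accessions have kinship equal to the diagonal", {
  codes <- rbind(a = c(0, 1, 2, 0, 2), b = c(0, 1, 2, 0, 2),
                 c = c(2, 1, 0, 2, 0))
  K <- kinship(toy_genotypes(codes))
  expect_equal(K[1, 2], K[1, 1], tolerance = 1e-5)
  expect_error(kinship(toy_genotypes(matrix(2, 3, 4))), "monomorphic")
})

test_that("unrelated accessions at many SNPs have near-zero kinship", {
  set.seed(31)
  codes <- 2 * matrix(rbinom(200 * 5000, 1, 0.5), 200, 5000)
  K <- kinship(toy_genotypes(codes))
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.02)
})

test_that("REML finds no genetic variance in unstructured noise", {
  p <- simulate_panel(n_accessions = 384, n_snps = 400, n_chromosomes = 2,
                      seed = 77)
  K <- kinship(p$genotypes)
  eig <- eigen(K, symmetric = TRUE)
  set.seed(5)
  small_lambda <- replicate(20, {
    fit <- suppressWarnings(reml_variance_components(rnorm(384), K, eig = eig))
    fit$lambda
  })
  # null sampling spread of the one-sided variance ratio: about half the
  # estimates sit at the boundary, the rest are O(1/n)
  expect_lt(median(small_lambda), 1e-3)
  expect_gte(mean(small_lambda < 0.1), 0.9)
})

test_that("REML optimum dominates a fixed unit variance ratio", {
  set.seed(8)
  p <- simulate_panel(n_accessions = 150, n_snps = 500, n_chromosomes = 2,
                      seed = 41)
  K <- kinship(p$genotypes)
  n <- 150
  u <- drop(t(chol(K + diag(1e-8, n))) %*% rnorm(n))
  y <- u / sd(u) + rnorm(n)
  fit <- reml_variance_components(y, K)
  eig <- eigen(K, symmetric = TRUE)
  ll_at_1 <- gwaspect:::reml_loglik_at(
    0, pmax(eig$values, 0),
    drop(crossprod(eig$vectors, y)), crossprod(eig$vectors, matrix(1, n, 1))
  )
  expect_gte(fit$loglik, ll_at_1 - 1e-6)
  expect_equal(glance(fit)$h2, fit$h2)
})

test_that("forcing zero genetic variance reduces the scan to least squares", {
  p <- simulate_panel(n_accessions = 100, n_snps = 300, n_chromosomes = 2,
                      missing_rate = 0, seed = 13)
  G <- p$genotypes
  ph <- simulate_phenotype(G, h2_polygenic = 0.3, noise_sd = 0.05, seed = 6)
  K <- kinship(G)
  scan <- mlm_scan(G, ph$phenotypes, K, vc = list(sigma_g2 = 0, sigma_e2 = 1))
  y <- ph$phenotypes$aspect_ratio
  X <- gwaspect:::impute_mean(G$geno)
  take <- scan$snp_id[seq(1, nrow(scan), by = 23)]
  p_ols <- vapply(take, function(s) {
    summary(lm(y ~ X[, s]))$coefficients[2, 4]
  }, 0)
  expect_lt(max(abs(p_ols - scan$p_value[match(take, scan$snp_id)])), 1e-8)
})

test_that("scan p-values are invariant to affine rescaling of the phenotype", {
  p <- simulate_panel(n_accessions = 80, n_snps = 200, n_chromosomes = 2,
                      seed = 19)
  G <- p$genotypes
  ph <- simulate_phenotype(G, h2_polygenic = 0.4, noise_sd = 0.05, seed = 3)
  K <- kinship(G)
  s1 <- mlm_scan(G, ph$phenotypes, K)
  ph2 <- ph$phenotypes
  ph2$aspect_ratio <- -3.7 * ph2$aspect_ratio + 11
  s2 <- mlm_scan(G, ph2, K)
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-9)
})

test_that("full REML per marker agrees with P3D on a well-behaved panel", {
  p <- simulate_panel(n_accessions = 60, n_snps = 60, n_chromosomes = 1,
                      seed = 3)
  G <- p$genotypes
  st <- snp_stats(G)
  causal <- st$snp_id[which.max(st$maf)]
  ph <- simulate_phenotype(G, causal = data.frame(snp_id = causal, effect = 0.2),
                           h2_polygenic = 0.2, noise_sd = 0.05, seed = 5)
  K <- kinship(G)
  s_p3d <- mlm_scan(G, ph$phenotypes, K, mode = "p3d")
  s_full <- suppressWarnings(mlm_scan(G, ph$phenotypes, K, mode = "full_reml"))
  expect_equal(s_p3d$snp_id[1], s_full$snp_id[1])
  common <- intersect(s_p3d$snp_id, s_full$snp_id)
  lp1 <- -log10(s_p3d$p_value[match(common, s_p3d$snp_id)])
  lp2 <- -log10(s_full$p_value[match(common, s_full$snp_id)])
  expect_gt(cor(lp1, lp2), 0.98)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  bh_oracle <- function(p, m = length(p)) {
    k <- length(p)
    o <- order(p)
    adj_sorted <- numeric(k)
    for (i in seq_len(k)) {
      cands <- vapply(i:k, function(j) p[o][j] * m / j, 0)
      adj_sorted[i] <- min(c(cands, 1))
    }
    out <- numeric(k)
    out[o] <- adj_sorted
    out
  }
  set.seed(99)
  for (rep in 1:20) {
    k <- sample(1:6, 1)
    p <- runif(k)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
    m_tot <- k + sample(0:100, 1)
    expect_equal(bh_fdr(p, m_tot), bh_oracle(p, m_tot), tolerance = 1e-12)
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 0.1), m_total = 1), "m_total")
})

test_that("adjusted p is monotone in raw p and bounded below by it", {
  set.seed(3)
  p <- runif(200)^2
  adj <- bh_fdr(p)
  expect_true(all(adj >= p - 1e-12))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
})

test_that("the published five-marker table is reproduced by the FDR arithmetic", {
  tab <- table1_fixture()
  adj <- bh_fdr(tab$p_value, m_total = 14030)
  expect_equal(adj[1], 0.0324, tolerance = 5e-3)
  expect_equal(signif(adj[1], 2), 0.032)
  expect_true(all(adj[-1] > 0.05))

  res <- tab |>
    dplyr::mutate(fdr_adjusted_p = adj)
  rep <- significance_report(res, fdr_cutoff = 0.05, candidate_p = 1e-4)
  expect_equal(nrow(rep$candidates), 5)
  expect_equal(nrow(rep$significant), 1)
  expect_equal(rep$significant$snp_id, "AX-177640219")
})

test_that("significance_report handles empty and all-null scans", {
  empty <- tibble::tibble(snp_id = character(), chrom = character(),
                          pos = integer(), p_value = numeric(),
                          fdr_adjusted_p = numeric())
  rep0 <- significance_report(empty)
  expect_equal(nrow(rep0$significant), 0)
  expect_equal(nrow(rep0$candidates), 0)
  all1 <- tibble::tibble(snp_id = "s", chrom = "c", pos = 1L,
                         p_value = 1, fdr_adjusted_p = 1)
  rep1 <- significance_report(all1)
  expect_equal(nrow(rep1$significant) + nrow(rep1$candidates), 0)
})

test_that("plot tables carry every marker and the null QQ sits on the diagonal", {
  set.seed(2)
  m <- 10000
  res <- tibble::tibble(
    snp_id = paste0("s", 1:m), chrom = rep(c("c1", "c2"), m / 2),
    pos = rep(1:(m / 2), 2), p_value = runif(m),
    fdr_adjusted_p = bh_fdr(runif(m))
  )
  pd <- gwas_plot_data(res)
  expect_equal(nrow(pd$manhattan), m)
  expect_equal(nrow(pd$qq), m)
  # body of the distribution hugs the diagonal (the extreme tail has
  # order-statistic noise of order 1/sqrt(rank))
  body <- pd$qq$expected <= 2
  expect_lt(max(abs(pd$qq$expected[body] - pd$qq$observed[body])), 0.2)
  expect_gt(cor(pd$qq$expected, pd$qq$observed), 0.99)
  one <- gwas_plot_data(tibble::tibble(snp_id = "s", chrom = "c", pos = 1L,
                                       p_value = 1e-6, fdr_adjusted_p = 1e-2))
  expect_equal(one$manhattan$neglog10_p, 6)
})
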