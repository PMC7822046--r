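enet_objective <- function(X, y, beta, lambda, alpha) {
  n <- length(y)
  sum((y - X %*% beta)^2) / (2 * n) + lambda * alpha * sum(abs(beta)) +
    lambda * (1 - alpha) * sum(beta^2)
}

test_that("the lasso null threshold zeroes every coefficient", {
  set.seed(1)
  X <- gwaspect:::standardize_cols(matrix(rnorm(50 * 20), 50, 20))$X
  y <- rnorm(50); y <- y - mean(y)
  lambda_max <- max(abs(crossprod(X, y))) / length(y)
  b <- elastic_net_fit(X, y, lambda = lambda_max * 1.0001, alpha = 1,
                       standardize = FALSE)
  expect_true(all(b == 0))
  b2 <- elastic_net_fit(X, y, lambda = lambda_max * 0.8, alpha = 1,
                        standardize = FALSE)
  expect_gt(sum(b2 != 0), 0)
})

test_that("a single standardized predictor has the soft-threshold solution", {
  set.seed(2)
  n <- 100
  x <- rnorm(n)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- 0.4 * x + rnorm(n)
  y <- y - mean(y)
  z <- sum(x * y) / n
  for (lam in c(0.01, 0.1, 0.3, 2)) {
    b <- elastic_net_fit(matrix(x), y, lambda = lam, alpha = 1,
                         standardize = FALSE)
    soft <- sign(z) * max(abs(z) - lam, 0)
    expect_equal(unname(b), soft, tolerance = 1e-8)
  }
})

test_that("an unpenalized full-rank fit is ordinary least squares", {
  set.seed(3)
  n <- 80; p <- 10
  X <- gwaspect:::standardize_cols(matrix(rnorm(n * p), n, p))$X
  y <- drop(X %*% rnorm(p)) + rnorm(n); y <- y - mean(y)
  b <- elastic_net_fit(X, y, lambda = 0, standardize = FALSE)
  b_ols <- coef(lm(y ~ X - 1))
  expect_equal(unname(b), unname(b_ols), tolerance = 1e-6)
})

test_that("coordinate descent minimizes the printed objective", {
  set.seed(4)
  n <- 60; p <- 30
  X <- gwaspect:::standardize_cols(matrix(rnorm(n * p), n, p))$X
  y <- drop(X[, 1:3] %*% c(1, -1, 0.5)) + rnorm(n); y <- y - mean(y)
  for (alpha in c(1, 0.5)) {
    lam <- 0.1
    b <- elastic_net_fit(X, y, lambda = lam, alpha = alpha,
                         standardize = FALSE)
    q_hat <- enet_objective(X, y, b, lam, alpha)
    expect_lte(q_hat, enet_objective(X, y, rep(0, p), lam, alpha))
    # local perturbations never improve the objective
    for (k in 1:20) {
      bp <- b + rnorm(p, 0, 0.01)
      expect_gte(enet_objective(X, y, bp, lam, alpha), q_hat - 1e-10)
    }
  }
})

test_that("the lasso solution agrees with the glmnet oracle", {
  skip_if_not_installed("glmnet")
  set.seed(5)
  n <- 100; p <- 50
  X <- gwaspect:::standardize_cols(matrix(rnorm(n * p), n, p))$X
  y <- drop(X[, 1:4] %*% c(1, -0.8, 0.6, -0.4)) + rnorm(n)
  # unit-variance centred response: glmnet standardizes y internally, which
  # rescales the ridge/L1 balance unless sd(y) is already 1
  y <- (y - mean(y)) / sd(y)
  lam <- 0.15
  b <- elastic_net_fit(X, y, lambda = lam, alpha = 1, standardize = FALSE)
  gfit <- glmnet::glmnet(X, y, alpha = 1, lambda = lam, standardize = FALSE,
                         intercept = FALSE, thresh = 1e-12)
  expect_equal(unname(b), unname(as.numeric(gfit$beta)), tolerance = 1e-5)

  # elastic net: this penalty's lambda*(1-alpha)*L2 maps onto glmnet's
  # lambda_g*(1-alpha_g)/2*L2 with lambda_g*alpha_g = lambda*alpha
  lam_l1 <- 0.1; lam_l2 <- 0.05
  lam_g <- lam_l1 + 2 * lam_l2
  alpha_g <- lam_l1 / lam_g
  b2 <- elastic_net_fit(X, y, lambda = lam_l1 + lam_l2,
                        alpha = lam_l1 / (lam_l1 + lam_l2),
                        standardize = FALSE)
  gfit2 <- glmnet::glmnet(X, y, alpha = alpha_g, lambda = lam_g,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-12)
  # both solvers sit at the unique minimum; residual differences reflect
  # glmnet's convergence-threshold scale
  expect_equal(unname(b2), unname(as.numeric(gfit2$beta)), tolerance = 1e-3)
})

test_that("selection probabilities with one resample are exactly 0 or 1", {
  set.seed(6)
  X <- matrix(rbinom(60 * 40, 2, 0.3), 60, 40)
  y <- rnorm(60)
  prof <- selection_probability(X, y, B = 1, seed = 1)
  expect_true(all(prof$profile$selection_probability %in% c(0, 1)))
  expect_equal(prof$B, 1)
})

test_that("selection probability is reproducible and column-order invariant", {
  set.seed(7)
  X <- matrix(rbinom(80 * 30, 2, 0.4), 80, 30)
  colnames(X) <- paste0("m", 1:30)
  y <- 0.8 * X[, 7] + rnorm(80)
  p1 <- selection_probability(X, y, B = 20, seed = 9)
  p2 <- selection_probability(X, y, B = 20, seed = 9)
  expect_identical(p1$profile, p2$profile)
  perm <- sample(30)
  p3 <- selection_probability(X[, perm], y, B = 20, seed = 9)
  expect_equal(p3$profile$selection_probability[match("m7", p3$profile$snp_id)],
               p1$profile$selection_probability[match("m7", p1$profile$snp_id)],
               tolerance = 0.3)
  expect_gte(p1$profile$selection_probability[7], 0.9)
})

test_that("a strong causal marker is selected almost always", {
  hits <- vapply(1:5, function(r) {
    set.seed(400 + r)
    n <- 200; p <- 500
    X <- matrix(rbinom(n * p, 2, 0.3), n, p)
    g <- X[, 123] * 0.5
    y <- g + rnorm(n, 0, sd(g) * sqrt(3))  # SNP explains ~25% of variance
    prof <- selection_probability(X, y, B = 50, seed = r)
    prof$profile$selection_probability[123]
  }, 0)
  expect_gte(mean(hits >= 0.9), 0.8)
})

test_that("the theoretical threshold follows the closed form", {
  expect_equal(theoretical_threshold(0, 1, 100), 0.5)
  expect_equal(theoretical_threshold(13, 1, 14030), 169 / 28060 + 0.5)
  expect_equal(round(theoretical_threshold(13, 1, 14030), 3), 0.506)
  expect_equal(theoretical_threshold(10, 1, 100), 1.0)
  expect_warning(v <- theoretical_threshold(15, 1, 100), "exceeds 1")
  expect_equal(v, 1.625)
  expect_error(theoretical_threshold(5, 1, 0), "p must be")
  # monotone: increasing in q, decreasing in theta and p
  expect_gt(theoretical_threshold(10, 1, 1000), theoretical_threshold(5, 1, 1000))
  expect_gt(theoretical_threshold(10, 1, 1000), theoretical_threshold(10, 2, 1000))
  expect_gt(theoretical_threshold(10, 1, 500),
            suppressWarnings(theoretical_threshold(10, 1, 1000)))
})

test_that("the empirical threshold is deterministic given its seed", {
  set.seed(8)
  X <- matrix(rbinom(50 * 30, 2, 0.4), 50, 30)
  y <- rnorm(50)
  t1 <- empirical_threshold(X, y, theta = 1, B_perm = 3, B_bootstrap = 10,
                            seed = 5)
  t2 <- empirical_threshold(X, y, theta = 1, B_perm = 3, B_bootstrap = 10,
                            seed = 5)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_length(attr(t1, "per_permutation"), 3)
  # theta = p takes the minimum selection probability per permutation
  tp <- empirical_threshold(X, y, theta = 30, B_perm = 2, B_bootstrap = 5,
                            seed = 5)
  expect_gte(as.numeric(tp), 0)
  expect_error(empirical_threshold(X, y, theta = 31, B_perm = 1), "theta")
})

test_that("marker selection applies a strict threshold with stable ordering", {
  prof <- structure(list(
    profile = tibble::tibble(
      snp_id = c("a", "b", "c"), chrom = "chr01", pos = c(100, 200, 300),
      selection_probability = c(0.95, 0.60, 0.10)
    ),
    B = 100, q_avg = 2, lambda = 0.1, alpha = 1, p = 3, theta = 1,
    theoretical_threshold = NA_real_, empirical_threshold = 0.894, seed = 1
  ), class = "selection_profile")
  expect_equal(select_markers(prof, "empirical")$snp_id, "a")
  expect_equal(nrow(select_markers(prof, 1.0)), 0)
  expect_equal(select_markers(prof, 0)$snp_id, c("a", "b", "c"))
  expect_error(select_markers(prof, "theoretical"), "not been set")
  # ties broken by genome order
  prof$profile$selection_probability <- c(0.6, 0.6, 0.6)
  expect_equal(select_markers(prof, 0.5)$snp_id, c("a", "b", "c"))
})

test_that("profile accessors expose one value per marker", {
  set.seed(9)
  p <- simulate_panel(n_accessions = 50, n_snps = 80, n_chromosomes = 2,
                      seed = 31)
  ph <- simulate_phenotype(p$genotypes, h2_polygenic = 0.3, noise_sd = 0.05,
                           seed = 2)
  prof <- selection_probability(p$genotypes, ph$phenotypes, B = 10, seed = 3)
  td <- tidy(prof)
  expect_equal(nrow(td), n_snps(p$genotypes))
  expect_true(all(td$selection_probability >= 0 & td$selection_probability <= 1))
  expect_true(all(abs(td$selection_probability * prof$B -
                        round(td$selection_probability * prof$B)) < 1e-9))
  expect_s3_class(autoplot(prof), "ggplot")
})
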