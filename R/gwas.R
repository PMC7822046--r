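#' Genomic relationship (kinship) matrix
#'
#' VanRaden method 1: missing calls are mean-imputed per SNP, each column is
#' centred by twice its allele frequency, and `K = W W' / (2 * sum(f(1-f)))`.
#' A ridge `1e-6 * mean(diag(K))` is added to the diagonal so downstream
#' factorizations see a positive-definite matrix.
#'
#' @param G a [genotype_matrix()].
#' @return A symmetric n-by-n kinship matrix.
#' @export
kinship <- function(G) {
  X <- impute_mean(G$geno)
  n <- nrow(X)
  if (n < 2) abort("need at least 2 accessions")
  f <- colMeans(X) / 2
  denom <- 2 * sum(f * (1 - f))
  if (denom <= 0) abort("all SNPs monomorphic; kinship undefined")
  W <- sweep(X, 2, 2 * f)
  K <- tcrossprod(W) / denom
  K + diag(1e-6 * mean(diag(K)), n)
}

reml_loglik_at <- function(log_lambda, d, yt, Xt) {
  lambda <- exp(log_lambda)
  w <- lambda * d + 1
  q <- ncol(Xt)
  n <- length(yt)
  Xw <- Xt / w
  XtWX <- crossprod(Xt, Xw)
  XtWy <- crossprod(Xw, yt)
  b <- solve(XtWX, XtWy)
  r <- yt - Xt %*% b
  rss <- sum(r^2 / w)
  sigma_e2 <- rss / (n - q)
  -0.5 * ((n - q) * log(2 * pi * sigma_e2) + (n - q) +
            sum(log(w)) + determinant(XtWX, logarithm = TRUE)$modulus[1])
}

#' REML variance components of the kinship mixed model
#'
#' Fits `y = X b + u + e`, `u ~ N(0, sigma_g2 K)`, `e ~ N(0, sigma_e2 I)` by
#' restricted maximum likelihood. One spectral decomposition of K reduces
#' the problem to a 1-D search over the variance ratio
#' `lambda = sigma_g2 / sigma_e2`, done on a log-spaced grid followed by
#' golden-section refinement (`stats::optimize`).
#'
#' @param y phenotype vector.
#' @param K kinship matrix (must be positive semidefinite).
#' @param X fixed-effect design matrix (default: intercept only).
#' @param eig optional pre-computed `eigen(K, symmetric = TRUE)`.
#' @return A `reml_fit`: `sigma_g2`, `sigma_e2`, `lambda`, `h2`, `loglik`,
#'   `at_bound`, plus the spectral pieces used by [mlm_scan()]. Methods:
#'   [tidy()], [glance()].
#' @export
reml_variance_components <- function(y, K, X = NULL, eig = NULL) {
  n <- length(y)
  if (nrow(K) != n) abort("length(y) must match dim(K)")
  if (sd(y) == 0) abort("phenotype is constant")
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values))) {
    abort("K is not positive semidefinite")
  }
  d <- pmax(eig$values, 0)
  # the variance-ratio search runs on the centred, unit-sd phenotype so the
  # estimate is numerically invariant under affine rescaling of y; the
  # variance components are mapped back to the original scale afterwards
  s_y <- sd(y)
  yt <- drop(crossprod(eig$vectors, (y - mean(y)) / s_y))
  Xt <- crossprod(eig$vectors, X)
  grid <- seq(-10, 10, length.out = 81)
  ll <- vapply(grid, reml_loglik_at, 0, d = d, yt = yt, Xt = Xt)
  i <- which.max(ll)
  at_bound <- i == 1L || i == length(grid)
  if (at_bound) warn("heritability at bound of the variance-ratio grid")
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(reml_loglik_at, c(lo, hi), d = d, yt = yt, Xt = Xt,
                  maximum = TRUE, tol = 1e-10)
  lambda <- exp(opt$maximum)
  w <- lambda * d + 1
  q <- ncol(Xt)
  Xw <- Xt / w
  b <- solve(crossprod(Xt, Xw), crossprod(Xw, yt))
  r <- yt - Xt %*% b
  sigma_e2 <- s_y^2 * sum(r^2 / w) / (n - q)
  # h2 as the per-accession variance share: diag(K) is ~1+F, not 1, for an
  # inbreeding panel, so the genetic variance per accession is sigma_g2 * Kii
  mean_kii <- mean(d)
  structure(
    list(sigma_g2 = lambda * sigma_e2, sigma_e2 = sigma_e2, lambda = lambda,
         h2 = lambda * mean_kii / (lambda * mean_kii + 1),
         loglik = opt$objective - (n - q) * log(s_y),
         at_bound = at_bound, eig = eig, n = n),
    class = "reml_fit"
  )
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("<reml_fit> sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f (n = %d)\n",
              x$sigma_g2, x$sigma_e2, x$h2, x$n))
  invisible(x)
}

#' @rdname reml_variance_components
#' @param x,object a `reml_fit`.
#' @param ... ignored.
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble(component = c("genetic", "residual"),
         estimate = c(x$sigma_g2, x$sigma_e2))
}

#' @rdname reml_variance_components
#' @export
glance.reml_fit <- function(x, ...) {
  tibble(sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2, h2 = x$h2,
         loglik = x$loglik, at_bound = x$at_bound, n = x$n)
}

#' Mixed-linear-model association scan
#'
#' Tests each marker by generalized least squares of the phenotype on
#' `[1, x]` (plus optional covariates) under covariance
#' `sigma_g2 K + sigma_e2 I`, with a Wald t-test on the marker coefficient.
#' The default `"p3d"` mode estimates the variance components once from the
#' no-marker model and holds them fixed across markers; `"full_reml"`
#' re-estimates them per marker. Missing genotypes are mean-imputed per SNP;
#' monomorphic markers are skipped with a message. Accessions lacking a
#' phenotype are dropped with a message.
#'
#' @param G a [genotype_matrix()] (post-QC).
#' @param phenotypes tibble with `accession_id`, `aspect_ratio` (or any
#'   numeric trait column named by `trait`).
#' @param K kinship matrix from [kinship()].
#' @param mode `"p3d"` or `"full_reml"`.
#' @param covariates optional numeric matrix of fixed-effect covariates
#'   (e.g. leading PCoA axes), rows aligned with accessions of `G`.
#' @param vc optional list `(sigma_g2, sigma_e2)` overriding REML (e.g.
#'   `sigma_g2 = 0` reduces the scan to ordinary least squares).
#' @param trait phenotype column name.
#' @return A tibble ordered by ascending p-value: `snp_id`, `chrom`, `pos`,
#'   `maf`, `effect`, `se`, `p_value`, `fdr_adjusted_p`. The REML fit and
#'   the number of tested markers are attached as attributes `"vc"` and
#'   `"m_tested"`.
#' @export
mlm_scan <- function(G, phenotypes, K, mode = c("p3d", "full_reml"),
                     covariates = NULL, vc = NULL, trait = "aspect_ratio") {
  mode <- match.arg(mode)
  acc <- rownames(G$geno)
  phen <- as_tibble(phenotypes)
  idx <- match(acc, phen$accession_id)
  keep <- !is.na(idx)
  if (!all(keep)) {
    inform(sprintf("dropping %d accession(s) without phenotype", sum(!keep)))
  }
  y <- phen[[trait]][idx[keep]]
  Gk <- G$geno[keep, , drop = FALSE]
  Kk <- K[keep, keep, drop = FALSE]
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  n <- length(y)
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)

  Ximp <- impute_mean(Gk)
  sds <- apply(Ximp, 2, sd)
  poly <- sds > 0
  if (!any(poly)) abort("all SNPs monomorphic; nothing to test")
  if (any(!poly)) inform(sprintf("skipping %d monomorphic SNP(s)", sum(!poly)))
  Ximp <- Ximp[, poly, drop = FALSE]
  map <- G$map[poly, , drop = FALSE]
  maf <- pmin(colMeans(Ximp) / 2, 1 - colMeans(Ximp) / 2)

  eig <- eigen(Kk, symmetric = TRUE)
  fit0 <- if (is.null(vc)) {
    reml_variance_components(y, Kk, X = X0, eig = eig)
  } else {
    list(sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2,
         lambda = vc$sigma_g2 / vc$sigma_e2, h2 = NA_real_, eig = eig, n = n)
  }

  if (mode == "p3d") {
    w <- fit0$lambda * pmax(eig$values, 0) + 1
    Tm <- t(eig$vectors) / sqrt(w)              # whitening transform
    yt <- drop(Tm %*% y)
    X0t <- Tm %*% X0
    Xt <- Tm %*% Ximp
    qr0 <- qr(X0t)
    ry <- qr.resid(qr0, yt)
    rx <- qr.resid(qr0, Xt)
    sxx <- colSums(rx^2)
    sxy <- colSums(rx * ry)
    beta <- sxy / sxx
    df <- n - ncol(X0) - 1
    rss <- sum(ry^2) - beta^2 * sxx
    se <- sqrt(pmax(rss, 0) / df / sxx)
    tval <- beta / se
    p <- 2 * pt(-abs(tval), df)
  } else {
    m <- ncol(Ximp)
    beta <- se <- p <- numeric(m)
    d <- pmax(eig$values, 0)
    U <- eig$vectors
    s_y <- sd(y)
    yt0 <- drop(crossprod(U, (y - mean(y)) / s_y))
    X0t0 <- crossprod(U, X0)
    for (j in seq_len(m)) {
      xt <- drop(crossprod(U, Ximp[, j]))
      Xt <- cbind(X0t0, xt)
      grid <- seq(-10, 10, length.out = 41)
      ll <- vapply(grid, reml_loglik_at, 0, d = d, yt = yt0, Xt = Xt)
      i <- which.max(ll)
      opt <- optimize(reml_loglik_at,
                      c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)]),
                      d = d, yt = yt0, Xt = Xt, maximum = TRUE, tol = 1e-10)
      w <- exp(opt$maximum) * d + 1
      Xw <- Xt / w
      XtWX <- crossprod(Xt, Xw)
      b <- solve(XtWX, crossprod(Xw, yt0))
      r <- yt0 - Xt %*% b
      df <- n - ncol(Xt)
      s2 <- sum(r^2 / w) / df
      cov_b <- s2 * solve(XtWX)
      k <- ncol(Xt)
      beta[j] <- b[k] * s_y
      se[j] <- sqrt(cov_b[k, k]) * s_y
      tv <- beta[j] / se[j]
      p[j] <- 2 * pt(-abs(tv), df)
    }
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  res <- tibble(
    snp_id = map$snp_id, chrom = map$chrom, pos = map$pos, maf = maf,
    effect = beta, se = se, p_value = p,
    fdr_adjusted_p = bh_fdr(p)
  ) |>
    arrange(.data$p_value)
  attr(res, "vc") <- fit0
  attr(res, "m_tested") <- nrow(res)
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment `adj_(i) = min_(j >= i) p_(j) * m / j`, capped at 1.
#' `m_total` lets a printed subset of p-values (e.g. a table of top hits) be
#' adjusted against the full number of tests performed.
#'
#' @param p_values p-values in `(0, 1]`.
#' @param m_total total number of tests; defaults to `length(p_values)`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values, m_total = NULL) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  k <- length(p_values)
  if (k == 0) return(numeric(0))
  m <- m_total %||% k
  if (m < k) abort("m_total must be at least length(p_values)")
  o <- order(p_values)
  ranked <- p_values[o] * m / seq_len(k)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(k)
  out[o] <- adj
  out
}

#' Significant and candidate markers of a scan
#'
#' @param results association tibble from [mlm_scan()] (needs `p_value` and
#'   `fdr_adjusted_p`).
#' @param fdr_cutoff FDR-adjusted significance cutoff.
#' @param candidate_p raw-p candidate cutoff.
#' @return A list of two tibbles sorted by ascending p: `significant`
#'   (adjusted p < `fdr_cutoff`) and `candidates` (raw p < `candidate_p`).
#' @export
significance_report <- function(results, fdr_cutoff = 0.05, candidate_p = 1e-4) {
  res <- arrange(as_tibble(results), .data$p_value)
  list(
    significant = filter(res, .data$fdr_adjusted_p < fdr_cutoff),
    candidates = filter(res, .data$p_value < candidate_p)
  )
}

#' Manhattan and QQ plot tables for a scan
#'
#' @param results association tibble from [mlm_scan()].
#' @return A list of two tibbles: `manhattan` (`snp_id`, `chrom`, `pos`,
#'   `neglog10_p`, genome order) and `qq` (`expected` vs `observed`
#'   `-log10 p` at plotting positions `(i - 0.5)/m`).
#' @export
gwas_plot_data <- function(results) {
  res <- as_tibble(results)
  manhattan <- res |>
    arrange(.data$chrom, .data$pos) |>
    mutate(neglog10_p = -log10(.data$p_value)) |>
    select("snp_id", "chrom", "pos", "neglog10_p")
  m <- nrow(res)
  obs <- sort(res$p_value)
  qq <- tibble(
    expected = -log10((seq_len(m) - 0.5) / m),
    observed = -log10(obs)
  ) |>
    arrange(dplyr::desc(.data$expected))
  list(manhattan = manhattan, qq = qq)
}

#' Manhattan plot of an association scan
#'
#' @param results association tibble from [mlm_scan()].
#' @param fdr_cutoff draw markers below this adjusted p in colour.
#' @return A ggplot.
#' @export
plot_manhattan <- function(results, fdr_cutoff = 0.05) {
  dat <- as_tibble(results) |>
    arrange(.data$chrom, .data$pos) |>
    mutate(neglog10_p = -log10(.data$p_value),
           significant = .data$fdr_adjusted_p < fdr_cutoff,
           order = row_number())
  ggplot2::ggplot(dat, ggplot2::aes(.data$order, .data$neglog10_p,
                                    colour = .data$chrom)) +
    ggplot2::geom_point(show.legend = FALSE, size = 0.7) +
    ggplot2::geom_point(data = filter(dat, .data$significant),
                        colour = "red", size = 1.5) +
    ggplot2::labs(x = "genome order", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' QQ plot of an association scan
#'
#' @param results association tibble from [mlm_scan()].
#' @return A ggplot.
#' @export
plot_qq <- function(results) {
  qq <- gwas_plot_data(results)$qq
  ggplot2::ggplot(qq, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}
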