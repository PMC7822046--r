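standardize_cols <- function(X, quiet = FALSE) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- sqrt(colMeans(Xc^2))
  keep <- s > 0
  if (!all(keep) && !quiet) {
    inform(sprintf("dropping %d zero-variance column(s) before fitting", sum(!keep)))
  }
  Xs <- sweep(Xc[, keep, drop = FALSE], 2, s[keep], "/")
  list(X = Xs, keep = keep, mu = mu, sd = s)
}

#' Penalty configuration for stability selection
#'
#' @param alpha elastic-net mixing parameter in `[0, 1]`; `alpha = 1` is the
#'   LASSO.
#' @param lambda_grid descending positive penalty grid; by default 30
#'   log-spaced values from `lambda_max` (smallest penalty setting every
#'   coefficient to zero) down to `lambda_max / 100`.
#' @param lambda_rule `"cv_min"` (5-fold cross-validated MSE minimizer over
#'   the grid, chosen once on the full data) or `"fixed"` (use `lambda`).
#' @param lambda fixed penalty when `lambda_rule = "fixed"`.
#' @param resample `"bootstrap"` (n-out-of-n with replacement) or
#'   `"subsample"` (floor(n/2) without replacement).
#' @param lambda_per_fit when `TRUE`, a marker counts as selected in a
#'   resample if its coefficient is nonzero anywhere on the lambda grid
#'   (max-over-grid variant) instead of at the single chosen lambda.
#' @return A `penalty_config` list.
#' @export
penalty_config <- function(alpha = 1, lambda_grid = NULL,
                           lambda_rule = c("cv_min", "fixed"), lambda = NULL,
                           resample = c("bootstrap", "subsample"),
                           lambda_per_fit = FALSE) {
  lambda_rule <- match.arg(lambda_rule)
  resample <- match.arg(resample)
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  if (!is.null(lambda_grid)) {
    if (any(lambda_grid <= 0) || is.unsorted(rev(lambda_grid), strictly = TRUE)) {
      abort("lambda_grid must be strictly descending and positive")
    }
  }
  if (lambda_rule == "fixed" && is.null(lambda)) {
    abort("lambda_rule 'fixed' needs lambda")
  }
  structure(list(alpha = alpha, lambda_grid = lambda_grid,
                 lambda_rule = lambda_rule, lambda = lambda,
                 resample = resample, lambda_per_fit = lambda_per_fit),
            class = "penalty_config")
}

#' Elastic-net fit with the penalty as printed
#'
#' Minimizes `(1/2n) ||y - X b||^2 + lambda*alpha*||b||_1 +
#' lambda*(1-alpha)*||b||_2^2` by cyclic coordinate descent (convergence
#' when the largest coefficient change is below `tol`). Note the quadratic
#' term carries no factor 1/2, unlike the common library convention; with
#' `alpha = 1` the two conventions coincide (LASSO).
#'
#' @param X predictor matrix. With `standardize = TRUE` (default) columns
#'   are centred and scaled to unit population variance (zero-variance
#'   columns dropped with a message) and `y` is centred; with
#'   `standardize = FALSE` the caller guarantees that contract.
#' @param y response vector.
#' @param lambda penalty, `>= 0`.
#' @param alpha mixing parameter in `[0, 1]`.
#' @param standardize standardize internally?
#' @param tol,max_iter coordinate-descent controls.
#' @return Named coefficient vector on the standardized scale, one entry per
#'   input column (zero for dropped columns).
#' @export
elastic_net_fit <- function(X, y, lambda, alpha = 1, standardize = TRUE,
                            tol = 1e-7, max_iter = 100000L) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) abort("non-finite inputs")
  if (lambda < 0) abort("lambda must be >= 0")
  cn <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  if (standardize) {
    st <- standardize_cols(X)
    beta <- numeric(ncol(X))
    beta[st$keep] <- enet_cd(st$X, y - mean(y), lambda, alpha, tol,
                             as.integer(max_iter))
    names(beta) <- cn
    return(beta)
  }
  beta <- enet_cd(X, y, lambda, alpha, tol, as.integer(max_iter))
  names(beta) <- cn
  beta
}

default_lambda_grid <- function(X, y, length_out = 30, min_ratio = 0.01) {
  lambda_max <- max(abs(crossprod(X, y))) / length(y)
  if (lambda_max <= 0) lambda_max <- 1e-3
  exp(seq(log(lambda_max), log(lambda_max * min_ratio), length.out = length_out))
}

cv_min_lambda <- function(X, y, grid, alpha, n_folds = 5) {
  n <- length(y)
  folds <- rep(seq_len(n_folds), length.out = n)[sample.int(n)]
  mse <- matrix(NA_real_, n_folds, length(grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    st <- standardize_cols(X[tr, , drop = FALSE], quiet = TRUE)
    mu_y <- mean(y[tr])
    max_nnz <- floor(0.9 * sum(tr))
    path <- enet_path(st$X, y[tr] - mu_y, grid, alpha, 1e-7, 100000L, max_nnz)
    Xte <- sweep(X[!tr, st$keep, drop = FALSE], 2, st$mu[st$keep])
    Xte <- sweep(Xte, 2, st$sd[st$keep], "/")
    pred <- Xte %*% path + mu_y
    mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  grid[which.min(colMeans(mse))]
}

# Choose the penalty by the configured rule; callers run this under their
# own seeded RNG stream.
resolve_lambda <- function(X, y, config) {
  st <- standardize_cols(X)
  grid <- config$lambda_grid %||% default_lambda_grid(st$X, y - mean(y))
  lambda <- switch(config$lambda_rule,
    cv_min = cv_min_lambda(X, y, grid, config$alpha),
    fixed = config$lambda
  )
  list(lambda = lambda, grid = grid)
}

resolve_xy <- function(X, y) {
  map <- NULL
  if (inherits(X, "genotype_matrix")) {
    map <- X$map
    geno <- impute_mean(X$geno)
    if (is.data.frame(y)) {
      idx <- match(rownames(X$geno), y$accession_id)
      if (anyNA(idx)) abort("phenotype missing for some accessions")
      y <- y$aspect_ratio[idx]
    }
    X <- geno
  }
  list(X = as.matrix(X), y = as.numeric(y), map = map)
}

#' Bootstrap selection probabilities under an elastic-net penalty
#'
#' The penalty `lambda` is chosen once on the full data by
#' `config$lambda_rule` and held fixed. Each of `B` resamples (bootstrap by
#' default) is restandardized and refit; a marker's selection probability is
#' the fraction of resamples in which its coefficient is nonzero, and
#' `q_avg` is the average number of nonzero coefficients per resample.
#' Resamples with zero phenotypic variance are redrawn (with a message).
#'
#' @param X predictor matrix (accessions x SNPs) or a [genotype_matrix()]
#'   (missing calls mean-imputed).
#' @param y numeric response, or a phenotype tibble when `X` is a
#'   [genotype_matrix()].
#' @param config a [penalty_config()].
#' @param B number of resamples.
#' @param seed integer seed.
#' @return A `selection_profile`: tibble-like object with per-SNP
#'   `selection_probability`, plus fields `B`, `q_avg`, `lambda`, `alpha`,
#'   `theta` and thresholds (unset until [theoretical_threshold()] /
#'   [empirical_threshold()] results are attached by the caller). Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @export
selection_probability <- function(X, y, config = penalty_config(), B = 100,
                                  seed = 1) {
  stopifnot(B >= 1)
  dat <- resolve_xy(X, y)
  X <- dat$X
  y <- dat$y
  n <- nrow(X)
  p <- ncol(X)
  with_seed(seed, {
    resolved <- resolve_lambda(X, y, config)
    lambda <- resolved$lambda
    grid <- resolved$grid
    m_re <- if (config$resample == "bootstrap") n else floor(n / 2)
    idx_mat <- matrix(0L, m_re, B)
    for (b in seq_len(B)) {
      repeat {
        idx <- if (config$resample == "bootstrap") {
          sample.int(n, m_re, replace = TRUE)
        } else {
          sample.int(n, m_re, replace = FALSE)
        }
        if (sd(y[idx]) > 0) break
        inform("resample with constant phenotype redrawn")
      }
      idx_mat[, b] <- idx
    }
    if (config$lambda_per_fit) {
      n_sel <- integer(p)
      q_sum <- 0
      for (b in seq_len(B)) {
        st <- standardize_cols(X[idx_mat[, b], , drop = FALSE], quiet = TRUE)
        yb <- y[idx_mat[, b]]
        path <- enet_path(st$X, yb - mean(yb), grid, config$alpha, 1e-7,
                          100000L, floor(0.9 * m_re))
        nz <- logical(p)
        nz[st$keep] <- rowSums(path != 0) > 0
        n_sel <- n_sel + nz
        q_sum <- q_sum + sum(nz)
      }
    } else {
      boot <- enet_boot(X, y, idx_mat, lambda, config$alpha, 1e-7, 100000L)
      n_sel <- boot$counts
      q_sum <- sum(boot$q)
    }
    snp_id <- if (!is.null(dat$map)) dat$map$snp_id else
      (colnames(X) %||% paste0("x", seq_len(p)))
    profile <- tibble(
      snp_id = snp_id,
      chrom = if (!is.null(dat$map)) dat$map$chrom else NA_character_,
      pos = if (!is.null(dat$map)) dat$map$pos else seq_len(p),
      selection_probability = n_sel / B
    )
    structure(
      list(profile = profile, B = B, q_avg = q_sum / B, lambda = lambda,
           alpha = config$alpha, p = p, theta = NA_real_,
           theoretical_threshold = NA_real_, empirical_threshold = NA_real_,
           seed = seed),
      class = "selection_profile"
    )
  })
}

#' @export
print.selection_profile <- function(x, ...) {
  cat(sprintf(
    "<selection_profile> %d SNPs, B = %d, q_avg = %.2f, lambda = %.4g, alpha = %g\n",
    x$p, x$B, x$q_avg, x$lambda, x$alpha))
  thr <- c(theoretical = x$theoretical_threshold, empirical = x$empirical_threshold)
  if (any(!is.na(thr))) {
    cat("  thresholds:", paste(sprintf("%s = %.3f", names(thr)[!is.na(thr)],
                                       thr[!is.na(thr)]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname selection_probability
#' @param x,object a `selection_profile`.
#' @param ... ignored.
#' @export
tidy.selection_profile <- function(x, ...) x$profile

#' @rdname selection_probability
#' @export
glance.selection_profile <- function(x, ...) {
  tibble(B = x$B, q_avg = x$q_avg, lambda = x$lambda, alpha = x$alpha,
         theta = x$theta, theoretical_threshold = x$theoretical_threshold,
         empirical_threshold = x$empirical_threshold)
}

#' @rdname selection_probability
#' @export
autoplot.selection_profile <- function(object, ...) {
  dat <- object$profile |>
    arrange(.data$chrom, .data$pos) |>
    mutate(order = row_number())
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$order, .data$selection_probability,
                                         colour = .data$chrom)) +
    ggplot2::geom_point(show.legend = FALSE, size = 0.7) +
    ggplot2::labs(x = "genome order", y = "selection probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  for (thr in c(object$theoretical_threshold, object$empirical_threshold)) {
    if (!is.na(thr)) p <- p + ggplot2::geom_hline(yintercept = thr, linetype = 2)
  }
  p
}

#' Theoretical selection-probability threshold
#'
#' `pi_theta = q_avg^2 / (2 * theta * p) + 1/2`, where `q_avg` is the
#' average number of markers selected per resample, `theta` the tolerated
#' expected number of false selections, and `p` the number of markers.
#' Values above 1 are returned as computed, with a warning.
#'
#' @param q_avg average selected count per resample, `>= 0`.
#' @param theta expected false discoveries, `> 0`.
#' @param p number of markers.
#' @return The threshold `pi_theta`.
#' @export
theoretical_threshold <- function(q_avg, theta = 1, p) {
  if (p < 1) abort("p must be >= 1")
  if (theta <= 0) abort("theta must be > 0")
  if (q_avg < 0) abort("q_avg must be >= 0")
  out <- q_avg^2 / (2 * theta * p) + 0.5
  if (out > 1) warn(sprintf("theoretical threshold %.3f exceeds 1", out))
  out
}

#' Permutation-based empirical selection-probability threshold
#'
#' The penalty is first resolved on the *observed* data by the configured
#' rule, exactly as [selection_probability()] would resolve it. Then, for
#' each of `B_perm` random permutations of the phenotype, the bootstrap
#' selection-probability procedure is rerun at that same fixed penalty and
#' the theta-th largest selection probability recorded; the threshold is
#' the mean of those order statistics across permutations. Holding the
#' penalty fixed is what makes the permutations a null distribution for
#' the profile actually being thresholded — re-tuning per permutation
#' would estimate the null of a different (usually sparser) procedure.
#'
#' @inheritParams selection_probability
#' @param theta rank of the order statistic (expected false discoveries),
#'   `<= p`.
#' @param B_perm number of phenotype permutations. The default of 20 keeps
#'   the procedure affordable; increase for a steadier threshold.
#' @param B_bootstrap resamples per permutation.
#' @param lambda penalty to hold fixed; pass the `lambda` field of the
#'   [selection_probability()] profile being thresholded. When `NULL` it
#'   is re-resolved from the observed data by the configured rule.
#' @return The threshold `pi_theta_star` with attributes `per_permutation`
#'   (the B_perm order statistics) and `lambda` (the fixed penalty).
#' @export
empirical_threshold <- function(X, y, config = penalty_config(), theta = 1,
                                B_perm = 20, B_bootstrap = 100, seed = 1,
                                lambda = NULL) {
  stopifnot(B_perm >= 1)
  dat <- resolve_xy(X, y)
  if (theta > ncol(dat$X)) abort("theta must be <= number of markers")
  with_seed(seed, {
    if (is.null(lambda)) lambda <- resolve_lambda(dat$X, dat$y, config)$lambda
    fixed_config <- config
    fixed_config$lambda_rule <- "fixed"
    fixed_config$lambda <- lambda
    sub_seeds <- sample.int(2^30, B_perm)
    perms <- replicate(B_perm, sample.int(length(dat$y)), simplify = FALSE)
    sp_theta <- vapply(seq_len(B_perm), function(b) {
      prof <- selection_probability(dat$X, dat$y[perms[[b]]], fixed_config,
                                    B = B_bootstrap, seed = sub_seeds[b])
      sort(prof$profile$selection_probability, decreasing = TRUE)[theta]
    }, 0)
    out <- mean(sp_theta)
    attr(out, "per_permutation") <- sp_theta
    attr(out, "lambda") <- lambda
    out
  })
}

#' Markers exceeding a selection-probability threshold
#'
#' @param profile a `selection_profile` from [selection_probability()]; to
#'   use the named thresholds, set `profile$theoretical_threshold` /
#'   `profile$empirical_threshold` first.
#' @param threshold `"theoretical"`, `"empirical"`, or a numeric value.
#'   Strict inequality: a marker is returned iff its selection probability
#'   is greater than the threshold.
#' @return The profile rows above the threshold, sorted by descending
#'   selection probability, ties broken by genome order.
#' @export
select_markers <- function(profile, threshold = "theoretical") {
  thr <- if (is.numeric(threshold)) {
    threshold
  } else {
    val <- switch(threshold,
      theoretical = profile$theoretical_threshold,
      empirical = profile$empirical_threshold,
      abort("threshold must be 'theoretical', 'empirical' or numeric")
    )
    if (is.na(val)) abort(paste0(threshold, " threshold has not been set"))
    val
  }
  profile$profile |>
    arrange(.data$chrom, .data$pos) |>
    mutate(.genome_order = row_number()) |>
    filter(.data$selection_probability > thr) |>
    arrange(dplyr::desc(.data$selection_probability), .data$.genome_order) |>
    select(-".genome_order")
}
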