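#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for a pair of unphased biallelic
#' genotype vectors (dosage codes 0/1/2, `NA` missing). Only the
#' double-heterozygote phase is ambiguous; the EM is initialized at linkage
#' equilibrium and iterated until the largest frequency change is below
#' 1e-8 or 100 iterations. Pairwise-complete accessions only.
#'
#' @param g_a,g_b genotype code vectors of equal length.
#' @return Named numeric vector `c(AB, Ab, aB, ab)` where `A`/`B` are the
#'   coded (counted) alleles; attributes `n` (accessions used) and
#'   `loglik_trace`.
#' @export
two_locus_em <- function(g_a, g_b) {
  stopifnot(length(g_a) == length(g_b))
  ok <- !is.na(g_a) & !is.na(g_b)
  if (sum(ok) < 2) abort("fewer than 2 shared non-missing accessions")
  ga <- g_a[ok]
  gb <- g_b[ok]
  # genotype-pair counts, cell = 3*ga + gb + 1
  cnt <- tabulate(3 * ga + gb + 1, nbins = 9)
  n <- sum(cnt)
  n00 <- cnt[1]; n01 <- cnt[2]; n02 <- cnt[3]
  n10 <- cnt[4]; n11 <- cnt[5]; n12 <- cnt[6]
  n20 <- cnt[7]; n21 <- cnt[8]; n22 <- cnt[9]
  pA <- mean(ga) / 2
  pB <- mean(gb) / 2
  fAB <- pA * pB
  fAb <- pA * (1 - pB)
  faB <- (1 - pA) * pB
  fab <- (1 - pA) * (1 - pB)
  two_n <- 2 * n
  ll <- numeric(0)
  loglik <- function(fAB, fAb, faB, fab) {
    probs <- c(
      fab^2, 2 * fab * faB, faB^2,
      2 * fab * fAb, 2 * (fAB * fab + fAb * faB),
      2 * faB * fAB, fAb^2, 2 * fAb * fAB, fAB^2
    )
    sum(cnt[cnt > 0] * log(pmax(probs[cnt > 0], 1e-300)))
  }
  for (it in seq_len(100)) {
    denom <- fAB * fab + fAb * faB
    q <- if (denom > 0) fAB * fab / denom else 0.5
    nAB <- (2 * n22 + n21 + n12 + q * n11) / two_n
    nAb <- (2 * n20 + n21 + n10 + (1 - q) * n11) / two_n
    naB <- (2 * n02 + n01 + n12 + (1 - q) * n11) / two_n
    nab <- (2 * n00 + n01 + n10 + q * n11) / two_n
    ll <- c(ll, loglik(nAB, nAb, naB, nab))
    delta <- max(abs(c(nAB - fAB, nAb - fAb, naB - faB, nab - fab)))
    fAB <- nAB; fAb <- nAb; faB <- naB; fab <- nab
    if (delta < 1e-8) break
  }
  f <- c(AB = fAB, Ab = fAb, aB = faB, ab = fab)
  attr(f, "n") <- n
  attr(f, "loglik_trace") <- ll
  f
}

#' Disequilibrium statistics from haplotype frequencies
#'
#' `D = f(AB) - f(A) f(B)`; `D' = |D| / Dmax` with
#' `Dmax = min(f(A) f(b), f(a) f(B))` when `D > 0` and
#' `min(f(A) f(B), f(a) f(b))` otherwise; `r2 = D^2 / (f(A) f(a) f(B) f(b))`.
#' When either locus is monomorphic, `d_prime` and `r2` are `NA`.
#'
#' @param hap_freqs numeric vector `(AB, Ab, aB, ab)` summing to 1.
#' @return A tibble with columns `D`, `d_prime`, `r2`, `p_A`, `p_B`.
#' @export
ld_statistics <- function(hap_freqs) {
  f <- as.numeric(hap_freqs)
  if (length(f) != 4 || any(f < -1e-8)) abort("need 4 non-negative frequencies")
  if (abs(sum(f) - 1) > 1e-8) abort("haplotype frequencies must sum to 1")
  pA <- f[1] + f[2]
  pB <- f[1] + f[3]
  D <- f[1] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom <= 0) {
    return(tibble(D = D, d_prime = NA_real_, r2 = NA_real_, p_A = pA, p_B = pB))
  }
  d_max <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
           else min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (d_max > 0) abs(D) / d_max else 0
  tibble(D = D, d_prime = min(d_prime, 1), r2 = min(D^2 / denom, 1),
         p_A = pA, p_B = pB)
}

#' Pairwise linkage disequilibrium
#'
#' Computes D, D' and r-squared (via [two_locus_em()]) for SNP pairs. Only
#' intra-chromosomal pairs of markers with MAF strictly above `maf_min` are
#' considered.
#'
#' @param G a [genotype_matrix()] with a map sorted by (chrom, pos).
#' @param scope `"chromosome"` for all intra-chromosomal pairs (optionally a
#'   single chromosome via `chrom`), or `"window"` for pairs formed by an
#'   index SNP and its neighbours within `window_bp`.
#' @param chrom restrict to this chromosome (scope `"chromosome"`).
#' @param index_snp snp_id of the index marker (scope `"window"`).
#' @param window_bp half-width of the window around the index SNP.
#' @param maf_min minimum (exclusive) minor allele frequency.
#' @param max_bp drop pairs further apart than this (decay estimation is
#'   usually capped, e.g. at a few times the expected decay scale).
#' @param max_pairs when more pairs qualify, a random subsample of this size
#'   is used (seeded); `Inf` disables subsampling.
#' @param seed seed for the pair subsample.
#' @return A tibble: `snp_a`, `snp_b`, `chrom`, `distance`, `D`, `d_prime`,
#'   `r2`.
#' @export
pairwise_ld <- function(G, scope = c("chromosome", "window"), chrom = NULL,
                        index_snp = NULL, window_bp = NULL, maf_min = 0.01,
                        max_bp = Inf, max_pairs = Inf, seed = 1) {
  scope <- match.arg(scope)
  st <- snp_stats(G)
  usable <- st$maf > maf_min
  map <- G$map
  if (scope == "chromosome") {
    chroms <- if (is.null(chrom)) unique(map$chrom) else chrom
    idx <- which(usable & map$chrom %in% chroms)
    pairs <- purrr::map_dfr(split(idx, map$chrom[idx]), function(ii) {
      if (length(ii) < 2) return(NULL)
      cmb <- utils::combn(ii, 2)
      tibble(i = cmb[1, ], j = cmb[2, ])
    })
  } else {
    if (is.null(index_snp) || is.null(window_bp)) {
      abort("scope 'window' needs index_snp and window_bp")
    }
    k <- match(index_snp, map$snp_id)
    if (is.na(k)) abort(paste0("index SNP not found: ", index_snp))
    neigh <- which(usable & map$chrom == map$chrom[k] &
                     abs(map$pos - map$pos[k]) <= window_bp &
                     seq_len(nrow(map)) != k)
    pairs <- tibble(i = rep(k, length(neigh)), j = neigh)
  }
  if (nrow(pairs) && is.finite(max_bp)) {
    pairs <- filter(pairs, abs(map$pos[.data$i] - map$pos[.data$j]) <= max_bp)
  }
  if (!nrow(pairs)) {
    return(tibble(snp_a = character(), snp_b = character(), chrom = character(),
                  distance = integer(), D = numeric(), d_prime = numeric(),
                  r2 = numeric()))
  }
  if (nrow(pairs) > max_pairs) {
    pairs <- with_seed(seed, pairs[sample.int(nrow(pairs), max_pairs), ])
  }
  stats <- purrr::map2_dfr(pairs$i, pairs$j, function(i, j) {
    ld_statistics(two_locus_em(G$geno[, i], G$geno[, j]))
  })
  tibble(
    snp_a = map$snp_id[pairs$i], snp_b = map$snp_id[pairs$j],
    chrom = map$chrom[pairs$i],
    distance = abs(map$pos[pairs$i] - map$pos[pairs$j])
  ) |>
    dplyr::bind_cols(stats[, c("D", "d_prime", "r2")])
}

hill_weir_r2 <- function(d, rho, n) {
  C <- rho * d
  (10 + C) / ((2 + C) * (11 + C)) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit an LD decay curve
#'
#' For `statistic = "r2"` fits the Hill-Weir drift expectation of r-squared
#' as a function of distance (parameter `rho` per bp, sample size `n`
#' chromosomes) by nonlinear least squares. For `statistic = "d_prime"` fits
#' a monotone exponential with floor, `a * exp(-d / b) + c`. The decay
#' distance is the smallest distance at which the fitted curve equals
#' `cutoff` (bisection to 1 bp), `Inf` when the curve never crosses and `0`
#' when it starts below.
#'
#' @param pairs tibble from [pairwise_ld()] (`distance` plus the statistic
#'   column).
#' @param statistic `"r2"` or `"d_prime"`.
#' @param cutoff decay cutoff on the statistic scale.
#' @param n number of sampled chromosomes (2 x accessions) for the
#'   Hill-Weir finite-sample term.
#' @return An `ld_decay_fit`: `statistic`, `params`, `decay_distance_bp`,
#'   `n_pairs`, `curve` (the fitted function). Methods: [tidy()],
#'   [glance()], [autoplot()], `predict()`.
#' @export
decay_fit <- function(pairs, statistic = c("r2", "d_prime"), cutoff = 0.1,
                      n = 100) {
  statistic <- match.arg(statistic)
  col <- if (statistic == "r2") "r2" else "d_prime"
  dat <- tibble(d = as.numeric(pairs$distance), s = pairs[[col]]) |>
    filter(!is.na(.data$s))
  if (nrow(dat) < 4) abort("too few pairs to fit a decay curve")
  if (nrow(dat) < 50 || diff(range(log10(pmax(dat$d, 1)))) < 1) {
    warn("decay fit on few pairs or a narrow distance range; interpret with care")
  }
  if (sd(dat$s) < 1e-10) {
    lev <- mean(dat$s)
    curve <- function(d) rep(lev, length(d))
    params <- c(a = 0, b = Inf, c = lev)
  } else if (statistic == "r2") {
    sse <- function(log_rho) {
      sum((dat$s - hill_weir_r2(dat$d, 10^log_rho, n))^2)
    }
    opt <- optimize(sse, c(-12, 0))
    rho <- 10^opt$minimum
    params <- c(rho = rho, n = n)
    curve <- function(d) hill_weir_r2(d, rho, n)
  } else {
    start <- list(a = max(dat$s) - min(dat$s), b = median(dat$d) + 1,
                  c = min(dat$s))
    fit <- tryCatch(
      minpack.lm::nlsLM(s ~ a * exp(-d / b) + c, data = dat, start = start,
                        lower = c(a = 0, b = 1, c = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        abort(paste0("decay fit did not converge: ", conditionMessage(e),
                     "; residual sd of data = ", signif(sd(dat$s), 4)))
      }
    )
    params <- coef(fit)
    curve <- function(d) params[["a"]] * exp(-d / params[["b"]]) + params[["c"]]
  }
  dd <- decay_crossing(curve, cutoff, max(dat$d))
  structure(
    list(statistic = statistic, params = params, cutoff = cutoff,
         decay_distance_bp = dd, n_pairs = nrow(dat), curve = curve,
         data_range = range(dat$d)),
    class = "ld_decay_fit"
  )
}

decay_crossing <- function(curve, cutoff, d_max) {
  if (curve(0) <= cutoff) return(0)
  hi <- d_max
  for (k in 1:30) {
    if (curve(hi) < cutoff) break
    hi <- hi * 2
    if (k == 30) return(Inf)
  }
  lo <- 0
  while (hi - lo > 1) {
    mid <- (lo + hi) / 2
    if (curve(mid) >= cutoff) lo <- mid else hi <- mid
  }
  round((lo + hi) / 2)
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("<ld_decay_fit> %s over %d pairs; decay to %.2g at %s bp\n",
              x$statistic, x$n_pairs, x$cutoff,
              if (is.finite(x$decay_distance_bp))
                format(x$decay_distance_bp, big.mark = ",") else "Inf"))
  invisible(x)
}

#' @rdname decay_fit
#' @param x,object an `ld_decay_fit`.
#' @param ... ignored.
#' @export
tidy.ld_decay_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = as.numeric(x$params))
}

#' @rdname decay_fit
#' @export
glance.ld_decay_fit <- function(x, ...) {
  tibble(statistic = x$statistic, cutoff = x$cutoff,
         decay_distance_bp = x$decay_distance_bp, n_pairs = x$n_pairs)
}

#' @export
predict.ld_decay_fit <- function(object, distance, ...) {
  object$curve(distance)
}

#' @rdname decay_fit
#' @param pairs_data optionally the pair table, to show the scatter under
#'   the curve.
#' @export
autoplot.ld_decay_fit <- function(object, pairs_data = NULL, ...) {
  grid <- tibble(
    distance = seq(0, object$data_range[2], length.out = 400),
    fitted = object$curve(seq(0, object$data_range[2], length.out = 400))
  )
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$distance, .data$fitted))
  if (!is.null(pairs_data)) {
    col <- if (object$statistic == "r2") "r2" else "d_prime"
    pts <- tibble(distance = as.numeric(pairs_data$distance),
                  value = pairs_data[[col]])
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(.data$distance, .data$value),
      alpha = 0.2, size = 0.5
    )
  }
  p + ggplot2::geom_line(colour = "blue") +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = 2) +
    ggplot2::labs(x = "distance (bp)", y = object$statistic) +
    ggplot2::theme_minimal()
}

#' Strong-LD window around an index SNP
#'
#' Extends left and right from the index marker, including each next marker
#' while its pairwise D' with the index is at least `d_prime_min`; the first
#' failure on a side stops that side. An undefined D' (monomorphic
#' neighbour) counts as a failure.
#'
#' @param G a [genotype_matrix()].
#' @param index_snp snp_id of the index marker (must be polymorphic).
#' @param d_prime_min inclusion threshold on D'.
#' @return A tibble: `chrom`, `start`, `end`, `n_snps`, `index_snp`;
#'   degenerate (`start == end == index position`) when both immediate
#'   neighbours fail.
#' @export
strong_ld_window <- function(G, index_snp, d_prime_min = 0.80) {
  k <- match(index_snp, G$map$snp_id)
  if (is.na(k)) abort(paste0("index SNP not found: ", index_snp))
  g0 <- G$geno[, k]
  if (sd(g0, na.rm = TRUE) == 0 || all(is.na(g0))) {
    abort("index SNP is monomorphic")
  }
  on_chrom <- which(G$map$chrom == G$map$chrom[k])
  pos_in <- match(k, on_chrom)
  dp_with_index <- function(j) {
    s <- ld_statistics(two_locus_em(g0, G$geno[, j]))
    s$d_prime
  }
  included <- k
  for (step in c(-1, 1)) {
    i <- pos_in + step
    while (i >= 1 && i <= length(on_chrom)) {
      j <- on_chrom[i]
      dp <- tryCatch(dp_with_index(j), error = function(e) NA_real_)
      if (is.na(dp) || dp < d_prime_min) break
      included <- c(included, j)
      i <- i + step
    }
  }
  tibble(
    chrom = G$map$chrom[k],
    start = min(G$map$pos[included]),
    end = max(G$map$pos[included]),
    n_snps = length(included),
    index_snp = index_snp
  )
}

#' Genes overlapping a candidate interval
#'
#' Selects genes whose `[start, end]` overlaps the query interval with
#' inclusive coordinates (a gene ending exactly at the interval start is
#' included). The interval is given directly or as a centre position with a
#' symmetric flank.
#'
#' @param genes tibble from [read_gff()].
#' @param chrom chromosome of the interval.
#' @param start,end interval bounds (1-based inclusive), or
#' @param center,flank_bp centre position and half-width (default 150 kb).
#' @return The overlapping rows of `genes`, sorted by start.
#' @export
candidate_genes <- function(genes, chrom, start = NULL, end = NULL,
                            center = NULL, flank_bp = 150000) {
  if (is.null(start) || is.null(end)) {
    if (is.null(center)) abort("give start/end or center")
    start <- center - flank_bp
    end <- center + flank_bp
  }
  genes |>
    filter(.data$chrom == !!chrom, .data$end >= !!start, .data$start <= !!end) |>
    arrange(.data$start)
}
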