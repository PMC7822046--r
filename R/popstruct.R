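#' Allele-sharing genetic distance
#'
#' `d(i, j)` is the mean over SNPs non-missing in both accessions of
#' `|code_i - code_j| / 2`, which lies in `[0, 1]`: 0 for identical
#' genotypes, 1 for opposite homozygotes at every shared locus. Missing data
#' are handled pairwise (per-pair SNP intersection), not by imputation.
#'
#' @param G a [genotype_matrix()].
#' @return A symmetric n-by-n distance matrix with zero diagonal, accession
#'   ids as dimnames.
#' @export
genetic_distance <- function(G) {
  geno <- G$geno
  n <- nrow(geno)
  if (n < 2) abort("need at least 2 accessions")
  M <- (!is.na(geno)) + 0
  A0 <- (!is.na(geno) & geno == 0) + 0
  A1 <- (!is.na(geno) & geno == 1) + 0
  A2 <- (!is.na(geno) & geno == 2) + 0
  n_shared <- tcrossprod(M)
  if (any(n_shared[upper.tri(n_shared)] == 0)) {
    idx <- which(n_shared == 0 & upper.tri(n_shared), arr.ind = TRUE)[1, ]
    abort(sprintf("accessions %s and %s share no non-missing SNPs",
                  rownames(geno)[idx[1]], rownames(geno)[idx[2]]))
  }
  # |a - b| is 1 for (0,1) and (1,2) pairs, 2 for (0,2) pairs
  sum_abs <- tcrossprod(A0, A1) + tcrossprod(A1, A0) +
    tcrossprod(A1, A2) + tcrossprod(A2, A1) +
    2 * (tcrossprod(A0, A2) + tcrossprod(A2, A0))
  D <- sum_abs / (2 * n_shared)
  diag(D) <- 0
  dimnames(D) <- list(rownames(geno), rownames(geno))
  D
}

#' Principal coordinate analysis
#'
#' Classical metric MDS: Gower double-centering of `-D^2 / 2`, then an
#' eigendecomposition. Axes with non-positive eigenvalues carry no
#' representable variance and are dropped; per-axis variance fractions are
#' relative to the positive eigenvalue mass.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param n_axes number of axes to return (truncated with a warning if it
#'   exceeds the positive-eigenvalue count).
#' @return A `pcoa_result`: list with `coordinates` (n x axes matrix),
#'   `eigenvalues` (all, sorted descending), `variance_fraction` (per kept
#'   axis). Methods: [tidy()], [glance()], [autoplot()].
#' @export
pcoa <- function(D, n_axes = 2) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) abort("D must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) abort("D must have zero diagonal")
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  n_pos <- sum(pos)
  if (n_pos == 0) {
    coords <- matrix(0, n, 0)
    vf <- numeric(0)
  } else {
    if (n_axes > n_pos) {
      warn(sprintf("only %d positive-eigenvalue axes available; truncating", n_pos))
      n_axes <- n_pos
    }
    keep <- seq_len(n_axes)
    coords <- e$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(e$values[keep]), n_axes, n_axes)
    vf <- e$values[keep] / sum(e$values[pos])
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- if (ncol(coords)) paste0("axis", seq_len(ncol(coords)))
  structure(
    list(coordinates = coords, eigenvalues = e$values, variance_fraction = vf,
         n_positive = n_pos),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d accessions, %d axes kept of %d positive\n",
              nrow(x$coordinates), ncol(x$coordinates), x$n_positive))
  if (length(x$variance_fraction)) {
    cat("  variance: ",
        paste(sprintf("%.2f%%", 100 * x$variance_fraction), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname pcoa
#' @param x a `pcoa_result`.
#' @param ... ignored.
#' @export
tidy.pcoa_result <- function(x, ...) {
  as_tibble(x$coordinates) |>
    mutate(accession_id = rownames(x$coordinates) %||%
             sprintf("acc%03d", row_number()), .before = 1)
}

#' @rdname pcoa
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble(
    n_axes = ncol(x$coordinates),
    n_positive = x$n_positive,
    var_axis1 = if (length(x$variance_fraction) >= 1) x$variance_fraction[1] else NA_real_,
    var_axis2 = if (length(x$variance_fraction) >= 2) x$variance_fraction[2] else NA_real_
  )
}

#' @rdname pcoa
#' @param object a `pcoa_result`.
#' @param colour optional vector (e.g. subpopulation) to colour points by.
#' @export
autoplot.pcoa_result <- function(object, colour = NULL, ...) {
  dat <- tidy(object)
  if (ncol(object$coordinates) < 2) abort("need at least 2 axes to plot")
  if (!is.null(colour)) dat$colour <- factor(colour)
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$axis1, .data$axis2)) +
    ggplot2::labs(
      x = sprintf("Axis 1 (%.1f%%)", 100 * object$variance_fraction[1]),
      y = sprintf("Axis 2 (%.1f%%)", 100 * object$variance_fraction[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour), alpha = 0.7) +
      ggplot2::labs(colour = "group")
  }
}
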