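otsu_threshold <- function(x, n_bins = 256) {
  # maximize between-class variance over histogram thresholds
  h <- hist(x, breaks = seq(min(x), max(x), length.out = n_bins + 1), plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

label_components <- function(mask) {
  # 8-connected labelling via the pixel adjacency graph
  n <- sum(mask)
  if (n == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  idx <- matrix(0L, nrow(mask), ncol(mask))
  idx[mask] <- seq_len(n)
  nr <- nrow(mask)
  nc <- ncol(mask)
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  k <- 1L
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1L - dc, nc)
    a <- idx[r1, c1, drop = FALSE]
    b <- idx[r1 + dr, c1 + dc, drop = FALSE]
    both <- a > 0L & b > 0L
    if (any(both)) {
      edges[[k]] <- rbind(a[both], b[both])
      k <- k + 1L
    }
  }
  memb <- if (length(edges)) {
    gr <- igraph::graph_from_edgelist(t(do.call(cbind, edges)), directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, n - igraph::vcount(gr)))
    igraph::components(gr)$membership
  } else {
    seq_len(n)
  }
  lab <- matrix(0L, nr, nc)
  lab[mask] <- memb[idx[mask]]
  lab
}

#' Measure seeds in a binary image
#'
#' Labels 8-connected foreground components, drops small or border-touching
#' ones, and measures each survivor by its equivalent ellipse: the ellipse
#' with the same second central moments as the pixel set. For a uniform
#' ellipse the eigenvalues of the covariance of pixel coordinates are
#' `a^2/4` and `b^2/4`, so semi-axes are `2*sqrt(eigenvalue)` and the aspect
#' ratio is `sqrt(lambda_1 / lambda_2)`.
#'
#' @param image logical or 0/1 matrix (foreground = seed). A numeric
#'   grayscale matrix in `[0, 1]` is accepted and binarized by Otsu's
#'   threshold, with a message.
#' @param min_area minimum component area in pixels.
#' @param exclude_border drop components touching the image border?
#' @return A tibble with one row per seed: `label`, `area`, `major_axis`,
#'   `minor_axis`, `aspect_ratio`, `centroid_x`, `centroid_y`. Zero rows when
#'   nothing survives the filters.
#' @export
measure_seeds <- function(image, min_area = 10, exclude_border = TRUE) {
  if (!is.matrix(image)) abort("image must be a matrix")
  if (is.logical(image)) {
    mask <- image
  } else {
    vals <- unique(as.vector(image))
    if (all(vals %in% c(0, 1))) {
      mask <- image == 1
    } else {
      inform("grayscale input binarized by Otsu threshold")
      mask <- image > otsu_threshold(image)
    }
  }
  lab <- label_components(mask)
  out <- tibble(label = integer(), area = integer(), major_axis = numeric(),
                minor_axis = numeric(), aspect_ratio = numeric(),
                centroid_x = numeric(), centroid_y = numeric())
  if (!any(lab > 0)) return(out)
  coords <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  rows <- vector("list", max(labs))
  for (l in seq_len(max(labs))) {
    pix <- coords[labs == l, , drop = FALSE]
    if (nrow(pix) < min_area) next
    if (exclude_border &&
        (any(pix[, 1] %in% c(1L, nrow(mask))) || any(pix[, 2] %in% c(1L, ncol(mask))))) {
      next
    }
    y <- pix[, 1]; x <- pix[, 2]
    mx <- mean(x); my <- mean(y)
    n <- nrow(pix)
    cxx <- sum((x - mx)^2) / n
    cyy <- sum((y - my)^2) / n
    cxy <- sum((x - mx) * (y - my)) / n
    ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)$values
    ev <- pmax(ev, 1e-12)
    a <- 2 * sqrt(ev[1])
    b <- 2 * sqrt(ev[2])
    rows[[l]] <- tibble(label = l, area = n, major_axis = 2 * a,
                        minor_axis = 2 * b, aspect_ratio = a / b,
                        centroid_x = mx, centroid_y = my)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows)) dplyr::bind_rows(rows) else out
}

#' Mean aspect ratio of an accession's seeds
#'
#' Arithmetic mean of per-seed ratios; warns when the seed count differs
#' from the customary ten seeds per scan.
#'
#' @param measurements tibble from [measure_seeds()], or a numeric vector of
#'   ratios.
#' @return The mean aspect ratio (scalar).
#' @export
accession_aspect_ratio <- function(measurements) {
  ratios <- if (is.data.frame(measurements)) measurements$aspect_ratio else measurements
  if (!length(ratios)) abort("no seed measurements; cannot average")
  if (length(ratios) != 10) {
    warn(sprintf("averaging %d seed(s); 10 per accession is customary", length(ratios)))
  }
  mean(ratios)
}

#' Normality check for a phenotype
#'
#' Quantile-quantile pairs against the standard normal at plotting positions
#' `(i - 0.5)/n`, plus a Shapiro-Wilk test. The verdict is `"normal"` iff
#' the Shapiro-Wilk p-value is at least 0.05.
#'
#' @param values numeric vector, length `>= 3`, non-constant.
#' @return A list with `qq` (tibble `theoretical`, `sample`), `shapiro_p`,
#'   and `verdict` (`"normal"` / `"non-normal"`).
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) abort("need at least 3 values")
  if (sd(values) == 0) abort("constant input; normality test undefined")
  s <- sort(values)
  n <- length(s)
  qq <- tibble(theoretical = qnorm((seq_len(n) - 0.5) / n), sample = s)
  # shapiro.test caps at n = 5000; subsample deterministically beyond that
  sv <- if (n > 5000) s[round(seq(1, n, length.out = 5000))] else s
  p <- shapiro.test(sv)$p.value
  list(qq = qq, shapiro_p = p,
       verdict = if (p >= 0.05) "normal" else "non-normal")
}
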