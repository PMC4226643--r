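# Texture descriptors: first-order statistics on the gray-level histogram
# of the masked region, and second-order statistics on a single-offset
# gray-level co-occurrence matrix (GLCM).

#' First-order histogram statistics of the masked region
#'
#' Builds the gray-level histogram of the region of interest (each count
#' divided by the region area, so it is a probability distribution), and
#' returns the histogram together with its mean \eqn{\mu = \sum_x x\,h(x)}
#' and variance \eqn{\delta^2 = \sum_x (x-\mu)^2 h(x)}. Intensities are
#' rounded to integer gray levels 0--255 for the histogram.
#'
#' @param gray Grayscale matrix on 0--255.
#' @param mask Binary mask, same shape.
#' @return List with `h` (named probability vector over the observed
#'   levels), `mu`, `var`.
#' @export
first_order_stats <- function(gray, mask) {
  stopifnot(is.matrix(gray), identical(dim(gray), dim(mask)))
  if (sum(mask) == 0) stop("empty mask")
  v <- round(gray[mask == 1L])
  tab <- table(v)
  h <- as.numeric(tab) / length(v)
  names(h) <- names(tab)
  x <- as.numeric(names(tab))
  mu <- sum(x * h)
  va <- sum((x - mu)^2 * h)
  list(h = h, mu = mu, var = va)
}

#' Gray-level co-occurrence matrix at a fixed offset
#'
#' Intensities of the masked pixels are uniformly quantized to `levels`
#' bins over the masked min--max range (masked minimum maps to bin 0, the
#' maximum to bin `levels - 1`), then ordered pixel pairs are counted at
#' the given offset -- by default (+1, +1), the down-right diagonal, i.e.
#' the direction at \eqn{\theta = -45^\circ} with distance one pixel --
#' with both pixels required to lie in the mask. Counts are normalized to
#' probabilities; the matrix is NOT symmetrized.
#'
#' @param gray Grayscale matrix.
#' @param mask Binary mask, same shape.
#' @param levels Number of gray bins (>= 2); default 16.
#' @param offset Integer `c(drow, dcol)` pixel offset; default `c(1, 1)`.
#' @return Object of class `glcm`: list with `P` (levels x levels
#'   probability matrix), `levels`, `offset`.
#' @export
compute_glcm <- function(gray, mask, levels = 16L, offset = c(1L, 1L)) {
  stopifnot(is.matrix(gray), identical(dim(gray), dim(mask)), levels >= 2)
  if (sum(mask) == 0) stop("empty mask")
  inmask <- mask == 1L
  mn <- min(gray[inmask]); mx <- max(gray[inmask])
  if (mx > mn) {
    q <- floor((gray - mn) / (mx - mn) * levels)
    q[q >= levels] <- levels - 1L
    q[q < 0L] <- 0L
  } else {
    q <- matrix(0L, nrow(gray), ncol(gray))
  }
  nr <- nrow(gray); nc <- ncol(gray)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(r1) == 0 || length(c1) == 0)
    stop("degenerate co-occurrence: no valid pixel pair at this offset")
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- inmask[r1, c1, drop = FALSE] & inmask[r1 + dr, c1 + dc, drop = FALSE]
  if (!any(ok))
    stop("degenerate co-occurrence: no valid pixel pair at this offset")
  code <- a[ok] * levels + b[ok]  # 0-based (row-level, col-level)
  cnt <- tabulate(code + 1L, nbins = levels * levels)
  P <- matrix(cnt / sum(cnt), levels, levels, byrow = TRUE)
  structure(list(P = P, levels = as.integer(levels),
                 offset = as.integer(offset)),
            class = "glcm")
}

#' Second-order texture features of a co-occurrence matrix
#'
#' Uniformity \eqn{\sum P^2}; co-occurrence entropy
#' \eqn{-\sum P \log P} (natural log, with \eqn{0 \log 0 := 0});
#' homogeneity \eqn{\sum P/(1 + |x - y|)}; inertia
#' \eqn{\sum P (x - y)^2}, where \eqn{x, y} index the gray bins.
#'
#' @param glcm A `glcm` object or a plain probability matrix.
#' @param log_base Base of the entropy logarithm; default `exp(1)`.
#' @return Named list `uniformity, entropy, homogeneity, inertia`.
#' @export
glcm_features <- function(glcm, log_base = exp(1)) {
  P <- if (inherits(glcm, "glcm")) glcm$P else glcm
  L <- nrow(P)
  i <- row(P); j <- col(P)
  nz <- P > 0
  list(
    uniformity = sum(P^2),
    entropy = -sum(P[nz] * log(P[nz], base = log_base)),
    homogeneity = sum(P / (1 + abs(i - j))),
    inertia = sum(P * (i - j)^2)
  )
}

#' All six texture features of the masked region
#'
#' Convenience wrapper: first-order mean and variance plus the four
#' co-occurrence features, in the fixed feature order.
#'
#' @inheritParams compute_glcm
#' @return Named list `mu, var, uniformity, entropy, homogeneity, inertia`.
#' @export
texture_features <- function(gray, mask, levels = 16L, offset = c(1L, 1L)) {
  fo <- first_order_stats(gray, mask)
  gf <- glcm_features(compute_glcm(gray, mask, levels = levels,
                                   offset = offset))
  c(list(mu = fo$mu, var = fo$var), gf)
}
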