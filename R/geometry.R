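# Geometric region descriptors computed on the binary mask and its contour.
# Perimeter is a boundary-pixel COUNT (the number of pixels on the edge of
# the region), not an arc-length estimate; an optional sqrt(2)-weighted
# arc-length mode exists for comparison but is off by default.

# Count the pixels whose centers fall inside (or on) the convex hull of the
# foreground pixel centers. The hull is rasterized by exact scanline
# clipping of the convex polygon; boundary ties count as inside.
convex_hull_pixel_count <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) stop("empty mask")
  x <- idx[, 2] - 1  # column, 0-based
  y <- idx[, 1] - 1  # row, 0-based
  if (n <= 2L) return(n)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  k <- length(h)
  if (k <= 2L) {
    # collinear set: integer points on the extreme segment
    dx <- max(x) - min(x); dy <- max(y) - min(y)
    g <- if (dx == 0 && dy == 0) 0 else gcd_int(dx, dy)
    return(g + 1L)
  }
  eps <- 1e-9
  total <- 0L
  for (yy in ceiling(min(hy) - eps):floor(max(hy) + eps)) {
    xs <- numeric(0)
    for (i in seq_len(k)) {
      j <- if (i == k) 1L else i + 1L
      y1 <- hy[i]; y2 <- hy[j]
      if (abs(y1 - y2) < eps) {
        if (abs(yy - y1) < eps) xs <- c(xs, hx[i], hx[j])
      } else if (yy >= min(y1, y2) - eps && yy <= max(y1, y2) + eps) {
        t <- (yy - y1) / (y2 - y1)
        xs <- c(xs, hx[i] + t * (hx[j] - hx[i]))
      }
    }
    if (length(xs) == 0) next
    lo <- ceiling(min(xs) - 1e-7)
    hi <- floor(max(xs) + 1e-7)
    if (hi >= lo) total <- total + (hi - lo + 1L)
  }
  total
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' Geometric features of a segmented region
#'
#' The six region-shape descriptors: area \eqn{A} (foreground pixel count),
#' perimeter \eqn{P} (boundary pixel count), equivalent diameter
#' \eqn{D = \sqrt{4A/\pi}} (diameter of the circle with the same area),
#' compatibility \eqn{C = 4\pi A / P^2}, compactness \eqn{Co = P^2/(4\pi A)}
#' (exact reciprocals, both kept to preserve the 15-feature contract), and
#' solidity \eqn{S} = area / pixel count of the filled convex hull of the
#' foreground.
#'
#' @param mask Binary mask over {0, 1} with at least one foreground pixel.
#'   If it has several connected components the union is measured; set
#'   `largest_component = TRUE` to restrict to the biggest.
#' @param contour Optional precomputed contour (from [extract_contour()]);
#'   computed if missing.
#' @param largest_component Restrict to the largest 8-connected component.
#' @param arc_length_perimeter If TRUE, use a sqrt(2)-weighted arc-length
#'   perimeter estimate instead of the boundary-pixel count. Default FALSE.
#' @return Named list `A, P, D, C, Co, S`.
#' @export
compute_geometry <- function(mask, contour = NULL, largest_component = FALSE,
                             arc_length_perimeter = FALSE) {
  stopifnot(is.matrix(mask))
  if (sum(mask) == 0) stop("empty mask")
  if (largest_component) {
    lab <- label_components8(mask)
    if (lab$n > 1L) {
      keep <- which.max(tabulate(lab$labels[lab$labels > 0], lab$n))
      mask <- (lab$labels == keep) * 1L
      mode(mask) <- "integer"
      contour <- NULL
    }
  }
  if (is.null(contour)) contour <- extract_contour(mask)
  A <- sum(mask)
  if (arc_length_perimeter) {
    P <- perimeter_arc_length(contour)
  } else {
    P <- sum(contour)
  }
  D <- sqrt(4 * A / pi)
  C <- 4 * pi * A / P^2
  Co <- P^2 / (4 * pi * A)
  S <- A / convex_hull_pixel_count(mask)
  list(A = A, P = P, D = D, C = C, Co = Co, S = S)
}

# sqrt(2)-weighted chain length along the contour (optional mode): each
# contour pixel contributes 1, plus (sqrt(2)-1) when its only continuation
# is diagonal. Kept deliberately simple; the default count mode is the one
# the feature contract uses.
perimeter_arc_length <- function(contour) {
  idx <- which(contour == 1L, arr.ind = TRUE)
  if (nrow(idx) <= 1L) return(nrow(idx))
  nb <- shift8(contour)
  ortho <- nb[[1]] + nb[[3]] + nb[[5]] + nb[[7]]
  diag_only <- contour == 1L & ortho == 0L
  sum(contour) + (sqrt(2) - 1) * sum(diag_only)
}
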