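# Image moments of the segmented region: raw Cartesian moments m_pq,
# central moments u_pq (translation invariant), normalized central moments
# n_pq, the first Hu invariant, and two affine moment invariants (AMI).
# Coordinates: x = 0-based column, y = 0-based row; pixel area = 1.

#' Cartesian, central, and normalized central moments of a region
#'
#' Raw moments \eqn{m_{pq} = \sum x^p y^q I(x, y)} over the masked pixels
#' to order 3 (p + q <= 3), central moments
#' \eqn{u_{pq} = \sum (x-\bar x)^p (y-\bar y)^q I(x, y)} about the
#' centroid \eqn{\bar x = m_{10}/m_{00}}, \eqn{\bar y = m_{01}/m_{00}},
#' and normalized central moments \eqn{n_{pq} = u_{pq}/u_{00}^\gamma}.
#' By default the intensity is the binary mask itself (shape moments,
#' \eqn{I \in \{0, 1\}}); pass `gray` to weight by intensity.
#'
#' @param mask Binary mask over {0, 1}, at least one foreground pixel.
#' @param gray Optional grayscale matrix for intensity weighting.
#' @param gamma_normalization `"plain"` uses \eqn{\gamma = (p+q)/2} for
#'   p + q >= 2; `"hu"` uses the standard \eqn{\gamma = 1 + (p+q)/2}.
#'   The choice does not affect the affine invariants, which normalize
#'   explicitly by powers of \eqn{u_{00}}.
#' @return Object of class `moment_set`: list with matrices `m` and `u`
#'   (4 x 4, entry [p+1, q+1] = order (p, q), NA where p + q > 3), `n`
#'   (normalized), centroid `xbar`, `ybar`, and the `gamma_normalization`
#'   used.
#' @export
compute_moments <- function(mask, gray = NULL,
                            gamma_normalization = c("plain", "hu")) {
  gamma_normalization <- match.arg(gamma_normalization)
  stopifnot(is.matrix(mask))
  if (sum(mask) == 0) stop("empty mask")
  idx <- which(mask == 1L, arr.ind = TRUE)
  x <- idx[, 2] - 1
  y <- idx[, 1] - 1
  w <- if (is.null(gray)) rep(1, nrow(idx)) else gray[idx]
  m <- matrix(NA_real_, 4, 4)
  for (p in 0:3) for (q in 0:(3 - p))
    m[p + 1, q + 1] <- sum(w * x^p * y^q)
  if (m[1, 1] <= 0) stop("zeroth moment is zero: empty or zero-weight region")
  xbar <- m[2, 1] / m[1, 1]
  ybar <- m[1, 2] / m[1, 1]
  u <- matrix(NA_real_, 4, 4)
  xc <- x - xbar; yc <- y - ybar
  for (p in 0:3) for (q in 0:(3 - p))
    u[p + 1, q + 1] <- sum(w * xc^p * yc^q)
  n <- matrix(NA_real_, 4, 4)
  for (p in 0:3) for (q in 0:(3 - p)) {
    g <- if (p + q >= 2) {
      if (gamma_normalization == "plain") (p + q) / 2 else 1 + (p + q) / 2
    } else 1
    n[p + 1, q + 1] <- u[p + 1, q + 1] / u[1, 1]^g
  }
  structure(list(m = m, u = u, n = n, xbar = xbar, ybar = ybar,
                 gamma_normalization = gamma_normalization),
            class = "moment_set")
}

#' Moment-invariant features: first Hu invariant and two affine invariants
#'
#' The first Hu invariant \eqn{\varphi_1} is, by default, computed from the
#' normalized central moments, \eqn{\varphi_1 = n_{20} + n_{02}}, which is
#' invariant to translation, rotation and scale; `hu_mode = "raw"` gives
#' the raw-moment reading \eqn{m_{20} + m_{02}} (not translation
#' invariant -- provided for comparison only). The affine moment
#' invariants are
#' \deqn{I_1 = (u_{20} u_{02} - u_{11}^2) / u_{00}^4}
#' \deqn{I_2 = (u_{30}^2 u_{03}^2 - 6 u_{30} u_{21} u_{12} u_{03}
#'   + 4 u_{30} u_{12}^3 + 4 u_{21}^3 u_{03}
#'   - 3 u_{21}^2 u_{12}^2) / u_{00}^{10}}
#'
#' @param ms A `moment_set` from [compute_moments()].
#' @param hu_mode `"normalized"` (default) or `"raw"`.
#' @return Named list `hu1, ami1, ami2`.
#' @export
invariant_features <- function(ms, hu_mode = c("normalized", "raw")) {
  hu_mode <- match.arg(hu_mode)
  stopifnot(inherits(ms, "moment_set"))
  u <- ms$u
  u00 <- u[1, 1]
  if (u00 <= 0) stop("zeroth central moment is zero")
  hu1 <- if (hu_mode == "normalized") {
    # scale-true Hu normalization regardless of the n_pq convention stored
    (u[3, 1] + u[1, 3]) / u00^2
  } else {
    ms$m[3, 1] + ms$m[1, 3]
  }
  u20 <- u[3, 1]; u02 <- u[1, 3]; u11 <- u[2, 2]
  u30 <- u[4, 1]; u03 <- u[1, 4]; u21 <- u[3, 2]; u12 <- u[2, 3]
  ami1 <- (u20 * u02 - u11^2) / u00^4
  ami2 <- (u30^2 * u03^2 - 6 * u30 * u21 * u12 * u03 +
             4 * u30 * u12^3 + 4 * u21^3 * u03 -
             3 * u21^2 * u12^2) / u00^10
  list(hu1 = hu1, ami1 = ami1, ami2 = ami2)
}
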