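# Brute-force oracles and shape fixtures, independent of the package's
# vectorized implementations.

# reflect-padding index
refl <- function(i, n) {
  if (i < 1) return(2 - i)
  if (i > n) return(2 * n - i)
  i
}

# naive mean-then-median 3x3 filter with reflect padding
oracle_denoise3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  sm <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    v <- numeric(0)
    for (di in -1:1) for (dj in -1:1)
      v <- c(v, m[refl(i + di, nr), refl(j + dj, nc)])
    sm[i, j] <- mean(v)
  }
  md <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    v <- numeric(0)
    for (di in -1:1) for (dj in -1:1)
      v <- c(v, sm[refl(i + di, nr), refl(j + dj, nc)])
    md[i, j] <- median(v)
  }
  md
}

# naive raw/central moments by double loop (x = col-1, y = row-1)
oracle_moments <- function(mask, p, q, central = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (central) {
    m00 <- sum(mask)
    xb <- 0; yb <- 0
    for (i in 1:nr) for (j in 1:nc) if (mask[i, j] == 1) {
      xb <- xb + (j - 1); yb <- yb + (i - 1)
    }
    xb <- xb / m00; yb <- yb / m00
    s <- 0
    for (i in 1:nr) for (j in 1:nc) if (mask[i, j] == 1)
      s <- s + (j - 1 - xb)^p * (i - 1 - yb)^q
    return(s)
  }
  s <- 0
  for (i in 1:nr) for (j in 1:nc) if (mask[i, j] == 1)
    s <- s + (j - 1)^p * (i - 1)^q
  s
}

# naive GLCM by pair enumeration at offset (drow, dcol)
oracle_glcm <- function(gray, mask, levels, drow = 1, dcol = 1) {
  inm <- mask == 1
  mn <- min(gray[inm]); mx <- max(gray[inm])
  q <- if (mx > mn) pmin(floor((gray - mn) / (mx - mn) * levels),
                         levels - 1) else gray * 0
  q <- pmax(q, 0)
  P <- matrix(0, levels, levels)
  nr <- nrow(gray); nc <- ncol(gray)
  for (i in 1:nr) for (j in 1:nc) {
    i2 <- i + drow; j2 <- j + dcol
    if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc &&
        inm[i, j] && inm[i2, j2])
      P[q[i, j] + 1, q[i2, j2] + 1] <- P[q[i, j] + 1, q[i2, j2] + 1] + 1
  }
  P / sum(P)
}

oracle_glcm_features <- function(P) {
  u <- 0; e <- 0; h <- 0; iner <- 0
  L <- nrow(P)
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    u <- u + p^2
    if (p > 0) e <- e - p * log(p)
    h <- h + p / (1 + abs(i - j))
    iner <- iner + p * (i - j)^2
  }
  list(uniformity = u, entropy = e, homogeneity = h, inertia = iner)
}

# shape fixtures -------------------------------------------------------

disk_mask <- function(r, pad = 4L, center_offset = c(0, 0)) {
  n <- 2L * r + 2L * pad + 1L
  cx <- r + pad + 1 + center_offset[2]
  cy <- r + pad + 1 + center_offset[1]
  m <- outer(1:n, 1:n, function(i, j) ((i - cy)^2 + (j - cx)^2 <= r^2) * 1L)
  mode(m) <- "integer"
  m
}

# union of a few random disks inside an n x n canvas
random_blob <- function(n = 32L, k = 3L) {
  m <- matrix(0L, n, n)
  for (s in seq_len(k)) {
    r <- sample(3:7, 1)
    cc <- sample((r + 2):(n - r - 1), 2, replace = TRUE)
    m <- pmax(m, outer(1:n, 1:n, function(i, j)
      ((i - cc[1])^2 + (j - cc[2])^2 <= r^2) * 1L))
  }
  mode(m) <- "integer"
  m
}

# clockwise 90-degree rotation of a matrix
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

# count of 8-connected components by brute-force BFS flood fill
n_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- 0
  for (i0 in 1:nr) for (j0 in 1:nc) {
    if (mask[i0, j0] != 1L || seen[i0, j0]) next
    comps <- comps + 1
    queue <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1] + di; j <- p[2] + dj
        if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
            mask[i, j] == 1L && !seen[i, j]) {
          seen[i, j] <- TRUE
          queue[[length(queue) + 1]] <- c(i, j)
        }
      }
    }
  }
  comps
}

# a gray texture mirror-symmetric about the vertical axis, on an odd canvas
symmetric_texture <- function(n = 33L, seed = 5L) {
  set.seed(seed)
  half <- matrix(round(runif(n * ((n + 1) / 2), 40, 220)), n, (n + 1) / 2)
  cbind(half, half[, ((n - 1) / 2):1, drop = FALSE])
}

# central finite-difference gradients of the per-pattern squared error
oracle_fd_gradients <- function(x, target, Wh, bh, Wo, bo, h = 1e-5) {
  f <- function(Wh, bh, Wo, bo) {
    ah <- 1 / (1 + exp(-(drop(crossprod(Wh, x)) + bh)))
    o <- 1 / (1 + exp(-(drop(crossprod(Wo, ah)) + bo)))
    0.5 * sum((o - target)^2)
  }
  num <- function(par, set) {
    g <- par
    for (k in seq_along(par)) {
      p1 <- par; p1[k] <- p1[k] + h
      p2 <- par; p2[k] <- p2[k] - h
      g[k] <- (do.call(f, set(p1)) - do.call(f, set(p2))) / (2 * h)
    }
    g
  }
  list(
    dWh = num(Wh, function(p) list(p, bh, Wo, bo)),
    dbh = num(bh, function(p) list(Wh, p, Wo, bo)),
    dWo = num(Wo, function(p) list(Wh, bh, p, bo)),
    dbo = num(bo, function(p) list(Wh, bh, Wo, p)))
}

# tiny labeled feature table of two separable Gaussian classes, padded
# to the 15-feature layout
toy_table <- function(n_per = 10L, sep = 4, seed = 1L) {
  set.seed(seed)
  X <- rbind(
    cbind(rnorm(n_per, 0), rnorm(n_per, 0)),
    cbind(rnorm(n_per, sep), rnorm(n_per, sep)))
  M <- cbind(X, matrix(0, 2L * n_per, 13L))
  feature_table(M, rep(c("alpha", "beta"), each = n_per))
}

# brute-force convex-hull rasterization: test every pixel center against
# the hull polygon with cross-product signs (boundary counts as inside)
convex_hull_pixel_count_oracle <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  k <- length(h)
  inside <- function(px, py) {
    s <- 0
    for (i in seq_len(k)) {
      j <- if (i == k) 1 else i + 1
      cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
      if (abs(cr) < 1e-9) next
      if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
    }
    TRUE
  }
  cnt <- 0
  for (py in min(y):max(y)) for (px in min(x):max(x))
    if (inside(px, py)) cnt <- cnt + 1
  cnt
}

# smooth asymmetric "egg" blob and its exact affine shear, rendered by
# point-inclusion of pixel centers (>= 3000 px at the defaults)
sheared_egg_pair <- function(a = 40, b = 30, shear = 0.3, n = 140L) {
  cc <- (n + 1) / 2
  inc <- function(xs, ys) {
    x <- xs / a; y <- ys / (b * (1 + 0.25 * xs / a))
    (x^2 + y^2 <= 1) * 1L
  }
  orig <- outer(1:n, 1:n, function(i, j) inc(j - cc, i - cc))
  sheared <- outer(1:n, 1:n, function(i, j)
    inc((j - cc) - shear * (i - cc), i - cc))
  mode(orig) <- "integer"; mode(sheared) <- "integer"
  list(orig = orig, sheared = sheared)
}
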