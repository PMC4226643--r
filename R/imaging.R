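#' @importFrom stats median rnorm runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

# Internal raster convention: plain numeric matrix, rows = image rows,
# columns = image columns, intensities on 0..255. Color images are
# row x col x 3 arrays. Masks are matrices over {0, 1}. Where equations
# use (x, y), x is the 0-based column and y the 0-based row.

#' Read a specimen photograph
#'
#' Reads a PNG/JPEG/TIFF image into the package's raster convention:
#' a numeric matrix (grayscale) or a row x col x 3 array (color) with
#' intensities on 0--255.
#'
#' @param path Path to the image file.
#' @return A numeric matrix or 3-d array of intensities in [0, 255].
#' @export
read_specimen_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  # EBImage stores [x, y, c]; transpose to [row, col, c]
  if (length(dim(dat)) == 2L) {
    out <- t(dat) * 255
  } else {
    nc <- dim(dat)[3]
    if (nc >= 3L) {
      out <- array(0, dim = c(dim(dat)[2], dim(dat)[1], 3L))
      for (k in 1:3) out[, , k] <- t(dat[, , k]) * 255
    } else {
      out <- t(dat[, , 1]) * 255
    }
  }
  out
}

#' Write a raster as an 8-bit grayscale PNG
#'
#' Masks (values in {0,1}) are written as {0, 255}.
#'
#' @param raster Numeric matrix on 0--255, or a binary mask.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(raster, path) {
  m <- as.matrix(raster)
  if (all(m %in% c(0, 1))) m <- m * 255
  m <- pmin(pmax(m, 0), 255)
  png::writePNG(m / 255, target = path)
  invisible(path)
}

#' Convert a color raster to grayscale
#'
#' Standard luminance weighting 0.299 R + 0.587 G + 0.114 B. Grayscale
#' input is returned unchanged.
#'
#' @param image Row x col x 3 array or numeric matrix, intensities 0--255.
#' @return Numeric matrix of luminances on 0--255.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("expected a 3-channel color raster")
  out <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  matrix(out, dim(image)[1], dim(image)[2])
}

# Reflect-pad a matrix by k pixels on every side (edge mirror without
# repeating the border pixel's outermost reflection convention: standard
# "reflect" duplicates rows 2..k+1 mirrored; for k=1 row 0 = row 2).
pad_reflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(k, nr - 1)) + 1L), seq_len(nr),
          nr - seq_len(min(k, nr - 1)))
  if (nr == 1L) ri <- rep(1L, nr + 2 * k)
  ci <- c(rev(seq_len(min(k, nc - 1)) + 1L), seq_len(nc),
          nc - seq_len(min(k, nc - 1)))
  if (nc == 1L) ci <- rep(1L, nc + 2 * k)
  m[ri, ci, drop = FALSE]
}

# The 3x3 neighborhood of every pixel as an n x 9 matrix (reflect padding).
neighborhood9 <- function(m) {
  p <- pad_reflect(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr * nc, 9L)
  j <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    j <- j + 1L
    out[, j] <- as.vector(p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  out
}

# Exact vectorized median of 9 columns via a partial sorting network:
# sort each column triple, then take the median of (max of mins,
# median of medians, min of maxes).
median9 <- function(x) {
  lo <- pmin; hi <- pmax
  s3 <- function(a, b, c) {
    l1 <- lo(a, b); h1 <- hi(a, b)
    l2 <- lo(h1, c); h2 <- hi(h1, c)
    list(lo(l1, l2), hi(l1, l2), h2)
  }
  t1 <- s3(x[, 1], x[, 2], x[, 3])
  t2 <- s3(x[, 4], x[, 5], x[, 6])
  t3 <- s3(x[, 7], x[, 8], x[, 9])
  a <- hi(hi(t1[[1]], t2[[1]]), t3[[1]])
  b <- s3(t1[[2]], t2[[2]], t3[[2]])[[2]]
  c <- lo(lo(t1[[3]], t2[[3]]), t3[[3]])
  s3(a, b, c)[[2]]
}

#' Denoise a grayscale raster
#'
#' A k x k mean (smoothing) filter followed by a k x k median filter,
#' both with reflect padding at the edges.
#'
#' @param gray Numeric matrix of intensities.
#' @param kernel Odd kernel side length; default 3.
#' @return Denoised matrix, same shape.
#' @export
denoise <- function(gray, kernel = 3L) {
  stopifnot(is.matrix(gray), kernel %% 2 == 1, kernel >= 1)
  if (kernel == 1L) return(gray)
  k <- (kernel - 1L) %/% 2L
  nr <- nrow(gray); nc <- ncol(gray)
  # mean filter
  p <- pad_reflect(gray, k)
  acc <- matrix(0, nr, nc)
  for (dc in -k:k) for (dr in -k:k)
    acc <- acc + p[(k + 1 + dr):(nr + k + dr), (k + 1 + dc):(nc + k + dc)]
  sm <- acc / (kernel * kernel)
  # median filter
  if (kernel == 3L) {
    med <- matrix(median9(neighborhood9(sm)), nr, nc)
  } else {
    p2 <- pad_reflect(sm, k)
    nb <- matrix(0, nr * nc, kernel * kernel)
    j <- 0L
    for (dc in -k:k) for (dr in -k:k) {
      j <- j + 1L
      nb[, j] <- as.vector(p2[(k + 1 + dr):(nr + k + dr),
                              (k + 1 + dc):(nc + k + dc)])
    }
    med <- matrix(apply(nb, 1L, stats::median), nr, nc)
  }
  med
}

#' Binarize a grayscale raster by Otsu's threshold
#'
#' The threshold is chosen by Otsu's method; the foreground is the side
#' of the threshold NOT held by the majority of frame-border pixels, so
#' that interior specimens come out as foreground whether they are darker
#' or lighter than the background.
#'
#' @param gray Numeric matrix of intensities on 0--255.
#' @return Binary mask matrix over {0, 1}.
#' @export
binarize <- function(gray) {
  stopifnot(is.matrix(gray))
  rng <- range(gray)
  if (diff(rng) < .Machine$double.eps * 255)
    stop("no threshold separates foreground: image is constant")
  thr <- EBImage::otsu(EBImage::Image(t(gray) / 255), range = c(0, 1)) * 255
  fg <- (gray > thr) * 1L
  nr <- nrow(gray); nc <- ncol(gray)
  border <- c(fg[1, ], fg[nr, ], fg[, 1], fg[, nc])
  if (mean(border) > 0.5) fg <- 1L - fg   # specimen is interior
  if (sum(fg) == 0) stop("segmentation produced empty foreground")
  mode(fg) <- "integer"
  fg
}

# 8-connected component labelling: 4-connected pass (EBImage::bwlabel),
# then union of label pairs that touch diagonally.
label_components8 <- function(mask) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  n <- max(lab)
  if (n <= 1L) return(list(labels = lab, n = as.integer(n)))
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  nr <- nrow(lab); nc <- ncol(lab)
  for (o in list(c(1L, 1L), c(1L, -1L))) {
    r1 <- 1:(nr - 1); c1 <- max(1, 1 - o[2]):min(nc, nc - o[2])
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + 1L, c1 + o[2], drop = FALSE]
    keep <- a > 0 & b > 0 & a != b
    if (any(keep)) {
      pairs <- unique(cbind(a[keep], b[keep]))
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  list(labels = out, n = length(unique(dense)))
}

# 8-neighbor shifted stacks of a binary mask, frame treated as background.
shift8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1), 2:(nc + 1)] <- mask
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  lapply(offs, function(o)
    p[(2 + o[1]):(nr + 1 + o[1]), (2 + o[2]):(nc + 1 + o[2]), drop = FALSE])
}

#' Extract the contour of a binary mask
#'
#' The contour is exactly the set of foreground pixels with at least one
#' background 8-neighbor; the raster frame counts as background.
#'
#' @param mask Binary mask matrix over {0, 1}.
#' @return Binary mask of boundary pixels.
#' @export
extract_contour <- function(mask) {
  stopifnot(is.matrix(mask))
  if (sum(mask) == 0) stop("empty mask: no contour")
  nb <- shift8(mask)
  nbg <- Reduce(`+`, lapply(nb, function(m) 1L - m))
  out <- (mask == 1L & nbg > 0L) * 1L
  mode(out) <- "integer"
  out
}

#' Skeletonize a binary mask by Zhang--Suen thinning
#'
#' Iterative morphological thinning to a one-pixel-wide, 8-connected
#' skeleton; the 8-connectivity of each component is preserved.
#'
#' @param mask Binary mask matrix over {0, 1}.
#' @return Binary skeleton mask.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  if (sum(mask) == 0) stop("empty mask: no skeleton")
  m <- mask
  mode(m) <- "integer"
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nb <- shift8(m)  # order: N, NE, E, SE, S, SW, W, NW = p2..p9
      p2 <- nb[[1]]; p3 <- nb[[2]]; p4 <- nb[[3]]; p5 <- nb[[4]]
      p6 <- nb[[5]]; p7 <- nb[[6]]; p8 <- nb[[7]]; p9 <- nb[[8]]
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (phase == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Remove the image background
#'
#' Rectangle-initialized background segmentation: background intensity
#' statistics are estimated from the frame ring outside the initialization
#' rectangle (default: the full frame inset by 2 pixels per side), pixels
#' are split by Otsu's threshold on their absolute distance from the
#' background level, and the foreground is cleaned up by hole filling and
#' (optionally) restriction to the largest connected component. Background
#' pixels are set to 0 in the returned raster.
#'
#' @param image Color or grayscale raster, intensities 0--255.
#' @param rect Optional initialization rectangle `c(row0, col0, row1, col1)`
#'   (1-based, inclusive); foreground is sought inside it.
#' @param mask Optional pre-segmented binary mask; when supplied the
#'   segmentation is bypassed and the mask is applied as-is.
#' @param largest_component If TRUE (default), keep only the largest
#'   8-connected foreground component.
#' @return List with `raster` (background zeroed) and `mask` (binary).
#' @export
remove_background <- function(image, rect = NULL, mask = NULL,
                              largest_component = TRUE) {
  gray <- to_grayscale(image)
  nr <- nrow(gray); nc <- ncol(gray)
  if (nr == 0 || nc == 0) stop("empty image")
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(gray)))
    out <- gray * mask
    return(list(raster = out, mask = mask))
  }
  if (is.null(rect)) rect <- c(3L, 3L, nr - 2L, nc - 2L)
  if (rect[1] < 1 || rect[2] < 1 || rect[3] > nr || rect[4] > nc ||
      rect[1] >= rect[3] || rect[2] >= rect[4])
    stop("initialization rectangle outside image bounds")
  ring <- matrix(TRUE, nr, nc)
  ring[rect[1]:rect[3], rect[2]:rect[4]] <- FALSE
  bg_level <- if (any(ring)) stats::median(gray[ring]) else stats::median(gray)
  d <- abs(gray - bg_level)
  if (max(d) < 1e-9) stop("segmentation produced empty foreground")
  thr <- EBImage::otsu(EBImage::Image(t(d) / max(d)), range = c(0, 1)) * max(d)
  fg <- matrix(as.integer(d > thr), nr, nc)
  inrect <- matrix(FALSE, nr, nc)
  inrect[rect[1]:rect[3], rect[2]:rect[4]] <- TRUE
  fg[!inrect] <- 0L
  if (sum(fg) == 0) stop("segmentation produced empty foreground")
  img <- EBImage::Image(t(fg))
  img <- EBImage::fillHull(img)
  fg <- t(EBImage::imageData(img))
  mode(fg) <- "integer"
  if (largest_component) {
    lab <- label_components8(fg)
    if (lab$n > 1L) {
      keep <- which.max(tabulate(lab$labels[lab$labels > 0], lab$n))
      fg <- (lab$labels == keep) * 1L
      mode(fg) <- "integer"
    }
  }
  if (sum(fg) == 0) stop("segmentation produced empty foreground")
  list(raster = gray * fg, mask = fg)
}

#' Run the full preprocessing chain
#'
#' Background removal, grayscale conversion, mean+median denoising, Otsu
#' binarization, contour tracing and skeletonization, producing every
#' intermediate raster the feature extractor needs.
#'
#' @param image Raster (matrix/array) or a path to an image file.
#' @param mask Optional pre-segmented binary mask (bypasses segmentation).
#' @param kernel Denoise kernel size (odd; default 3).
#' @param rect Optional segmentation init rectangle (see
#'   [remove_background()]).
#' @return Object of class `preprocess_result`: list with `gray` (denoised
#'   grayscale), `mask`, `contour`, `skeleton`.
#' @export
preprocess_image <- function(image, mask = NULL, kernel = 3L, rect = NULL) {
  if (is.character(image)) image <- read_specimen_image(image)
  seg <- remove_background(image, rect = rect, mask = mask)
  gray <- denoise(to_grayscale(image), kernel = kernel)
  m <- seg$mask
  if (is.null(mask)) {
    # re-binarize the denoised, background-zeroed raster for a clean mask
    m2 <- tryCatch(binarize(denoise(seg$raster, kernel = kernel)),
                   error = function(e) NULL)
    if (!is.null(m2) && sum(m2 * seg$mask) > 0.5 * sum(seg$mask))
      m <- m2 * seg$mask
    mode(m) <- "integer"
  }
  structure(list(gray = gray, mask = m,
                 contour = extract_contour(m),
                 skeleton = skeletonize(m)),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat("preprocess_result:", nrow(x$mask), "x", ncol(x$mask),
      "| foreground px:", sum(x$mask),
      "| contour px:", sum(x$contour),
      "| skeleton px:", sum(x$skeleton), "\n")
  invisible(x)
}
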