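# Assembly of the fixed-order 15-dimensional feature vector and the
# feature-table CSV plumbing ("the database" that training reads).

#' Canonical feature names, in the frozen vector order
#'
#' Six geometric (A, P, D, C, Co, S), six texture (mu, var, U, E, HG, I),
#' three moment invariants (phi1, I1, I2).
#'
#' @return Character vector of length 15.
#' @export
feature_names <- function() {
  c("A", "P", "D", "C", "Co", "S",
    "mu", "var", "U", "E", "HG", "I",
    "phi1", "I1", "I2")
}

#' Extract the 15-dimensional feature vector from one specimen image
#'
#' Runs the preprocessing chain (or accepts a precomputed
#' `preprocess_result`), then computes the six geometric descriptors on
#' the mask and contour, the six texture statistics on the denoised
#' grayscale restricted to the mask, and the three moment invariants on
#' the binary mask.
#'
#' @param image Raster, path, or a `preprocess_result`.
#' @param mask Optional pre-segmented binary mask (bypasses segmentation).
#' @param levels GLCM gray-level count; default 16.
#' @param offset GLCM pixel offset; default `c(1, 1)`.
#' @param kernel Denoise kernel size; default 3.
#' @param hu_mode `"normalized"` (default) or `"raw"` first Hu invariant.
#' @return Named numeric vector of length 15 in [feature_names()] order.
#' @export
extract_features <- function(image, mask = NULL, levels = 16L,
                             offset = c(1L, 1L), kernel = 3L,
                             hu_mode = "normalized") {
  pp <- if (inherits(image, "preprocess_result")) image else {
    if (is.character(image)) {
      tryCatch(preprocess_image(image, mask = mask, kernel = kernel),
               error = function(e)
                 stop("preprocessing failed for '", image, "': ",
                      conditionMessage(e)))
    } else {
      preprocess_image(image, mask = mask, kernel = kernel)
    }
  }
  geo <- compute_geometry(pp$mask, pp$contour)
  tex <- texture_features(pp$gray, pp$mask, levels = levels, offset = offset)
  inv <- invariant_features(compute_moments(pp$mask), hu_mode = hu_mode)
  out <- c(geo$A, geo$P, geo$D, geo$C, geo$Co, geo$S,
           tex$mu, tex$var, tex$uniformity, tex$entropy,
           tex$homogeneity, tex$inertia,
           inv$hu1, inv$ami1, inv$ami2)
  names(out) <- feature_names()
  if (any(!is.finite(out)))
    stop("non-finite feature value(s): ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Build a feature table from labeled feature vectors
#'
#' @param vectors Matrix or list of 15-vectors (rows = specimens).
#' @param species Character vector of species labels, one per row.
#' @return A `data.frame` with the 15 feature columns plus `species`.
#' @export
feature_table <- function(vectors, species) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  stopifnot(ncol(vectors) == 15L, nrow(vectors) == length(species))
  df <- as.data.frame(vectors)
  colnames(df) <- feature_names()
  df$species <- as.character(species)
  df
}

#' Extract features for a labeled directory tree
#'
#' `dir` must contain one subdirectory per species, each holding specimen
#' images; an optional sibling mask image `<name>_mask.png` is used as a
#' segmentation bypass when present.
#'
#' @param dir Root directory.
#' @param ... Passed to [extract_features()].
#' @return Feature table `data.frame` (15 columns + `species`).
#' @export
extract_features_dir <- function(dir, ...) {
  species_dirs <- list.dirs(dir, recursive = FALSE)
  if (length(species_dirs) == 0) stop("no species subdirectories in ", dir)
  rows <- list(); labs <- character(0)
  for (sd in species_dirs) {
    imgs <- list.files(sd, pattern = "\\.(png|jpe?g|tiff?)$",
                       ignore.case = TRUE, full.names = TRUE)
    imgs <- imgs[!grepl("_mask\\.", imgs)]
    for (f in imgs) {
      maskf <- sub("\\.(png|jpe?g|tiff?)$", "_mask.png", f,
                   ignore.case = TRUE)
      msk <- if (file.exists(maskf)) {
        mm <- read_specimen_image(maskf)
        (to_grayscale(mm) > 127) * 1L
      } else NULL
      rows[[length(rows) + 1L]] <- extract_features(f, mask = msk, ...)
      labs <- c(labs, basename(sd))
    }
  }
  feature_table(rows, labs)
}

#' Write / read a feature table as CSV
#'
#' The CSV carries the 15 canonical feature columns plus `species`;
#' reading validates the header and reports the offending line on
#' malformed input.
#'
#' @param table Feature table `data.frame`.
#' @param path CSV path.
#' @return `write_feature_table`: `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  need <- c(feature_names(), "species")
  if (!all(need %in% colnames(table)))
    stop("feature table missing column(s): ",
         paste(setdiff(need, colnames(table)), collapse = ", "))
  utils::write.csv(table[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @return `read_feature_table`: the feature table `data.frame`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(feature_names(), "species")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("malformed feature table '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  for (cn in feature_names()) {
    bad <- which(!is.finite(df[[cn]]))
    if (length(bad) > 0)
      stop("malformed feature table '", path, "': non-numeric value in ",
           "column ", cn, " at line ", bad[1] + 1L)
  }
  df[, need]
}
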