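# Texture and colour statistics of the rendered pressure image, and the
# assembly of the full 19-parameter posture feature vector.

GLCM_LEVELS <- 16L

# The fixed, documented order of the 19 posture features.
FEATURE_NAMES <- c(
  "circumference", "area", "roundness",
  paste0("hu", 1:7),
  "energy_mean", "energy_sd", "entropy_mean", "entropy_sd",
  "inertia_mean", "inertia_sd",
  "mean_red", "mean_green", "mean_blue"
)

#' Names and order of the 19 posture features
#'
#' @return Character vector of length 19 giving the fixed feature order used
#'   by [extract_feature_vector()] and the classifier.
#' @export
feature_names <- function() FEATURE_NAMES

# One co-occurrence matrix (symmetric, normalized) for a (dr, dc) offset,
# restricted to pixel pairs that both lie in the mask. Returns NULL when the
# offset yields no valid pair.
glcm_matrix <- function(lvl, mask, dr, dc) {
  nr <- nrow(lvl); nc <- ncol(lvl)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- lvl[r1, c1, drop = FALSE]
  b <- lvl[r1 + dr, c1 + dc, drop = FALSE]
  ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
  if (!any(ok)) return(NULL)
  code <- (a[ok]) * GLCM_LEVELS + b[ok] + 1L
  counts <- tabulate(code, nbins = GLCM_LEVELS * GLCM_LEVELS)
  m <- matrix(counts, GLCM_LEVELS, GLCM_LEVELS, byrow = TRUE)
  m <- m + t(m)
  m / sum(m)
}

#' Grey-level co-occurrence texture features
#'
#' Quantizes the grey image to 16 levels over the full 0-255 range, tabulates
#' four symmetric normalized co-occurrence matrices at distance 1 (angles 0,
#' 45, 90 and 135 degrees) over the masked region, computes per-matrix energy
#' (sum of squared probabilities), entropy (base-2, `0 * log 0 := 0`) and
#' inertia (moment of inertia about the diagonal), and reports the mean and
#' standard deviation of each statistic across the four directions.
#'
#' @param gray Integer grey-level matrix (0-255).
#' @param mask Logical matrix of the same shape; pairs are counted only where
#'   both pixels are masked.
#' @return Named numeric vector: `energy_mean`, `energy_sd`, `entropy_mean`,
#'   `entropy_sd`, `inertia_mean`, `inertia_sd`.
#' @export
glcm_features <- function(gray, mask) {
  if (!is.matrix(gray) || !is.matrix(mask) || !all(dim(gray) == dim(mask))) {
    stop_domain("`gray` and `mask` must be matrices of equal shape")
  }
  if (sum(mask) < 2L) stop_domain("masked region must contain at least 2 pixels")
  lvl <- pmin(pmax(gray, 0L), 255L) %/% (256L %/% GLCM_LEVELS)
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  idx <- seq_len(GLCM_LEVELS)
  inertia_w <- outer(idx, idx, function(i, j) (i - j)^2)
  stats <- vapply(offsets, function(off) {
    m <- glcm_matrix(lvl, mask, off[1], off[2])
    if (is.null(m)) stop_domain("masked region has no pixel pairs at distance 1")
    p <- m[m > 0]
    c(energy = sum(m^2),
      entropy = -sum(p * log2(p)),
      inertia = sum(inertia_w * m))
  }, numeric(3))
  c(energy_mean = mean(stats["energy", ]), energy_sd = sd(stats["energy", ]),
    entropy_mean = mean(stats["entropy", ]), entropy_sd = sd(stats["entropy", ]),
    inertia_mean = mean(stats["inertia", ]), inertia_sd = sd(stats["inertia", ]))
}

#' Mean colour of the masked image region
#'
#' Arithmetic means of the red, green and blue channels over the masked
#' pixels. A mask at a coarser resolution than the image is expanded by
#' integer-factor nearest-neighbour replication.
#'
#' @param image A `rendered_image`.
#' @param mask Logical matrix, same shape as the image or an integer fraction
#'   of it; must select at least one pixel.
#' @return Named numeric vector `mean_red`, `mean_green`, `mean_blue`
#'   (0-255).
#' @export
color_features <- function(image, mask) {
  stopifnot(inherits(image, "rendered_image"))
  dims <- dim(image$rgb)[1:2]
  if (!all(dim(mask) == dims)) {
    fac <- dims / dim(mask)
    if (any(fac != round(fac))) {
      stop_domain("mask shape must equal the image shape or divide it evenly")
    }
    mask <- mask[rep(seq_len(nrow(mask)), each = fac[1]),
                 rep(seq_len(ncol(mask)), each = fac[2])]
  }
  if (!any(mask)) stop_domain("mask selects no pixels")
  c(mean_red = mean(image$rgb[, , 1][mask]),
    mean_green = mean(image$rgb[, , 2][mask]),
    mean_blue = mean(image$rgb[, , 3][mask]))
}

#' Extract the 19-parameter posture feature vector from a pressure frame
#'
#' Runs the full preprocessing and feature chain: render the frame as a
#' colour image, convert to grey level, median-filter, binarize by the
#' between-class-variance criterion, keep the largest connected component,
#' then compute the geometric features (circumference, area, roundness, Hu
#' moments 1-7) on the component silhouette, the co-occurrence texture
#' statistics on the filtered grey image over the component, and the mean
#' red/green/blue over the component. The result is deterministic in the
#' frame and the configuration.
#'
#' @param frame 16x16 numeric pressure frame (volts).
#' @param upsample Rendering upsample factor (default 16).
#' Readings that dip below zero (sensor noise around an unloaded cell) are
#' clipped at zero before rendering.
#'
#' @return Named numeric vector of length 19 in the [feature_names()] order.
#' @export
#' @examples
#' f <- extract_feature_vector(posture_template(1)$base_map)
#' round(f[1:3], 2)
extract_feature_vector <- function(frame, upsample = 16L) {
  if (is.matrix(frame) && all(is.finite(frame))) frame <- pmax(frame, 0)
  img <- render_frame_image(frame, upsample = upsample)
  gray <- to_grayscale(img)
  smooth <- median_filter3(gray)
  bin <- binarize(smooth)
  shape <- extract_shape(bin$binary)
  area <- sum(shape$component)
  circumference <- contour_length(shape$contour)
  roundness <- if (circumference > 0) 4 * pi * area / circumference^2 else 0
  hu <- hu_moments(shape$component)
  tex <- glcm_features(smooth, shape$component)
  col <- color_features(img, shape$component)
  out <- c(circumference, area, roundness, hu, tex, col)
  names(out) <- FEATURE_NAMES
  out
}

#' Feature matrix of a posture dataset
#'
#' Applies [extract_feature_vector()] to every frame of a
#' [generate_posture_dataset()] result.
#'
#' @param dataset A `posture_dataset`.
#' @param upsample Rendering upsample factor.
#' @return Numeric matrix, one row per frame, 19 named columns.
#' @export
dataset_features <- function(dataset, upsample = 16L) {
  stopifnot(inherits(dataset, "posture_dataset"))
  n <- length(dataset$labels)
  out <- matrix(NA_real_, n, length(FEATURE_NAMES),
                dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(n)) {
    out[i, ] <- extract_feature_vector(dataset$frames[, , i],
                                       upsample = upsample)
  }
  out
}

#' Fit / apply the max-abs feature normalization
#'
#' Normalizes each feature by the maximum absolute value observed in the
#' fitting set, `Q* = Q / max|Q|`, so every training feature lies in
#' `[-1, 1]`. Columns that are identically zero keep denominator 1.
#' Denominators come from the fitting data only; apply the fitted scaler to
#' any later data.
#'
#' @param features Numeric matrix (rows = samples) or a single feature
#'   vector.
#' @return `fit_scaler`: an object of class `feature_scaler` (named
#'   denominators). `apply_scaler`: the normalized features, same shape as
#'   the input.
#' @export
fit_scaler <- function(features) {
  features <- rbind(features)
  denom <- apply(abs(features), 2, max)
  denom[denom == 0] <- 1
  structure(list(denominators = denom), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `feature_scaler`.
#' @export
apply_scaler <- function(scaler, features) {
  stopifnot(inherits(scaler, "feature_scaler"))
  if (is.matrix(features)) {
    sweep(features, 2, scaler$denominators, "/")
  } else {
    features / scaler$denominators
  }
}

#' @export
print.feature_scaler <- function(x, ...) {
  cat("<feature_scaler> max|Q| denominators for", length(x$denominators),
      "features\n")
  invisible(x)
}
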