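# Image preprocessing chain: render the 16x16 pressure frame as a colour map,
# convert to grey level, median-filter and binarize. Features downstream are
# computed on this image intermediate, not on the raw grid: at 16x16 the
# contour, moment and texture statistics are too coarse to be stable.

# Fixed rendering voltage range; frames are clipped into it before colouring.
RENDER_VMAX <- 3.0

# Blue -> cyan -> yellow -> red colour scale used for all rendered frames
# (jet-like; the exact ramp is a package convention and colour features are
# only meaningful relative to it).
render_ramp <- local({
  ramp <- NULL
  function() {
    if (is.null(ramp)) {
      ramp <<- grDevices::colorRamp(
        c("#00008F", "#0000FF", "#00FFFF", "#FFFF00", "#FF0000", "#8F0000"),
        space = "rgb")
    }
    ramp
  }
})

check_frame <- function(frame) {
  if (!is.matrix(frame) || !all(dim(frame) == c(MAT_NROW, MAT_NCOL))) {
    stop_domain("a pressure frame must be a 16x16 matrix")
  }
  if (!all(is.finite(frame)) || any(frame < 0)) {
    stop_domain("pressure frame values must be finite and >= 0")
  }
  invisible(frame)
}

# Bilinear upsampling of a matrix by an integer factor; output pixel centres
# are mapped into the input coordinate frame and clamped at the borders.
bilinear_upsample <- function(m, factor) {
  if (factor == 1) return(m)
  up_coord <- function(n_in, n_out) {
    x <- ((seq_len(n_out) - 0.5) * n_in / n_out) + 0.5
    pmin(pmax(x, 1), n_in)
  }
  xr <- up_coord(nrow(m), nrow(m) * factor)
  xc <- up_coord(ncol(m), ncol(m) * factor)
  r0 <- pmin(floor(xr), nrow(m) - 1L)
  c0 <- pmin(floor(xc), ncol(m) - 1L)
  fr <- xr - r0
  fc <- xc - c0
  a <- m[r0, c0, drop = FALSE]
  b <- m[r0 + 1L, c0, drop = FALSE]
  cc <- m[r0, c0 + 1L, drop = FALSE]
  d <- m[r0 + 1L, c0 + 1L, drop = FALSE]
  wr <- matrix(fr, length(xr), length(xc))
  wc <- matrix(fc, length(xr), length(xc), byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) + cc * (1 - wr) * wc +
    d * wr * wc
}

#' Render a pressure frame as a colour image
#'
#' Rescales the frame linearly over the fixed voltage range `[0, v_max]`
#' (clipping above), bilinearly upsamples it and maps it through a fixed
#' blue-to-red colour scale, reconstructing the colour-map images the posture
#' features are computed on.
#'
#' @param frame 16x16 numeric pressure frame (volts).
#' @param upsample Integer upsampling factor >= 1 (default 16, i.e. 256x256).
#' @param v_max Upper end of the rendering voltage range.
#' @return An object of class `rendered_image`: list with `rgb` (H x W x 3
#'   integer array, 0-255) and `colormap_name`.
#' @export
render_frame_image <- function(frame, upsample = 16L, v_max = RENDER_VMAX) {
  check_frame(frame)
  upsample <- as.integer(upsample)
  if (upsample < 1L) stop_domain("`upsample` must be >= 1")
  norm <- pmin(frame / v_max, 1)
  up <- bilinear_upsample(norm, upsample)
  cols <- render_ramp()(as.vector(up))
  rgb <- array(0L, c(nrow(up), ncol(up), 3L))
  for (ch in 1:3) {
    rgb[, , ch] <- matrix(as.integer(round(cols[, ch])), nrow(up), ncol(up))
  }
  structure(list(rgb = rgb, colormap_name = "seatbeat-jet"),
            class = "rendered_image")
}

#' Convert a rendered image to grey level
#'
#' Per-pixel luminance `0.299 R + 0.587 G + 0.114 B`, rounded to the nearest
#' integer (ITU-R 601 weights).
#'
#' @param image A `rendered_image`.
#' @return Integer matrix of grey levels 0-255.
#' @export
to_grayscale <- function(image) {
  stopifnot(inherits(image, "rendered_image"))
  dims <- dim(image$rgb)
  g <- 0.299 * image$rgb[, , 1] + 0.587 * image$rgb[, , 2] +
    0.114 * image$rgb[, , 3]
  matrix(as.integer(round(g)), dims[1], dims[2])
}

# Pad a matrix by one pixel on each side with edge reflection (the border
# pixel itself is mirrored, i.e. "symmetric" padding).
reflect_pad1 <- function(m) {
  m2 <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m2[, 1, drop = FALSE], m2, m2[, ncol(m2), drop = FALSE])
}

#' 3x3 median filter
#'
#' Replaces every pixel by the median of its 3x3 neighbourhood; edges are
#' handled by reflecting the border pixels. Implemented as a vectorised
#' 19-exchange sorting network over the nine shifted images, so it is exact
#' and fast on large grids.
#'
#' @param gray Numeric or integer matrix, at least 3x3.
#' @return Matrix of the same shape and type-compatible values.
#' @export
median_filter3 <- function(gray) {
  if (!is.matrix(gray) || nrow(gray) < 3L || ncol(gray) < 3L) {
    stop_domain("median_filter3 requires a grid of at least 3x3")
  }
  p <- reflect_pad1(gray)
  nr <- nrow(gray); nc <- ncol(gray)
  shift <- function(dr, dc) p[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  v <- list(shift(0, 0), shift(0, 1), shift(0, 2),
            shift(1, 0), shift(1, 1), shift(1, 2),
            shift(2, 0), shift(2, 1), shift(2, 2))
  xch <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]])
    hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  # Paeth's 19-comparator median-of-9 network; the median lands in v[[5]]
  xch(2, 3); xch(5, 6); xch(8, 9)
  xch(1, 2); xch(4, 5); xch(7, 8)
  xch(2, 3); xch(5, 6); xch(8, 9)
  xch(1, 4); xch(6, 9); xch(5, 8)
  xch(4, 7); xch(2, 5); xch(3, 6)
  xch(5, 8); xch(5, 3); xch(7, 5)
  xch(5, 3)
  v[[5]]
}

#' Binarize a grey image by between-class variance maximization
#'
#' Chooses the threshold maximizing the between-class variance of the
#' foreground/background split (Otsu's criterion, exhaustive over candidate
#' levels; ties resolved toward the lowest threshold). Pixels strictly above
#' the threshold are foreground. A constant image has no split and falls back
#' to all-foreground with threshold `value - 1`.
#'
#' @param gray Numeric or integer matrix.
#' @return List with `binary` (logical matrix, TRUE = foreground) and
#'   `threshold`.
#' @export
binarize <- function(gray) {
  if (!is.matrix(gray) || length(gray) == 0L) {
    stop_domain("binarize requires a non-empty matrix")
  }
  vals <- sort(unique(as.vector(gray)))
  if (length(vals) == 1L) {
    return(list(binary = matrix(TRUE, nrow(gray), ncol(gray)),
                threshold = vals - 1))
  }
  # histogram over the observed levels, then cumulative class statistics;
  # candidate thresholds are all levels except the maximum (foreground is
  # strictly above the cut, so the top level can never split)
  n <- length(gray)
  cnt <- tabulate(match(as.vector(gray), vals), nbins = length(vals))
  cumcnt <- cumsum(cnt)
  cumsumv <- cumsum(cnt * vals)
  k <- length(vals) - 1L
  counts <- cumcnt[seq_len(k)]
  sums <- cumsumv[seq_len(k)]
  tot_sum <- cumsumv[length(vals)]
  w0 <- counts / n
  w1 <- 1 - w0
  mu0 <- sums / counts
  mu1 <- (tot_sum - sums) / (n - counts)
  between <- w0 * w1 * (mu0 - mu1)^2
  threshold <- vals[which.max(between)]
  list(binary = gray > threshold, threshold = threshold)
}
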