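# Shape analysis of the binarized pressure image: largest connected
# component, 8-connected boundary tracing, minimum-area enclosing rectangle,
# and the geometric/moment features derived from them.

# Logical matrix -> logical matrix keeping only the largest connected
# component (ties broken toward the first label in scan order). Labeling is
# delegated to EBImage::bwlabel.
largest_component <- function(binary) {
  if (!is.matrix(binary)) stop_domain("binary grid must be a matrix")
  if (!any(binary)) stop_domain("binary grid has no foreground pixels")
  lab <- EBImage::bwlabel(matrix(as.numeric(binary), nrow(binary)))
  lab <- matrix(as.integer(lab), nrow(binary))
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  lab == keep
}

# Moore-neighbour boundary tracing of a single connected component. Returns
# an n x 2 matrix of (row, col) boundary pixels in traversal order; a lone
# pixel yields a single row.
trace_contour <- function(binary) {
  fg <- which(t(binary), arr.ind = FALSE) # row-major scan order
  if (length(fg) == 0L) stop_domain("empty foreground")
  start_idx <- fg[1L]
  nr <- nrow(binary); nc <- ncol(binary)
  start <- c((start_idx - 1L) %/% nc + 1L, (start_idx - 1L) %% nc + 1L)
  # clockwise Moore neighbourhood starting at W
  dirs <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                   0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                 ncol = 2L, byrow = TRUE)
  inside <- function(p) p[1] >= 1L && p[1] <= nr && p[2] >= 1L && p[2] <= nc
  is_fg <- function(p) inside(p) && binary[p[1], p[2]]
  contour <- matrix(start, 1L, 2L)
  # the scan reached `start` coming from the west
  backtrack_dir <- 1L
  cur <- start
  max_steps <- 4L * sum(binary) + 8L
  steps <- 0L
  repeat {
    found <- FALSE
    d <- backtrack_dir
    for (k in seq_len(8L)) {
      d <- d %% 8L + 1L
      cand <- cur + dirs[d, ]
      if (is_fg(cand)) {
        # new backtrack: direction from `cand` toward the (background)
        # neighbour checked just before it; consecutive ring cells are
        # adjacent, so this is always one of the eight directions
        prev <- d - 1L; if (prev == 0L) prev <- 8L
        back_cell <- cur + dirs[prev, ]
        delta <- back_cell - cand
        backtrack_dir <- which(dirs[, 1] == delta[1] & dirs[, 2] == delta[2])
        cur <- cand
        found <- TRUE
        break
      }
    }
    steps <- steps + 1L
    if (!found) break # isolated pixel
    if (all(cur == start) || steps > max_steps) break
    contour <- rbind(contour, cur)
  }
  dimnames(contour) <- list(NULL, c("row", "col"))
  contour
}

# Closed-path length of a traced contour: unit steps for axis moves, sqrt(2)
# for diagonal moves, including the closing step. A single-pixel contour has
# length 0.
contour_length <- function(contour) {
  n <- nrow(contour)
  if (n < 2L) return(0)
  nxt <- rbind(contour[-1L, , drop = FALSE], contour[1L, , drop = FALSE])
  steps <- sqrt(rowSums((nxt - contour)^2))
  sum(steps)
}

# Minimum-area (possibly rotated) rectangle enclosing the pixel squares of a
# component, via rotating calipers over the convex hull of the pixel corners.
min_enclosing_rect <- function(binary) {
  px <- which(binary, arr.ind = TRUE)
  if (nrow(px) == 0L) stop_domain("empty foreground")
  # each pixel contributes its four unit-square corners
  corners <- rbind(
    cbind(px[, 1] - 0.5, px[, 2] - 0.5),
    cbind(px[, 1] - 0.5, px[, 2] + 0.5),
    cbind(px[, 1] + 0.5, px[, 2] - 0.5),
    cbind(px[, 1] + 0.5, px[, 2] + 0.5)
  )
  hull <- corners[grDevices::chull(corners[, 1], corners[, 2]), , drop = FALSE]
  if (nrow(hull) == 1L) {
    return(list(sides = c(0, 0), angle = 0, center = hull[1, ]))
  }
  edges <- rbind(hull[-1L, , drop = FALSE], hull[1L, , drop = FALSE]) - hull
  angles <- unique(atan2(edges[, 2], edges[, 1]) %% (pi / 2))
  best <- NULL
  for (a in angles) {
    rot <- cbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
    pts <- hull %*% rot
    w <- diff(range(pts[, 1]))
    h <- diff(range(pts[, 2]))
    if (is.null(best) || w * h < best$area - 1e-12) {
      centre_rot <- c(mean(range(pts[, 1])), mean(range(pts[, 2])))
      best <- list(area = w * h, sides = sort(c(w, h)), angle = a,
                   center = as.vector(centre_rot %*% t(rot)))
    }
  }
  best$area <- NULL
  best
}

#' Contour and minimum enclosing rectangle of a binary image
#'
#' Keeps the largest connected component of the foreground, traces its
#' 8-connected boundary and computes the minimum-area (possibly rotated)
#' rectangle enclosing it.
#'
#' @param binary Logical matrix (TRUE = foreground) with at least one
#'   foreground pixel.
#' @return List with `contour` (n x 2 matrix of boundary (row, col) pixels in
#'   traversal order), `rect` (list with `sides` — the two side lengths in
#'   pixels, ascending —, `angle` and `center`) and `component` (the logical
#'   mask of the kept component).
#' @export
extract_shape <- function(binary) {
  comp <- largest_component(binary)
  contour <- trace_contour(comp)
  rect <- min_enclosing_rect(comp)
  list(contour = contour, rect = rect, component = comp)
}

# The seven Hu invariant moments of a binary pixel set (unit mass per pixel).
hu_moments <- function(binary) {
  px <- which(binary, arr.ind = TRUE)
  x <- px[, 2]; y <- px[, 1]
  n <- length(x)
  xc <- mean(x); yc <- mean(y)
  dx <- x - xc; dy <- y - yc
  mu <- function(p, q) sum(dx^p * dy^q)
  eta <- function(p, q) mu(p, q) / n^(1 + (p + q) / 2)
  e20 <- eta(2, 0); e02 <- eta(0, 2); e11 <- eta(1, 1)
  e30 <- eta(3, 0); e03 <- eta(0, 3); e21 <- eta(2, 1); e12 <- eta(1, 2)
  s1 <- e30 + e12; s2 <- e21 + e03
  d1 <- e30 - 3 * e12; d2 <- 3 * e21 - e03
  c(
    e20 + e02,
    (e20 - e02)^2 + 4 * e11^2,
    d1^2 + d2^2,
    s1^2 + s2^2,
    d1 * s1 * (s1^2 - 3 * s2^2) + d2 * s2 * (3 * s1^2 - s2^2),
    (e20 - e02) * (s1^2 - s2^2) + 4 * e11 * s1 * s2,
    d2 * s1 * (s1^2 - 3 * s2^2) - d1 * s2 * (3 * s1^2 - s2^2)
  )
}

#' Geometric features of the binarized pressure image
#'
#' On the largest connected component: `area` is the foreground pixel count,
#' `circumference` the traced 8-connected boundary length (diagonal steps
#' count sqrt(2)), `roundness` the circularity `4 * pi * area /
#' circumference^2` (1 for an ideal disk; 0 for a degenerate contour), and
#' `hu` the seven Hu invariant moments of the component silhouette.
#'
#' @param binary Logical matrix with at least one foreground pixel.
#' @return Named list: `circumference`, `area`, `roundness`, `hu` (length 7).
#' @export
geometric_features <- function(binary) {
  comp <- largest_component(binary)
  contour <- trace_contour(comp)
  area <- sum(comp)
  circumference <- contour_length(contour)
  roundness <- if (circumference > 0) 4 * pi * area / circumference^2 else 0
  list(circumference = circumference, area = area, roundness = roundness,
       hu = hu_moments(comp))
}
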