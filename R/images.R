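## Low-level image utilities shared by the synthetic generators and the
## quantification modules. Frames are plain numeric matrices in [0, 1] with
## row index = y (increasing downward) and column index = x (increasing
## rightward); all node coordinates are 0-based pixel indices.

#' Validate and coerce a grayscale frame
#'
#' @param frame numeric matrix; values outside [0, 1] are clamped.
#' @return numeric matrix in [0, 1]
#' @keywords internal
as_frame <- function(frame) {
  if (is.array(frame) && length(dim(frame)) == 3L) {
    # collapse RGB to luminance
    frame <- apply(frame, c(1, 2), mean)
  }
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("a frame must be a numeric matrix")
  if (anyNA(frame)) stop("frame contains NA pixels")
  pmin(pmax(frame, 0), 1)
}

# Affine intensity normalization to [0, 1]; flat frames map to all zeros.
normalize_frame <- function(frame) {
  frame <- as_frame(frame)
  rng <- range(frame)
  if (diff(rng) < .Machine$double.eps) return(frame * 0)
  (frame - rng[1]) / diff(rng)
}

# Pixel-center coordinate grids (0-based). Returns list(x, y) of matrices
# shaped like the frame.
pixel_grid_xy <- function(shape) {
  x <- matrix(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[1], shape[2])
  y <- matrix(rep(seq_len(shape[1]) - 1, times = shape[2]), shape[1], shape[2])
  list(x = x, y = y)
}

#' Warp an image through a backward (target-to-source) coordinate map
#'
#' Inverse mapping avoids holes: every target pixel samples the source at the
#' mapped location with bicubic (Catmull-Rom) interpolation, preserving the
#' smooth speckle texture that subset correlation relies on. Samples outside
#' the source are clamped to the border.
#'
#' @param img numeric matrix in [0, 1]
#' @param backward_map function(x, y) taking vectors of 0-based target
#'   coordinates and returning list(x, y) of source coordinates
#' @return warped matrix, same shape
#' @keywords internal
warp_backward <- function(img, backward_map) {
  sh <- dim(img)
  g <- pixel_grid_xy(sh)
  src <- backward_map(as.vector(g$x), as.vector(g$y))
  out <- interp_bicubic(img, src$x, src$y)
  matrix(pmin(pmax(out, 0), 1), sh[1], sh[2])
}

# Catmull-Rom bicubic interpolation at fractional 0-based (x, y), vectorized.
interp_bicubic <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # Catmull-Rom weights for offsets -1, 0, 1, 2
  wcat <- function(f) {
    f2 <- f * f; f3 <- f2 * f
    list(-0.5 * f3 + f2 - 0.5 * f,
         1.5 * f3 - 2.5 * f2 + 1,
         -1.5 * f3 + 2 * f2 + 0.5 * f,
         0.5 * f3 - 0.5 * f2)
  }
  wx <- wcat(fx); wy <- wcat(fy)
  clamp <- function(v, hi) pmin(pmax(v, 0), hi)
  out <- numeric(length(x))
  for (j in 1:4) {
    xi <- clamp(x0 + j - 2, nc - 1)
    col_acc <- numeric(length(x))
    for (i in 1:4) {
      yi <- clamp(y0 + i - 2, nr - 1)
      col_acc <- col_acc + wy[[i]] * img[cbind(yi + 1, xi + 1)]
    }
    out <- out + wx[[j]] * col_acc
  }
  out
}

# Stamp anti-aliased discs onto a canvas. centers: matrix [n, 2] of (x, y)
# 0-based; value blended by coverage; mode "min" darkens (speckles on bright
# background), "max" brightens (fluorescent blobs).
draw_discs <- function(canvas, centers, radius, value, mode = c("min", "max")) {
  mode <- match.arg(mode)
  nr <- nrow(canvas); nc <- ncol(canvas)
  r_out <- radius + 1
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    xs <- max(0, floor(cx - r_out)):min(nc - 1, ceiling(cx + r_out))
    ys <- max(0, floor(cy - r_out)):min(nr - 1, ceiling(cy + r_out))
    if (!length(xs) || !length(ys)) next
    d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
    cov <- pmin(pmax(radius + 0.5 - d, 0), 1)      # linear edge coverage
    patch <- canvas[ys + 1, xs + 1, drop = FALSE]
    mixed <- patch * (1 - cov) + value * cov
    canvas[ys + 1, xs + 1] <- if (mode == "min") pmin(patch, mixed) else pmax(patch, mixed)
  }
  canvas
}

# Additive Gaussian blobs (for soft fluorescent cells/nuclei).
draw_gaussian_blobs <- function(canvas, centers, sigma, amplitude = 0.9) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  r_out <- ceiling(3 * sigma)
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    xs <- max(0, floor(cx - r_out)):min(nc - 1, ceiling(cx + r_out))
    ys <- max(0, floor(cy - r_out)):min(nr - 1, ceiling(cy + r_out))
    if (!length(xs) || !length(ys)) next
    g <- exp(-outer((ys - cy)^2, (xs - cx)^2, `+`) / (2 * sigma^2))
    canvas[ys + 1, xs + 1] <- pmin(1, canvas[ys + 1, xs + 1] + amplitude * g)
  }
  canvas
}

# Rejection-sample n point centers with a minimum pairwise distance inside
# the frame (with a border margin). Errors when packing is impossible.
sample_centers <- function(n, shape, min_dist, margin, max_tries = 200L) {
  xs <- numeric(0); ys <- numeric(0)
  lim_x <- c(margin, shape[2] - 1 - margin)
  lim_y <- c(margin, shape[1] - 1 - margin)
  if (lim_x[2] <= lim_x[1] || lim_y[2] <= lim_y[1])
    stop("frame too small for the requested margin")
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, lim_x[1], lim_x[2])
      y <- runif(1, lim_y[1], lim_y[2])
      if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= min_dist^2) {
        xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("could not place %d objects with min distance %.1f px (packing too dense)",
                   n, min_dist))
  }
  cbind(x = xs, y = ys)
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  out <- EBImage::gblur(img, sigma = sigma)
  matrix(EBImage::imageData(out), nrow(img), ncol(img))
}
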