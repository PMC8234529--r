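## Image quantification: colony progression distance/rate, live/dead cell
## counting, nuclei counting with watershed splitting, and
## skeletonization-based total F-actin length. Segmentation primitives
## (median filter, Otsu threshold, distance-transform watershed) come from
## EBImage; skeletonization is a Zhang-Suen thinning implemented here.

ebi <- function(x) EBImage::Image(x)
ebi_mat <- function(x) {
  d <- dim(x)
  matrix(EBImage::imageData(x), d[1], d[2])
}

otsu_threshold <- function(img) {
  EBImage::otsu(ebi(img), range = c(0, 1), levels = 256L)
}

#' Segment the cell-occupied colony region of a frame
#'
#' Median filtering followed by Otsu binarization; the largest connected
#' component is kept and its holes filled. With \code{polarity = "auto"} the
#' minority intensity class is taken as the colony (the colony occupies less
#' than half of the frame); the flag exists so an inverted-contrast image
#' yields the same region.
#'
#' @param frame grayscale matrix
#' @param median_radius median filter half-size, px
#' @param polarity "auto", "bright" (colony brighter than background) or "dark"
#' @return list with \code{mask} (logical matrix) and \code{area} (px^2)
#' @export
segment_colony <- function(frame, median_radius = 2L,
                           polarity = c("auto", "bright", "dark")) {
  polarity <- match.arg(polarity)
  img <- normalize_frame(frame)
  if (diff(range(img)) < .Machine$double.eps)
    stop("empty (flat) frame: nothing to segment")
  if (median_radius > 0) img <- ebi_mat(EBImage::medianFilter(ebi(img), median_radius))
  th <- otsu_threshold(img)
  mask <- img > th
  if (polarity == "dark" || (polarity == "auto" && mean(mask) > 0.5)) mask <- !mask
  if (!any(mask)) stop("empty mask after binarization")
  labels <- EBImage::bwlabel(ebi(mask))
  sizes <- tabulate(as.integer(EBImage::imageData(labels)))
  keep <- which.max(sizes)
  comp <- ebi_mat(labels) == keep
  comp <- ebi_mat(EBImage::fillHull(ebi(comp))) > 0
  list(mask = comp, area = sum(comp))
}

#' Progression distance from occupied areas
#'
#' The difference between the equivalent-circle radii of the occupied area
#' at time t and at time 0: l_t = sqrt(a_t/pi) - sqrt(a_0/pi). Negative when
#' the region shrinks.
#'
#' @param a_t area at time t (same unit as a0, e.g. px^2 or mm^2); vectorized
#' @param a0 area at time 0
#' @return progression distance in the corresponding length unit
#' @export
progression_distance <- function(a_t, a0) {
  if (any(a_t <= 0) || a0 <= 0) stop("areas must be > 0")
  sqrt(a_t / pi) - sqrt(a0 / pi)
}

#' Colony measurement record
#'
#' @param times acquisition times, h (first must be 0)
#' @param areas occupied areas at each time (> 0); px^2, or mm^2 when
#'   \code{pixel_size} (mm/px) is given and areas are in px^2
#' @param pixel_size optional pixel size (length unit per px) used to convert
#'   areas to physical units
#' @return object of class \code{colony_measure} with \code{l_t} and
#'   \code{a0} fields
#' @export
colony_measure <- function(times, areas, pixel_size = NULL) {
  if (length(times) != length(areas)) stop("times and areas must match")
  if (times[1] != 0) stop("first time point must be 0")
  if (any(areas <= 0)) stop("areas must be > 0")
  if (!is.null(pixel_size)) areas <- areas * pixel_size^2
  structure(list(times = times, areas = areas, a0 = areas[1],
                 l_t = progression_distance(areas, areas[1])),
            class = "colony_measure")
}

#' Progression rate: slope of the progression distance over time
#'
#' Ordinary least-squares line of l_t against t.
#'
#' @param measure a [colony_measure()]
#' @return list(slope, intercept); slope in length unit per hour
#' @export
progression_rate <- function(measure) {
  stopifnot(inherits(measure, "colony_measure"))
  if (length(measure$times) < 3) stop("need at least 3 time points")
  fit <- lm(l ~ t, data = data.frame(t = measure$times, l = measure$l_t))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}

# Scale-normalized Laplacian-of-Gaussian kernel (bright blobs -> positive
# response after negation).
log_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  xs <- -r:r
  g <- outer(xs^2, xs^2, `+`)
  k <- (g - 2 * sigma^2) / sigma^4 * exp(-g / (2 * sigma^2))
  k <- k * sigma^2                          # scale normalization
  k - mean(k)                               # zero-DC: flat regions respond 0
}

#' Count rounded bright cells by Laplacian-of-Gaussian blob detection
#'
#' A functional equivalent of template-based nucleus counters: the frame is
#' intensity-normalized, convolved with a scale-normalized LoG matched to
#' \code{cell_diameter}, and blobs are local maxima of the response within a
#' \code{cell_diameter/2} suppression radius, above a threshold relative to
#' the strongest response.
#'
#' @param frame grayscale matrix
#' @param cell_diameter expected cell diameter, px (> 2)
#' @param rel_threshold maxima below \code{rel_threshold * max(response)}
#'   are discarded
#' @return integer count (0 for a blank frame)
#' @export
count_live_cells <- function(frame, cell_diameter = 12, rel_threshold = 0.2) {
  if (cell_diameter <= 2) stop("cell_diameter must be > 2 px")
  img <- normalize_frame(frame)
  if (diff(range(img)) < .Machine$double.eps) return(0L)
  sigma <- cell_diameter / (2 * sqrt(2))
  resp <- -ebi_mat(EBImage::filter2(ebi(img), log_kernel(sigma)))
  if (max(resp) <= 0) return(0L)
  supp <- max(3L, 2L * floor(cell_diameter / 4) + 1L)   # ~ d/2 suppression
  brush <- EBImage::makeBrush(supp, shape = "disc")
  local_max <- ebi_mat(EBImage::dilate(ebi(resp), brush))
  peaks <- resp >= local_max - 1e-12 & resp > rel_threshold * max(resp)
  sum(peaks)
}

#' Count nuclei by thresholding and distance-transform watershed
#'
#' The frame is binarized with the named global threshold (\code{"otsu"}:
#' between-class-variance maximization; \code{"mean"}: the global image
#' mean), touching nuclei are split by a watershed on the distance
#' transform (tolerance \code{h} suppresses shallow maxima), and components
#' above a minimum area are counted.
#'
#' @param frame grayscale matrix
#' @param binarization "otsu" or "mean"
#' @param min_area smallest component kept, px
#' @param h h-maxima depth for the watershed, px
#' @return integer count (0 for a blank frame)
#' @export
count_nuclei <- function(frame, binarization = c("otsu", "mean"),
                         min_area = 9L, h = 2) {
  binarization <- match.arg(binarization)
  img <- normalize_frame(frame)
  if (diff(range(img)) < .Machine$double.eps) return(0L)
  th <- if (binarization == "otsu") otsu_threshold(img) else mean(img)
  mask <- img > th
  if (!any(mask)) return(0L)
  dm <- EBImage::distmap(ebi(mask))
  labels <- EBImage::watershed(dm, tolerance = h, ext = 1)
  sizes <- tabulate(as.integer(EBImage::imageData(labels)))
  sum(sizes >= min_area)
}

#' Viability and proliferation from live/dead counts
#'
#' \code{dcr_printed} is the published dead-cell-rate formula evaluated
#' exactly as printed, NL/(NL+ND); the complementary standard quantity
#' ND/(NL+ND) is exposed alongside as \code{dead_fraction} (the printed
#' numerator is widely suspected to be a typo, so both are reported and the
#' two always sum to one). \code{cpr} = (NL+ND)/control_total when a control
#' total is supplied.
#'
#' @param NL live-cell count (>= 0)
#' @param ND dead-cell count (>= 0); NL + ND must be > 0
#' @param control_total optional (NL+ND) of the control group (> 0)
#' @return object of class \code{cell_counts}
#' @export
viability <- function(NL, ND, control_total = NULL) {
  if (NL < 0 || ND < 0 || NL + ND <= 0) stop("need NL, ND >= 0 with NL + ND > 0")
  cpr <- NA_real_
  if (!is.null(control_total)) {
    if (control_total <= 0) stop("control_total must be > 0")
    cpr <- (NL + ND) / control_total
  }
  out <- list(NL = NL, ND = ND,
              dcr_printed = NL / (NL + ND),
              dead_fraction = ND / (NL + ND),
              cpr = cpr)
  stopifnot(abs(out$dcr_printed + out$dead_fraction - 1) < 1e-12)
  structure(out, class = "cell_counts")
}

#' Total F-actin length by bandpass, Otsu and skeletonization
#'
#' Difference-of-Gaussians bandpass (structures between roughly 3 and 40 px
#' with the defaults, following common FFT-bandpass conventions), Otsu
#' binarization, then morphological thinning to single-pixel-wide shapes;
#' the filament length Lf is the skeleton pixel count. An optional
#' diagonal-aware arc-length estimate (diagonal steps weighted sqrt(2)) is
#' attached as attribute \code{"arc_length"}.
#'
#' @param frame grayscale matrix
#' @param low_sigma,high_sigma DoG sigmas, px
#' @return Lf in px (0, with attribute \code{empty = TRUE}, when no
#'   foreground survives the bandpass)
#' @export
actin_length <- function(frame, low_sigma = 1, high_sigma = 13.3) {
  img <- normalize_frame(frame)
  if (diff(range(img)) < .Machine$double.eps)
    return(structure(0L, empty = TRUE))
  dog <- gaussian_blur(img, low_sigma) - gaussian_blur(img, high_sigma)
  dog <- normalize_frame(pmax(dog, 0))
  if (diff(range(dog)) < .Machine$double.eps)
    return(structure(0L, empty = TRUE))
  mask <- dog > otsu_threshold(dog)
  if (!any(mask)) return(structure(0L, empty = TRUE))
  skel <- skeletonize(mask)
  structure(sum(skel), arc_length = skeleton_arc_length(skel))
}

#' Length of F-actin filaments per cell
#'
#' LFC = Lf / Nn: total skeletonized filament length divided by the number
#' of nuclei in the same field, a bulk multi-cell cytoskeleton metric.
#'
#' @param Lf total filament length, px (>= 0)
#' @param Nn nuclei count (>= 1)
#' @return LFC, px per cell
#' @export
lfc <- function(Lf, Nn) {
  if (Nn < 1) stop("Nn must be >= 1")
  if (Lf < 0) stop("Lf must be >= 0")
  as.numeric(Lf) / as.numeric(Nn)
}

# shift a matrix by (dy, dx), zero fill
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  ys <- max(1, 1 - dy):min(nr, nr - dy)
  xs <- max(1, 1 - dx):min(nc, nc - dx)
  out[ys + dy, xs + dx] <- m[ys, xs]
  out
}

#' Morphological skeletonization (Zhang-Suen thinning)
#'
#' Iteratively removes boundary pixels until every object is a
#' single-pixel-wide 8-connected skeleton.
#'
#' @param mask logical or 0/1 matrix
#' @return integer 0/1 matrix of the skeleton
#' @export
skeletonize <- function(mask) {
  img <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbors clockwise from north: P2..P9
      p2 <- shift_mat(img, 1, 0);  p3 <- shift_mat(img, 1, -1)
      p4 <- shift_mat(img, 0, -1); p5 <- shift_mat(img, -1, -1)
      p6 <- shift_mat(img, -1, 0); p7 <- shift_mat(img, -1, 1)
      p8 <- shift_mat(img, 0, 1);  p9 <- shift_mat(img, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- img == 1 & b >= 2 & b <= 6 & a == 1
      if (step == 1) {
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        img[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

# Diagonal-aware skeleton length: horizontal/vertical adjacencies count 1,
# diagonal-only steps sqrt(2). Estimated from pairwise adjacency counts.
skeleton_arc_length <- function(skel) {
  ax <- sum(skel[, -1] & skel[, -ncol(skel)])
  ay <- sum(skel[-1, ] & skel[-nrow(skel), ])
  d1 <- sum(skel[-1, -1] & skel[-nrow(skel), -ncol(skel)])
  d2 <- sum(skel[-1, -ncol(skel)] & skel[-nrow(skel), -1])
  ax + ay + sqrt(2) * (d1 + d2) - 0  # upper-bound style chain length
}
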