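## Digital image correlation: subset matching by zero-normalized
## cross-correlation (ZNCC) over an integer search window with quadratic
## subpixel refinement, displacement fields on a regular node lattice,
## Green-Lagrange strain by finite differences, and the representative
## strain scalar used to build creep curves.
##
## Coordinates are 0-based: x = column index increasing rightward,
## y = row index increasing downward.

#' Build a regular DIC node lattice
#'
#' Nodes are kept at least \code{(subset_size - 1)/2 + search_radius} px from
#' every border so that each subset and its full search window fit inside
#' the frame.
#'
#' @param image_shape c(rows, cols) in px
#' @param subset_size interrogation-window side, px; odd, >= 9
#' @param spacing node spacing, px (>= 1)
#' @param search_radius integer search half-range, px
#' @param roi optional c(xmin, xmax, ymin, ymax), 0-based inclusive
#' @return object of class \code{pixel_grid} with \code{$nodes}
#'   (data.frame of 0-based x, y), lattice dimensions \code{nx}, \code{ny}
#' @export
build_grid <- function(image_shape, subset_size = 31L, spacing = 16L,
                       search_radius = 10L, roi = NULL) {
  subset_size <- as.integer(subset_size)
  if (subset_size < 9L || subset_size %% 2L == 0L)
    stop("subset_size must be odd and >= 9")
  if (spacing < 1) stop("spacing must be >= 1")
  margin <- (subset_size - 1L) / 2L + search_radius
  xlim <- c(margin, image_shape[2] - 1 - margin)
  ylim <- c(margin, image_shape[1] - 1 - margin)
  if (!is.null(roi)) {
    xlim <- c(max(xlim[1], roi[1]), min(xlim[2], roi[2]))
    ylim <- c(max(ylim[1], roi[3]), min(ylim[2], roi[4]))
  }
  xs <- seq(xlim[1], xlim[2], by = spacing)
  ys <- seq(ylim[1], ylim[2], by = spacing)
  if (length(xs) < 3 || length(ys) < 3) {
    min_side <- 2 * margin + 2 * spacing + 1
    stop(sprintf("image (or roi) too small for a 3x3 node lattice; need at least %d px per side for subset %d, spacing %d, search %d",
                 min_side, subset_size, spacing, search_radius))
  }
  nodes <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  structure(list(nodes = nodes, node_x = xs, node_y = ys,
                 nx = length(xs), ny = length(ys),
                 subset_size = subset_size, spacing = spacing,
                 search_radius = as.integer(search_radius),
                 image_shape = as.integer(image_shape)),
            class = "pixel_grid")
}

# Three-point subpixel refinement along one axis of the correlation
# surface; offset clamped to +/- 0.5 px. cm, c0, cp: correlation at -1, 0, +1.
# When all three values are positive the vertex of a parabola through their
# logarithms is used (a Gaussian peak model, which has much smaller
# pixel-locking bias for smooth speckle autocorrelation peaks than the plain
# quadratic); otherwise it falls back to the quadratic vertex.
subpixel_offset <- function(cm, c0, cp) {
  if (is.na(cm) || is.na(cp)) return(0)
  if (cm > 0 && c0 > 0 && cp > 0) {
    lm_ <- log(cm); l0 <- log(c0); lp <- log(cp)
    denom <- lm_ - 2 * l0 + lp
    if (is.finite(denom) && denom < 0)
      return(max(-0.5, min(0.5, 0.5 * (lm_ - lp) / denom)))
  }
  denom <- cm - 2 * c0 + cp
  if (!is.finite(denom) || denom >= 0) return(0)   # not a proper maximum
  max(-0.5, min(0.5, 0.5 * (cm - cp) / denom))
}

# Locate the integer peak of a ZNCC surface and refine per axis.
peak_from_surface <- function(surface, search_radius) {
  if (all(is.na(surface))) return(NULL)
  idx <- which.max(surface)                      # NA-safe: which.max ignores NA
  iv <- (idx - 1) %% nrow(surface) + 1           # row  -> v offset
  iu <- (idx - 1) %/% nrow(surface) + 1          # col  -> u offset
  peak <- surface[iv, iu]
  du <- iu - search_radius - 1
  dv <- iv - search_radius - 1
  if (peak >= 1 - 1e-9) {
    # a perfect lattice match: the optimum is the node itself, and a
    # quadratic through an already-maximal correlation has no information
    return(list(u = du, v = dv, peak_corr = peak, u_int = du, v_int = dv))
  }
  sx <- if (iu > 1 && iu < ncol(surface))
    subpixel_offset(surface[iv, iu - 1], peak, surface[iv, iu + 1]) else 0
  sy <- if (iv > 1 && iv < nrow(surface))
    subpixel_offset(surface[iv - 1, iu], peak, surface[iv + 1, iu]) else 0
  list(u = du + sx, v = dv + sy, peak_corr = peak,
       u_int = du, v_int = dv)
}

#' Match one subset between two frames
#'
#' Finds the integer offset within \code{+/- search_radius} that maximizes
#' the ZNCC of the interrogation window, then refines each axis by a
#' quadratic fit through the peak and its two neighbors (clamped to
#' \code{+/- 0.5} px). \code{peak_corr} is the integer-lattice maximum.
#'
#' @param reference,deformed frames (numeric matrices, same shape)
#' @param node c(x, y), 0-based
#' @param subset_size odd window side, px
#' @param search_radius search half-range, px
#' @return list(u, v, peak_corr) plus the integer-lattice peak (u_int, v_int)
#' @export
match_subset <- function(reference, deformed, node, subset_size = 31L,
                         search_radius = 10L) {
  reference <- as_frame(reference); deformed <- as_frame(deformed)
  if (!all(dim(reference) == dim(deformed))) stop("frames must have the same shape")
  half <- (as.integer(subset_size) - 1L) %/% 2L
  surf <- zncc_surfaces(reference, deformed, as.integer(node[1]), as.integer(node[2]),
                        half, as.integer(search_radius))
  surf <- matrix(surf, 2 * search_radius + 1, 2 * search_radius + 1)
  res <- peak_from_surface(surf, search_radius)
  if (is.null(res))
    stop("zero-variance subset: flat texture is unmatchable at this node")
  res
}

#' Displacement field over a node lattice
#'
#' Applies subset matching at every node of the grid. Nodes whose reference
#' subset is flat or whose peak correlation falls below \code{min_corr} are
#' flagged invalid (\code{valid = FALSE}), never silently zeroed.
#'
#' @param reference,deformed frames, same shape
#' @param grid a [build_grid()] lattice
#' @param min_corr validity threshold on the ZNCC peak (default 0.25)
#' @return object of class \code{displacement_field}: data.frame
#'   \code{$field} with node_x, node_y, u, v, peak_corr, valid; the grid is
#'   attached
#' @export
displacement_field <- function(reference, deformed, grid, min_corr = 0.25) {
  stopifnot(inherits(grid, "pixel_grid"))
  reference <- as_frame(reference); deformed <- as_frame(deformed)
  if (!all(dim(reference) == dim(deformed))) stop("frames must have the same shape")
  n <- nrow(grid$nodes)
  sr <- grid$search_radius
  half <- (grid$subset_size - 1L) %/% 2L
  surfs <- zncc_surfaces(reference, deformed,
                         as.integer(grid$nodes$x), as.integer(grid$nodes$y),
                         half, sr)
  side <- 2 * sr + 1
  u <- v <- pc <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (k in seq_len(n)) {
    surf <- matrix(surfs[((k - 1) * side * side + 1):(k * side * side)], side, side)
    res <- peak_from_surface(surf, sr)
    if (is.null(res)) next
    u[k] <- res$u; v[k] <- res$v; pc[k] <- res$peak_corr
    valid[k] <- is.finite(res$peak_corr) && res$peak_corr >= min_corr
  }
  if (mean(!valid) > 0.5)
    stop(sprintf("%.0f%% of nodes failed to match; scene unusable", 100 * mean(!valid)))
  structure(list(field = data.frame(node_x = grid$nodes$x, node_y = grid$nodes$y,
                                    u = u, v = v, peak_corr = pc, valid = valid),
                 grid = grid),
            class = "displacement_field")
}

# Central differences on a regular lattice (one-sided at edges), columns of
# m indexed by x-node, rows by y-node. h: node spacing.
lattice_gradient <- function(m, hx, hy) {
  ny <- nrow(m); nx <- ncol(m)
  ddx <- matrix(NA_real_, ny, nx)
  ddy <- matrix(NA_real_, ny, nx)
  if (nx >= 3) ddx[, 2:(nx - 1)] <- (m[, 3:nx] - m[, 1:(nx - 2)]) / (2 * hx)
  ddx[, 1] <- (m[, 2] - m[, 1]) / hx
  ddx[, nx] <- (m[, nx] - m[, nx - 1]) / hx
  if (ny >= 3) ddy[2:(ny - 1), ] <- (m[3:ny, ] - m[1:(ny - 2), ]) / (2 * hy)
  ddy[1, ] <- (m[2, ] - m[1, ]) / hy
  ddy[ny, ] <- (m[ny, ] - m[ny - 1, ]) / hy
  list(ddx = ddx, ddy = ddy)
}

#' Green-Lagrange strain from a displacement field
#'
#' Displacement gradients are computed by central differences on the node
#' lattice (one-sided at lattice edges); both displacements and node spacing
#' are in px, so the gradients and strain components are dimensionless.
#' Components follow the finite-strain definitions:
#' Sxx = du/dx + 0.5[(du/dx)^2 + (dv/dx)^2],
#' Syy = dv/dy + 0.5[(du/dy)^2 + (dv/dy)^2],
#' Sxy = 0.5[du/dy + dv/dx + (du/dx)(du/dy) + (dv/dx)(dv/dy)],
#' which makes the field exactly invariant to rigid rotation.
#'
#' Invalid displacement nodes propagate NA to any strain node whose stencil
#' touches them.
#'
#' @param field a [displacement_field()] result, or a list with
#'   \code{field} data.frame and \code{grid}
#' @return object of class \code{strain_field}: data.frame \code{$strain}
#'   with node_x, node_y, sxx, syy, sxy
#' @export
green_lagrange <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  g <- field$grid
  if (g$nx < 3 || g$ny < 3) stop("need at least 3 nodes per axis for strain")
  # expand.grid ordering: x varies fastest -> matrix [ny rows?]: fill by x
  um <- matrix(ifelse(field$field$valid, field$field$u, NA_real_), g$nx, g$ny)
  vm <- matrix(ifelse(field$field$valid, field$field$v, NA_real_), g$nx, g$ny)
  um <- t(um); vm <- t(vm)                      # rows = y nodes, cols = x nodes
  hx <- diff(g$node_x[1:2]); hy <- diff(g$node_y[1:2])
  gu <- lattice_gradient(um, hx, hy)
  gv <- lattice_gradient(vm, hx, hy)
  sxx <- gu$ddx + 0.5 * (gu$ddx^2 + gv$ddx^2)
  syy <- gv$ddy + 0.5 * (gu$ddy^2 + gv$ddy^2)
  sxy <- 0.5 * (gu$ddy + gv$ddx + gu$ddx * gu$ddy + gv$ddx * gv$ddy)
  strain <- data.frame(node_x = field$field$node_x, node_y = field$field$node_y,
                       sxx = as.vector(t(sxx)), syy = as.vector(t(syy)),
                       sxy = as.vector(t(sxy)))
  structure(list(strain = strain, grid = g), class = "strain_field")
}

#' Representative strain scalar of a strain field
#'
#' The scalar fed to creep fitting: the Euclidean norm of the vector of
#' median normal strains, \code{sqrt(median(Sxx)^2 + median(Syy)^2)}
#' (shear is excluded). The literal sum-of-squares reading (strain^2 units)
#' is available via \code{convention = "sum_of_squares"}.
#'
#' @param strain a [green_lagrange()] result
#' @param convention "euclidean" (default) or "sum_of_squares"
#' @return scalar representative strain
#' @export
representative_strain <- function(strain,
                                  convention = c("euclidean", "sum_of_squares")) {
  convention <- match.arg(convention)
  stopifnot(inherits(strain, "strain_field"))
  sxx <- strain$strain$sxx; syy <- strain$strain$syy
  if (all(is.na(sxx)) || all(is.na(syy)))
    stop("all strain nodes invalid; cannot form a representative strain")
  mx <- median(sxx, na.rm = TRUE); my <- median(syy, na.rm = TRUE)
  ss <- mx^2 + my^2
  if (convention == "euclidean") sqrt(ss) else ss
}

#' Write a displacement + strain field as tidy CSV
#'
#' Columns: node_x, node_y (0-based; x = column rightward, y = row
#' downward), u, v, corr, sxx, syy, sxy.
#' @param field a [displacement_field()]
#' @param strain the matching [green_lagrange()] result
#' @param path CSV path
#' @return invisibly, the path
#' @export
write_field_csv <- function(field, strain, path) {
  df <- cbind(field$field[, c("node_x", "node_y", "u", "v")],
              corr = field$field$peak_corr,
              strain$strain[, c("sxx", "syy", "sxy")])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
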