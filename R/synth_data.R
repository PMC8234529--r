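## Seeded synthetic-data generators. Every generator takes an explicit
## integer seed (never defaulted from the clock) and returns its ground
## truth alongside the rendered frames, so each downstream stage can be
## validated against known answers. Spot appearance follows phase-contrast
## microsphere images: dark discs on a bright background with blurred edges.

SPECKLE_BG <- 0.85
SPECKLE_FG <- 0.12

#' Specification of a speckle image pair
#'
#' @param image_shape c(rows, cols) in px
#' @param n_spots number of microsphere-like spots (>= 10)
#' @param spot_radius spot radius, px (>= 1)
#' @param displacement one of [trans_displacement()], [strain_displacement()]
#'   describing the prescribed forward map
#' @param noise_sd additive Gaussian intensity noise, as a fraction of the
#'   full intensity range (>= 0)
#' @param seed integer RNG seed (mandatory)
#' @return object of class \code{speckle_spec}
#' @export
speckle_spec <- function(image_shape = c(200L, 200L), n_spots = 120L,
                         spot_radius = 3, displacement = trans_displacement(0, 0),
                         noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is a mandatory field")
  stopifnot(length(image_shape) == 2, all(image_shape >= 32))
  if (n_spots < 10) stop("n_spots must be >= 10")
  if (spot_radius < 1) stop("spot_radius must be >= 1 px")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(image_shape = as.integer(image_shape), n_spots = as.integer(n_spots),
                 spot_radius = spot_radius, displacement = displacement,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "speckle_spec")
}

#' Prescribed displacement maps
#'
#' \code{trans_displacement} is a uniform translation; \code{strain_displacement}
#' applies a homogeneous (symmetric) displacement-gradient tensor as an affine
#' map about the frame center, so u = exx (x - xc) + exy (y - yc), etc.
#'
#' @param tx,ty translation, px
#' @param exx,eyy,exy homogeneous displacement-gradient components
#' @return a displacement description used by [gen_speckle_pair()]
#' @export
trans_displacement <- function(tx, ty) {
  structure(list(type = "translation", tx = tx, ty = ty), class = "displacement_spec")
}

#' @rdname trans_displacement
#' @export
strain_displacement <- function(exx = 0, eyy = 0, exy = 0) {
  structure(list(type = "strain", exx = exx, eyy = eyy, exy = exy),
            class = "displacement_spec")
}

# Forward map x -> x + u(x) and its exact inverse, as vectorized closures.
displacement_maps <- function(disp, shape) {
  cx <- (shape[2] - 1) / 2; cy <- (shape[1] - 1) / 2
  if (disp$type == "translation") {
    list(
      u = function(x, y) list(u = rep(disp$tx, length(x)), v = rep(disp$ty, length(x))),
      backward = function(x, y) list(x = x - disp$tx, y = y - disp$ty)
    )
  } else if (disp$type == "strain") {
    A <- matrix(c(1 + disp$exx, disp$exy, disp$exy, 1 + disp$eyy), 2, 2)
    if (abs(det(A)) < 1e-8) stop("degenerate strain map")
    Ainv <- solve(A)
    list(
      u = function(x, y) list(u = disp$exx * (x - cx) + disp$exy * (y - cy),
                              v = disp$exy * (x - cx) + disp$eyy * (y - cy)),
      backward = function(x, y) {
        dx <- x - cx; dy <- y - cy
        list(x = cx + Ainv[1, 1] * dx + Ainv[1, 2] * dy,
             y = cy + Ainv[2, 1] * dx + Ainv[2, 2] * dy)
      }
    )
  } else stop("unknown displacement type: ", disp$type)
}

render_speckles <- function(shape, centers, radius) {
  canvas <- matrix(SPECKLE_BG, shape[1], shape[2])
  canvas <- draw_discs(canvas, centers, radius, SPECKLE_FG, mode = "min")
  gaussian_blur(canvas, 0.8)
}

#' Generate a reference/deformed speckle image pair with known displacement
#'
#' The deformed frame is the reference resampled through the prescribed
#' forward map (by exact inverse mapping with bicubic interpolation) plus
#' additive Gaussian noise. The analytic ground-truth displacement is
#' returned both as a vectorized function and, when a [build_grid()] result
#' is supplied, evaluated at its nodes.
#'
#' @param spec a [speckle_spec()]
#' @param grid optional \code{pixel_grid}; ground truth is evaluated at its nodes
#' @return list with \code{reference}, \code{deformed} (matrices),
#'   \code{truth_fun(x, y)}, and (if \code{grid} given) \code{truth}
#'   data.frame of per-node (u, v)
#' @export
gen_speckle_pair <- function(spec, grid = NULL) {
  stopifnot(inherits(spec, "speckle_spec"))
  sh <- spec$image_shape
  maps <- displacement_maps(spec$displacement, sh)
  with_seed(spec$seed, {
    centers <- sample_centers(spec$n_spots, sh,
                              min_dist = 2.2 * spec$spot_radius,
                              margin = spec$spot_radius + 1)
    reference <- render_speckles(sh, centers, spec$spot_radius)
    # reject scenes the prescribed motion pushes apart
    d <- maps$u(centers[, 1], centers[, 2])
    nx <- centers[, 1] + d$u; ny <- centers[, 2] + d$v
    out_frac <- mean(nx < 0 | nx > sh[2] - 1 | ny < 0 | ny > sh[1] - 1)
    if (out_frac > 0.25)
      stop(sprintf("displacement pushes %.0f%% of spots out of frame (unmatchable scene)",
                   100 * out_frac))
    deformed <- warp_backward(reference, maps$backward)
    if (spec$noise_sd > 0) {
      deformed <- pmin(pmax(deformed + matrix(rnorm(prod(sh), 0, spec$noise_sd),
                                              sh[1], sh[2]), 0), 1)
    }
    out <- list(reference = reference, deformed = deformed, truth_fun = maps$u)
    if (!is.null(grid)) {
      tv <- maps$u(grid$nodes$x, grid$nodes$y)
      out$truth <- data.frame(node_x = grid$nodes$x, node_y = grid$nodes$y,
                              u = tv$u, v = tv$v)
    }
    out
  })
}

#' Generate a time-lapse speckle sequence following Kelvin-Voigt creep
#'
#' Frame k is the reference warped by a horizontal homogeneous stretch whose
#' exact Green-Lagrange strain equals the creep strain gamma(t_k) from
#' [kv_strain()] (the stretch amplitude is sqrt(1 + 2 gamma) - 1, so the
#' recorded ground truth is exact in strain units, not merely to first
#' order). The first frame is taken under load: the instantaneous elastic
#' response has already occurred, as in a creep test where imaging starts at
#' load application, so image correlation against frame 0 measures strain
#' growth relative to t = 0.
#'
#' @param kv [kv_params()] ground-truth model parameters
#' @param duration total time, min
#' @param dt frame interval, min (duration/dt must give >= 5 frames)
#' @param spec a [speckle_spec()]; its displacement entry is ignored
#' @return list with \code{frames} (list of matrices), \code{times} (min),
#'   \code{gamma_true} (creep strain at each time), \code{kv}, and
#'   \code{tau_true}
#' @export
gen_creep_sequence <- function(kv, duration = 30, dt = 1, spec) {
  stopifnot(inherits(kv, "kv_params"), inherits(spec, "speckle_spec"))
  times <- seq(0, duration, by = dt)
  if (length(times) < 5) stop("duration/dt must give at least 5 frames")
  gamma <- kv_strain(times, kv)
  sh <- spec$image_shape
  cx <- (sh[2] - 1) / 2
  with_seed(spec$seed, {
    centers <- sample_centers(spec$n_spots, sh,
                              min_dist = 2.2 * spec$spot_radius,
                              margin = spec$spot_radius + 1)
    reference <- render_speckles(sh, centers, spec$spot_radius)
    frames <- vector("list", length(times))
    for (k in seq_along(times)) {
      stretch <- sqrt(1 + 2 * gamma[k]) - 1       # exact GL strain = gamma[k]
      frames[[k]] <- warp_backward(reference, function(x, y) {
        list(x = cx + (x - cx) / (1 + stretch), y = y)
      })
      if (spec$noise_sd > 0) {
        frames[[k]] <- pmin(pmax(frames[[k]] +
          matrix(rnorm(prod(sh), 0, spec$noise_sd), sh[1], sh[2]), 0), 1)
      }
    }
    list(frames = frames, times = times, gamma_true = gamma,
         kv = kv, tau_true = delay_time(kv$E2, kv$eta))
  })
}

#' Specification and generator for an expanding colony image series
#'
#' Each frame holds one filled quasi-circular bright region of equivalent
#' radius r0 + growth_rate * t, with a smooth periodic boundary perturbation
#' of amplitude \code{boundary_noise}. Ground-truth areas are the rasterized
#' pixel counts actually drawn.
#'
#' @param r0 initial equivalent radius, px (> 0)
#' @param growth_rate radial growth, px/h
#' @param frame_times acquisition times, h; strictly increasing, first = 0
#' @param boundary_noise boundary perturbation amplitude, px
#' @param image_shape c(rows, cols)
#' @param seed integer RNG seed
#' @return object of class \code{colony_spec}
#' @export
colony_spec <- function(r0, growth_rate, frame_times = c(0, 8, 16, 24),
                        boundary_noise = 0, image_shape = c(256L, 256L), seed) {
  if (missing(seed)) stop("seed is a mandatory field")
  if (r0 <= 0) stop("r0 must be > 0")
  if (frame_times[1] != 0 || any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing with first = 0")
  structure(list(r0 = r0, growth_rate = growth_rate, frame_times = frame_times,
                 boundary_noise = boundary_noise,
                 image_shape = as.integer(image_shape), seed = as.integer(seed)),
            class = "colony_spec")
}

#' @rdname colony_spec
#' @param spec a \code{colony_spec}
#' @return for \code{gen_colony_series}: list with \code{frames},
#'   \code{times} (h), \code{areas_true} (px^2, rasterized), and
#'   \code{radius_true}
#' @export
gen_colony_series <- function(spec) {
  stopifnot(inherits(spec, "colony_spec"))
  sh <- spec$image_shape
  radii <- spec$r0 + spec$growth_rate * spec$frame_times
  if (any(radii + spec$boundary_noise >= min(sh) / 2 - 2))
    stop("colony radius exceeds frame half-size; enlarge image_shape")
  if (any(radii <= 0)) stop("colony radius must stay positive")
  cx <- (sh[2] - 1) / 2; cy <- (sh[1] - 1) / 2
  g <- pixel_grid_xy(sh)
  theta <- atan2(as.vector(g$y) - cy, as.vector(g$x) - cx)
  dist <- sqrt((as.vector(g$x) - cx)^2 + (as.vector(g$y) - cy)^2)
  with_seed(spec$seed, {
    # smooth periodic boundary wobble, shared shape across frames
    harm <- 2:5
    amp <- rnorm(length(harm)); phase <- runif(length(harm), 0, 2 * pi)
    amp <- amp / sqrt(sum(amp^2) / 2 + 1e-12)     # unit-RMS perturbation
    wobble <- numeric(length(theta))
    for (i in seq_along(harm))
      wobble <- wobble + amp[i] * cos(harm[i] * theta + phase[i])
    frames <- vector("list", length(radii))
    areas <- numeric(length(radii))
    for (k in seq_along(radii)) {
      rb <- radii[k] + spec$boundary_noise * wobble
      inside <- dist <= rb
      areas[k] <- sum(inside)
      img <- matrix(0.08, sh[1], sh[2])
      img[matrix(inside, sh[1], sh[2])] <- 0.75
      img <- gaussian_blur(img, 1)
      frames[[k]] <- img
    }
    list(frames = frames, times = spec$frame_times, areas_true = areas,
         radius_true = radii)
  })
}

#' Specification and generator for a live/dead fluorescence pair
#'
#' Emulates calcein-AM / propidium-iodide double staining: live cells appear
#' as soft bright blobs in the green channel, dead cells in the red channel.
#' The dead count is \code{round(n_cells * dead_fraction)}.
#'
#' @param n_cells total cell count
#' @param dead_fraction fraction of dead cells in [0, 1]
#' @param cell_radius blob radius, px
#' @param overlap_allowance how much closer than 2*cell_radius two centers
#'   may sit, px
#' @param image_shape c(rows, cols)
#' @param seed integer RNG seed
#' @return object of class \code{livedead_spec}
#' @export
livedead_spec <- function(n_cells, dead_fraction, cell_radius = 6,
                          overlap_allowance = 0, image_shape = c(256L, 256L), seed) {
  if (missing(seed)) stop("seed is a mandatory field")
  if (dead_fraction < 0 || dead_fraction > 1) stop("dead_fraction must be in [0, 1]")
  if (n_cells < 1) stop("n_cells must be >= 1")
  structure(list(n_cells = as.integer(n_cells), dead_fraction = dead_fraction,
                 cell_radius = cell_radius, overlap_allowance = overlap_allowance,
                 image_shape = as.integer(image_shape), seed = as.integer(seed)),
            class = "livedead_spec")
}

#' @rdname livedead_spec
#' @param spec a \code{livedead_spec}
#' @return for \code{gen_livedead_pair}: list with \code{green}, \code{red}
#'   frames and ground-truth counts \code{NL}, \code{ND}
#' @export
gen_livedead_pair <- function(spec) {
  stopifnot(inherits(spec, "livedead_spec"))
  sh <- spec$image_shape
  nd <- round(spec$n_cells * spec$dead_fraction)
  nl <- spec$n_cells - nd
  with_seed(spec$seed, {
    centers <- sample_centers(spec$n_cells, sh,
                              min_dist = 2 * spec$cell_radius - spec$overlap_allowance,
                              margin = spec$cell_radius + 2)
    idx_dead <- if (nd > 0) sample(spec$n_cells, nd) else integer(0)
    green <- matrix(0.02, sh[1], sh[2])
    red <- matrix(0.02, sh[1], sh[2])
    sig <- spec$cell_radius / 2
    if (nl > 0)
      green <- draw_gaussian_blobs(green, centers[setdiff(seq_len(spec$n_cells), idx_dead), , drop = FALSE], sig)
    if (nd > 0)
      red <- draw_gaussian_blobs(red, centers[idx_dead, , drop = FALSE], sig)
    list(green = green, red = red, NL = nl, ND = nd)
  })
}

#' Specification and generator for an F-actin / nuclei scene
#'
#' Filaments are smooth random curves drawn in unit-length steps with a
#' slowly drifting heading, stroked at the given thickness; nuclei are soft
#' blobs in a separate channel. Ground-truth filament length \code{Lf} is
#' reported as the pixel count of the rasterized 8-connected centerline,
#' the same chain-code metric the skeleton estimator reports (the continuous
#' arc length is returned alongside as \code{arc_length}).
#'
#' @param n_filaments number of filaments
#' @param total_length total arc length across filaments, px (> 0)
#' @param thickness stroke thickness, px
#' @param n_nuclei nuclei count (>= 1)
#' @param image_shape c(rows, cols)
#' @param seed integer RNG seed
#' @return object of class \code{filament_spec}
#' @export
filament_spec <- function(n_filaments, total_length, thickness = 3,
                          n_nuclei = 10, image_shape = c(256L, 256L), seed) {
  if (missing(seed)) stop("seed is a mandatory field")
  if (total_length <= 0) stop("total_length must be > 0")
  if (n_nuclei < 1) stop("n_nuclei must be >= 1")
  if (n_filaments < 1) stop("n_filaments must be >= 1")
  structure(list(n_filaments = as.integer(n_filaments), total_length = total_length,
                 thickness = thickness, n_nuclei = as.integer(n_nuclei),
                 image_shape = as.integer(image_shape), seed = as.integer(seed)),
            class = "filament_spec")
}

# Sample one smooth random curve of the requested arc length; unit steps,
# heading random walk, reflected at a border margin. Returns [n, 2] points.
random_curve <- function(length_px, shape, margin, turn_sd = 0.12) {
  n <- max(2L, ceiling(length_px) + 1L)
  pts <- matrix(0, n, 2)
  pts[1, ] <- c(runif(1, margin, shape[2] - 1 - margin),
                runif(1, margin, shape[1] - 1 - margin))
  heading <- runif(1, 0, 2 * pi)
  for (i in 2:n) {
    heading <- heading + rnorm(1, 0, turn_sd)
    step <- c(cos(heading), sin(heading))
    nxt <- pts[i - 1, ] + step
    if (nxt[1] < margin || nxt[1] > shape[2] - 1 - margin) {
      heading <- pi - heading; step <- c(cos(heading), sin(heading))
      nxt <- pts[i - 1, ] + step
    }
    if (nxt[2] < margin || nxt[2] > shape[1] - 1 - margin) {
      heading <- -heading; step <- c(cos(heading), sin(heading))
      nxt <- pts[i - 1, ] + step
    }
    pts[i, ] <- pmin(pmax(nxt, margin), c(shape[2], shape[1]) - 1 - margin)
  }
  pts
}

# Rasterize polyline vertices to the unique 0-based pixel set of the
# centerline (unit-length steps make consecutive pixels 8-connected).
rasterize_centerline <- function(pts) {
  px <- unique(cbind(round(pts[, 1]), round(pts[, 2])))
  px
}

#' @rdname filament_spec
#' @param spec a \code{filament_spec}
#' @return for \code{gen_filament_scene}: list with \code{actin},
#'   \code{nuclei} frames, \code{Lf} (centerline pixel count),
#'   \code{arc_length}, and \code{Nn}
#' @export
gen_filament_scene <- function(spec) {
  stopifnot(inherits(spec, "filament_spec"))
  sh <- spec$image_shape
  margin <- spec$thickness + 3
  per_fil <- spec$total_length / spec$n_filaments
  if (per_fil > 4 * (min(sh) - 2 * margin))
    stop("total_length unrealizable in frame; reduce length or enlarge image_shape")
  with_seed(spec$seed, {
    actin <- matrix(0.03, sh[1], sh[2])
    lf_pixels <- 0
    for (f in seq_len(spec$n_filaments)) {
      pts <- random_curve(per_fil, sh, margin)
      cl <- rasterize_centerline(pts)
      lf_pixels <- lf_pixels + nrow(cl)
      actin <- draw_discs(actin, pts, spec$thickness / 2, 0.85, mode = "max")
    }
    actin <- gaussian_blur(actin, 0.6)
    nuc_centers <- sample_centers(spec$n_nuclei, sh, min_dist = 14, margin = 8)
    nuclei <- draw_gaussian_blobs(matrix(0.02, sh[1], sh[2]), nuc_centers, sigma = 3.5)
    list(actin = actin, nuclei = nuclei, Lf = lf_pixels,
         arc_length = spec$total_length, Nn = spec$n_nuclei)
  })
}

#' Specification and generator for a synthetic Ct table
#'
#' Emulates RT-qPCR output for one target and one reference gene across
#' groups with prescribed true fold changes relative to the calibrator
#' group. Per technical replicate, Ct(reference) = ct_reference_mean + noise
#' and Ct(target) = ct_reference_mean + calibrator_delta_ct - log2(fold) +
#' noise, so with zero noise the 2^-ddCt pipeline recovers the fold changes
#' exactly.
#'
#' @param group_fold_changes named numeric vector, group -> true fold change
#'   (> 0); the calibrator group must be present with fold 1
#' @param calibrator name of the calibrator group (default: first group)
#' @param ct_reference_mean mean reference-gene Ct, cycles
#' @param calibrator_delta_ct true target-minus-reference Ct offset in the
#'   calibrator, cycles
#' @param ct_noise_sd per-well Ct noise, cycles
#' @param replicates biological replicates per group (>= 1)
#' @param tech_replicates technical replicates per well
#' @param target,reference gene labels
#' @param seed integer RNG seed
#' @return object of class \code{ct_spec}
#' @export
ct_spec <- function(group_fold_changes, calibrator = names(group_fold_changes)[1],
                    ct_reference_mean = 18, calibrator_delta_ct = 5,
                    ct_noise_sd = 0, replicates = 3L, tech_replicates = 3L,
                    target = "Mmp14", reference = "Gapdh", seed) {
  if (missing(seed)) stop("seed is a mandatory field")
  if (is.null(names(group_fold_changes)) || any(names(group_fold_changes) == ""))
    stop("group_fold_changes must be a named vector")
  if (any(group_fold_changes <= 0)) stop("fold changes must be > 0")
  if (replicates < 1) stop("replicates must be >= 1")
  if (!calibrator %in% names(group_fold_changes))
    stop("calibrator group missing from group_fold_changes")
  if (abs(group_fold_changes[[calibrator]] - 1) > 1e-12)
    stop("the calibrator group must have fold change 1")
  structure(list(group_fold_changes = group_fold_changes, calibrator = calibrator,
                 ct_reference_mean = ct_reference_mean,
                 calibrator_delta_ct = calibrator_delta_ct,
                 ct_noise_sd = ct_noise_sd, replicates = as.integer(replicates),
                 tech_replicates = as.integer(tech_replicates),
                 target = target, reference = reference, seed = as.integer(seed)),
            class = "ct_spec")
}

#' @rdname ct_spec
#' @param spec a \code{ct_spec}
#' @return for \code{gen_ct_table}: data.frame with columns group, sample,
#'   gene, ct (one row per technical replicate)
#' @export
gen_ct_table <- function(spec) {
  stopifnot(inherits(spec, "ct_spec"))
  with_seed(spec$seed, {
    rows <- list()
    for (g in names(spec$group_fold_changes)) {
      fold <- spec$group_fold_changes[[g]]
      for (b in seq_len(spec$replicates)) {
        samp <- sprintf("%s_rep%d", g, b)
        for (r in seq_len(spec$tech_replicates)) {
          ct_ref <- spec$ct_reference_mean + rnorm(1, 0, spec$ct_noise_sd)
          ct_tgt <- spec$ct_reference_mean + spec$calibrator_delta_ct -
            log2(fold) + rnorm(1, 0, spec$ct_noise_sd)
          rows[[length(rows) + 1]] <- data.frame(
            group = g, sample = samp,
            gene = c(spec$reference, spec$target), ct = c(ct_ref, ct_tgt))
        }
      }
    }
    validate_ct_table(do.call(rbind, rows))
  })
}
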