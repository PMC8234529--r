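## End-to-end orchestration: a single structured configuration drives every
## stage; outputs are tidy CSV tables with a JSON run manifest carrying the
## seed, config hash and package version so tables from different runs are
## distinguishable.

#' Default run configuration
#'
#' Group labels follow the intermittent-compression design: an uncompressed
#' control plus cyclic-compression groups T4 (2 h on / 2 h off) and
#' T8 (4 h on / 4 h off). All tunable parameters consumed by any stage live
#' here; unknown keys are rejected at validation.
#'
#' @return nested list of parameters
#' @export
default_config <- function() {
  list(
    groups = c("control", "T4", "T8"),
    pixel_size_um = 1.0,
    frame_times_h = c(0, 8, 16, 24),
    dic = list(subset_size = 31L, spacing = 16L, search_radius = 10L,
               min_corr = 0.25, representative_strain_convention = "euclidean"),
    segmentation = list(median_radius = 2L, min_area = 9L, watershed_h = 2,
                        cell_diameter = 12),
    bandpass = list(low_sigma = 1, high_sigma = 13.3),
    fitting = list(sigma0 = 770, max_iter = 500L),
    stats = list(alpha = 0.05, n_draws = 1e5),
    seed = 1L
  )
}

#' Validate a run configuration against the default schema
#'
#' Unknown keys (at any level) are rejected before any computation; known
#' keys override the defaults.
#'
#' @param config partial or full configuration list
#' @return the merged, validated configuration
#' @export
validate_config <- function(config = list()) {
  template <- default_config()
  check <- function(cfg, tmpl, path = "") {
    extra <- setdiff(names(cfg), names(tmpl))
    if (length(extra))
      stop("unknown config key(s): ", paste0(path, extra, collapse = ", "))
    for (nm in names(cfg))
      if (is.list(tmpl[[nm]]) && !is.null(names(tmpl[[nm]])))
        check(cfg[[nm]], tmpl[[nm]], paste0(path, nm, "."))
  }
  check(config, template)
  modifyList(template, config)
}

# Stable hash of the configuration (md5 of its deparsed canonical form).
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(config))]), tf)
  unname(tools::md5sum(tf))
}

provenance <- function(config) {
  list(config_hash = config_hash(config),
       seed = config$seed,
       package = "melapress",
       version = as.character(utils::packageVersion("melapress")))
}

#' Run one pipeline stage on input files
#'
#' Dispatches to the corresponding analysis module and returns a tidy table
#' with provenance attributes (config hash, seed, package version).
#'
#' @param stage one of "creep", "progress", "viability", "actin", "stats"
#' @param config configuration (validated with [validate_config()])
#' @param inputs stage inputs: image files (TIFF sequences) for the image
#'   stages, a Ct CSV for "stats"; named lists are accepted where a stage
#'   needs several files
#' @return stage table (data.frame) with provenance attributes
#' @export
run_stage <- function(stage, config = list(), inputs) {
  valid <- c("creep", "progress", "viability", "actin", "stats")
  if (!stage %in% valid)
    stop("unknown stage '", stage, "'; valid stages: ", paste(valid, collapse = ", "))
  config <- validate_config(config)
  paths <- unlist(inputs, use.names = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing input file(s): ", paste(missing, collapse = ", "))
  tab <- switch(stage,
    creep = stage_creep(inputs, config),
    progress = stage_progress(inputs, config),
    viability = stage_viability(inputs, config),
    actin = stage_actin(inputs, config),
    stats = stage_stats(inputs, config))
  attr(tab, "provenance") <- provenance(config)
  tab
}

stage_creep <- function(inputs, config) {
  rows <- lapply(seq_along(inputs), function(i) {
    seq_in <- read_image_sequence(inputs[[i]])
    times <- seq_in$meta$times %||% seq(0, length(seq_in$frames) - 1)
    grid <- build_grid(dim(seq_in$frames[[1]]),
                       subset_size = config$dic$subset_size,
                       spacing = config$dic$spacing,
                       search_radius = config$dic$search_radius)
    res <- creep_analysis(seq_in$frames, times, sigma0 = config$fitting$sigma0,
                          grid = grid, min_corr = config$dic$min_corr,
                          convention = config$dic$representative_strain_convention)
    f <- res$fit
    data.frame(sample = i, file = inputs[[i]], E1 = f$params$E1, E2 = f$params$E2,
               eta = f$params$eta, tau_min = f$tau, pearson_r = f$fit_index,
               converged = f$converged)
  })
  per_sample <- do.call(rbind, rows)
  summary_row <- data.frame(sample = NA_integer_, file = "median", E1 = NA, E2 = NA,
                            eta = NA, tau_min = median(per_sample$tau_min),
                            pearson_r = median(per_sample$pearson_r), converged = NA)
  rbind(per_sample, summary_row)
}

stage_progress <- function(inputs, config) {
  rows <- lapply(names(inputs), function(group) {
    seq_in <- read_image_sequence(inputs[[group]])
    times <- seq_in$meta$times %||% config$frame_times_h
    areas <- vapply(seq_in$frames, function(f)
      segment_colony(f, median_radius = config$segmentation$median_radius)$area,
      numeric(1))
    cm <- colony_measure(times, areas, pixel_size = config$pixel_size_um)
    rate <- progression_rate(cm)
    data.frame(group = group, time_h = times, area = cm$areas, l_t = cm$l_t,
               slope = rate$slope, intercept = rate$intercept)
  })
  do.call(rbind, rows)
}

stage_viability <- function(inputs, config) {
  counts <- lapply(names(inputs), function(group) {
    pair <- inputs[[group]]
    green <- read_image_sequence(pair[["green"]])$frames[[1]]
    red <- read_image_sequence(pair[["red"]])$frames[[1]]
    NL <- count_live_cells(green, cell_diameter = config$segmentation$cell_diameter)
    ND <- count_nuclei(red, binarization = "otsu",
                       min_area = config$segmentation$min_area,
                       h = config$segmentation$watershed_h)
    list(group = group, NL = NL, ND = ND)
  })
  ctrl <- Filter(function(x) x$group == config$groups[1], counts)
  control_total <- if (length(ctrl)) ctrl[[1]]$NL + ctrl[[1]]$ND else NULL
  do.call(rbind, lapply(counts, function(x) {
    v <- viability(x$NL, x$ND, control_total = control_total)
    data.frame(group = x$group, NL = v$NL, ND = v$ND,
               dcr_printed = v$dcr_printed, dead_fraction = v$dead_fraction,
               cpr = v$cpr)
  }))
}

stage_actin <- function(inputs, config) {
  do.call(rbind, lapply(names(inputs), function(group) {
    pair <- inputs[[group]]
    actin <- read_image_sequence(pair[["actin"]])$frames[[1]]
    nuclei <- read_image_sequence(pair[["nuclei"]])$frames[[1]]
    Lf <- actin_length(actin, low_sigma = config$bandpass$low_sigma,
                       high_sigma = config$bandpass$high_sigma)
    Nn <- count_nuclei(nuclei, binarization = "mean",
                       min_area = config$segmentation$min_area,
                       h = config$segmentation$watershed_h)
    data.frame(group = group, Lf = as.numeric(Lf), Nn = Nn, LFC = lfc(Lf, Nn))
  }))
}

stage_stats <- function(inputs, config) {
  ct <- read_ct_table(unlist(inputs)[1])
  genes <- unique(ct$gene)
  reference <- if ("Gapdh" %in% genes) "Gapdh" else genes[1]
  target <- setdiff(genes, reference)[1]
  calibrator <- config$groups[1]
  fc <- fold_change(ct, target = target, reference = reference, calibrator = calibrator)
  folds <- split(fc$per_sample$fold, fc$per_sample$group)
  treat <- folds[setdiff(names(folds), calibrator)]
  dn <- dunnett_test(treat, folds[[calibrator]], alpha = config$stats$alpha,
                     n_draws = config$stats$n_draws, seed = config$seed)
  merge(fc$summary, dn$table, by = "group", all.x = TRUE)
}

#' Run a complete synthetic demonstration study
#'
#' Generates a full synthetic experiment from one seed (creep sequences,
#' colony series and live/dead, F-actin and Ct fixtures for the control, T4
#' and T8 groups), runs every analysis stage, and writes tidy CSV tables
#' plus a JSON run manifest to \code{outdir}. Re-running with the same seed
#' and configuration reproduces the tables byte for byte.
#'
#' @param seed integer seed driving every generator
#' @param outdir output directory (created if needed)
#' @param config configuration overrides (see [default_config()])
#' @return invisibly, a \code{results_bundle}: list of the tables plus
#'   provenance
#' @export
run_demo <- function(seed, outdir, config = list()) {
  config <- validate_config(config)
  config$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- provenance(config)
  log_stage <- function(fmt, ...) message(sprintf(paste0("[melapress] ", fmt), ...))

  ## creep: two replicate gel sequences, tau near the benchtop scale
  log_stage("stage creep: generating and fitting %d sequences", 2L)
  kv_true <- kv_params(sigma0 = config$fitting$sigma0, E1 = 2.2e4, E2 = 1.55e4,
                       eta = 1.55e4 * 7.74)
  seqs <- lapply(1:2, function(i)
    gen_creep_sequence(kv_true, duration = 30, dt = 2,
                       spec = speckle_spec(image_shape = c(160L, 160L), n_spots = 90L,
                                           noise_sd = 0.005, seed = seed + i)))
  creep_tab <- local({
    batch <- creep_batch(seqs, sigma0 = config$fitting$sigma0,
                         min_corr = config$dic$min_corr)
    rbind(cbind(batch$per_sample, tau_true = vapply(seqs, `[[`, numeric(1), "tau_true")),
          data.frame(sample = NA, E1 = NA, E2 = NA, eta = NA,
                     tau_min = batch$summary$median_tau_min,
                     pearson_r = batch$summary$median_pearson_r,
                     converged = NA, tau_true = NA))
  })

  ## colony progression: per-group growth rates chosen to differ
  log_stage("stage progress: colony series for %d groups", length(config$groups))
  rates <- c(control = 2.0, T4 = 1.2, T8 = 3.0)
  progress_tab <- do.call(rbind, lapply(config$groups, function(g) {
    series <- gen_colony_series(colony_spec(r0 = 30, growth_rate = rates[[g]],
                                            frame_times = config$frame_times_h,
                                            boundary_noise = 1.5,
                                            seed = seed + match(g, config$groups)))
    areas <- vapply(series$frames, function(f) segment_colony(f)$area, numeric(1))
    cm <- colony_measure(series$times, areas)
    rate <- progression_rate(cm)
    data.frame(group = g, time_h = series$times, area = cm$areas, l_t = cm$l_t,
               slope = rate$slope, intercept = rate$intercept)
  }))

  ## viability: equal low dead fractions, T8 with more cells (higher CPR)
  log_stage("stage viability: live/dead scenes")
  n_cells <- c(control = 100L, T4 = 100L, T8 = 130L)
  via_counts <- lapply(config$groups, function(g) {
    sc <- gen_livedead_pair(livedead_spec(n_cells = n_cells[[g]], dead_fraction = 0.05,
                                          image_shape = c(300L, 300L),
                                          seed = seed + 10 + match(g, config$groups)))
    NL <- count_live_cells(sc$green, cell_diameter = config$segmentation$cell_diameter)
    ND <- count_nuclei(sc$red, min_area = config$segmentation$min_area,
                       h = config$segmentation$watershed_h)
    list(group = g, NL = NL, ND = ND)
  })
  control_total <- via_counts[[1]]$NL + via_counts[[1]]$ND
  viability_tab <- do.call(rbind, lapply(via_counts, function(x) {
    v <- viability(x$NL, x$ND, control_total = control_total)
    data.frame(group = x$group, NL = v$NL, ND = v$ND, dcr_printed = v$dcr_printed,
               dead_fraction = v$dead_fraction, cpr = v$cpr)
  }))

  ## actin: total filament length differing by group
  log_stage("stage actin: filament scenes")
  lengths <- c(control = 2200, T4 = 1300, T8 = 1800)
  actin_tab <- do.call(rbind, lapply(config$groups, function(g) {
    sc <- gen_filament_scene(filament_spec(n_filaments = 10L,
                                           total_length = lengths[[g]],
                                           thickness = 3, n_nuclei = 15L,
                                           seed = seed + 20 + match(g, config$groups)))
    Lf <- actin_length(sc$actin, low_sigma = config$bandpass$low_sigma,
                       high_sigma = config$bandpass$high_sigma)
    Nn <- count_nuclei(sc$nuclei, binarization = "mean",
                       min_area = config$segmentation$min_area,
                       h = config$segmentation$watershed_h)
    data.frame(group = g, Lf = as.numeric(Lf), Nn = Nn, LFC = lfc(Lf, Nn))
  }))

  ## expression: configured fold changes and Dunnett comparison
  log_stage("stage stats: Ct table, fold changes and Dunnett test")
  ct <- gen_ct_table(ct_spec(group_fold_changes = c(control = 1, T4 = 0.5, T8 = 2),
                             ct_noise_sd = 0.15, replicates = 3L,
                             seed = seed + 30))
  fc <- fold_change(ct, target = "Mmp14", reference = "Gapdh", calibrator = "control")
  folds <- split(fc$per_sample$fold, fc$per_sample$group)
  dn <- dunnett_test(folds[c("T4", "T8")], folds$control,
                     alpha = config$stats$alpha, n_draws = config$stats$n_draws,
                     seed = config$seed)
  stats_tab <- merge(fc$summary, dn$table, by = "group", all.x = TRUE)

  tables <- list(creep = creep_tab, progression = progress_tab,
                 viability = viability_tab, actin = actin_tab, stats = stats_tab)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    tab$config_hash <- prov$config_hash
    write.csv(tab, file.path(outdir, paste0(nm, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(prov, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(structure(c(tables, list(provenance = prov)), class = "results_bundle"))
}
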