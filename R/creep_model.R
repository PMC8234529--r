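## Three-element generalized Kelvin-Voigt creep model: a spring (E1) in
## series with a spring-dashpot pair (E2, eta). Under constant stress
## sigma0 the creep strain is
##   gamma(t) = sigma0/E1 + sigma0/E2 * (1 - exp(-t/tau)),  tau = eta/E2.
## Fitting is nonlinear least squares by Levenberg-Marquardt on
## log(E1), log(E2), log(eta), which keeps all parameters positive without
## constraints. Time is in minutes, stress in Pa, throughout.

#' Kelvin-Voigt model parameters
#'
#' @param sigma0 applied constant stress, Pa (> 0)
#' @param E1 elastic modulus of the series spring, Pa (> 0)
#' @param E2 elastic modulus of the Voigt spring, Pa (> 0)
#' @param eta viscosity of the dashpot, Pa.min (> 0)
#' @return object of class \code{kv_params}
#' @export
kv_params <- function(sigma0, E1, E2, eta) {
  vals <- c(sigma0 = sigma0, E1 = E1, E2 = E2, eta = eta)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all Kelvin-Voigt parameters must be strictly positive")
  structure(as.list(vals), class = "kv_params")
}

#' Creep strain of the three-element Kelvin-Voigt model
#'
#' gamma(t) = sigma0/E1 + (sigma0/E2) (1 - exp(-t/tau)) with tau = eta/E2:
#' an instantaneous elastic step followed by a delayed viscoelastic rise to
#' the asymptote sigma0/E1 + sigma0/E2.
#'
#' @param t time(s), min (>= 0); vectorized
#' @param params a [kv_params()]
#' @return strain (dimensionless), same length as t
#' @export
kv_strain <- function(t, params) {
  stopifnot(inherits(params, "kv_params"))
  if (any(t < 0)) stop("t must be >= 0")
  tau <- params$eta / params$E2
  params$sigma0 / params$E1 + (params$sigma0 / params$E2) * (1 - exp(-t / tau))
}

#' Delay time of the Voigt element
#'
#' tau = eta / E2, the exponential time constant of the delayed strain.
#'
#' @param E2 Voigt spring modulus, Pa (> 0)
#' @param eta viscosity, Pa.min (>= 0)
#' @return tau, min
#' @export
delay_time <- function(E2, eta) {
  if (E2 <= 0) stop("E2 must be > 0")
  if (eta < 0) stop("eta must be >= 0")
  eta / E2
}

#' Assemble a creep curve
#'
#' @param t sample times, min; strictly increasing, t[1] >= 0
#' @param gamma representative strain at each time
#' @return object of class \code{creep_curve}
#' @export
creep_curve <- function(t, gamma) {
  if (length(t) != length(gamma)) stop("t and gamma must have equal length")
  if (length(t) < 5) stop("a creep curve needs at least 5 samples for fitting")
  if (t[1] < 0 || any(diff(t) <= 0)) stop("t must be strictly increasing with t[1] >= 0")
  if (any(!is.finite(gamma))) stop("gamma must be finite")
  structure(list(t = as.numeric(t), gamma = as.numeric(gamma)), class = "creep_curve")
}

# Plain Pearson correlation written out explicitly (the fit index); kept
# independent of stats::cor so tests can cross-check the two.
pearson_r <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

#' Fit the Kelvin-Voigt model to a creep curve by Levenberg-Marquardt
#'
#' sigma0 is treated as known and fixed; E1, E2 and eta are estimated in
#' log-parameterization (unconstrained LM, positivity by construction).
#' Default initial values come from the data: E1 from the first positive
#' strain sample, E2 from the total delayed rise, eta from a time constant
#' of one third of the record. Non-convergence is flagged
#' (\code{converged = FALSE}), not thrown.
#'
#' @param curve a [creep_curve()]
#' @param sigma0 applied constant stress, Pa
#' @param init optional [kv_params()] initial guess (its sigma0 is ignored)
#' @param max_iter Levenberg-Marquardt iteration cap
#' @return object of class \code{kv_fit}: \code{params} ([kv_params()]),
#'   \code{tau} (= eta/E2, min), \code{fit_index} (Pearson r between
#'   observed and fitted strain), \code{fitted}, \code{converged},
#'   \code{n_iter}
#' @export
fit_kv <- function(curve, sigma0, init = NULL, max_iter = 500L) {
  stopifnot(inherits(curve, "creep_curve"))
  if (sigma0 <= 0) stop("sigma0 must be > 0")
  t <- curve$t; gamma <- curve$gamma
  if (diff(range(gamma)) < .Machine$double.eps)
    stop("degenerate curve: gamma is constant")
  if (is.null(init)) {
    g_first <- gamma[match(TRUE, gamma > 0)]
    if (is.na(g_first)) g_first <- max(gamma) / 100
    rise <- max(gamma[length(gamma)] - gamma[1], max(gamma) / 100)
    E1 <- sigma0 / g_first
    E2 <- sigma0 / rise
    eta <- E2 * (t[length(t)] / 3)
  } else {
    stopifnot(inherits(init, "kv_params"))
    E1 <- init$E1; E2 <- init$E2; eta <- init$eta
  }
  model <- function(logp, t) {
    p <- exp(logp)
    sigma0 / p[1] + (sigma0 / p[2]) * (1 - exp(-t * p[2] / p[3]))
  }
  out <- minpack.lm::nls.lm(
    par = log(c(E1, E2, eta)),
    fn = function(logp) model(logp, t) - gamma,
    control = minpack.lm::nls.lm.control(maxiter = as.integer(max_iter),
                                         gtol = 1e-10))
  p <- exp(out$par)
  fitted <- model(out$par, t)
  params <- kv_params(sigma0 = sigma0, E1 = p[1], E2 = p[2], eta = p[3])
  structure(list(params = params,
                 tau = delay_time(p[2], p[3]),
                 fit_index = pearson_r(gamma, fitted),
                 fitted = fitted, curve = curve,
                 converged = out$info %in% 1:3,
                 n_iter = out$niter,
                 message = out$message),
            class = "kv_fit")
}

#' @export
print.kv_fit <- function(x, ...) {
  cat("Three-element Kelvin-Voigt creep fit\n")
  cat(sprintf("  sigma0 (fixed): %.4g Pa\n", x$params$sigma0))
  cat(sprintf("  E1 = %.4g Pa, E2 = %.4g Pa, eta = %.4g Pa.min\n",
              x$params$E1, x$params$E2, x$params$eta))
  cat(sprintf("  delay time tau = %.4g min\n", x$tau))
  cat(sprintf("  fit index (Pearson r) = %.4f; converged: %s (%d iterations)\n",
              x$fit_index, x$converged, x$n_iter))
  invisible(x)
}

#' Creep analysis of an image sequence
#'
#' For each frame k > 0, DIC against frame 0 gives a displacement field,
#' Green-Lagrange strain, and the representative strain gamma(t_k); the
#' anchor point gamma(t_0) = 0 is included, and the resulting creep curve is
#' fitted with [fit_kv()]. When the first frame is acquired under load (the
#' usual creep-test protocol), the instantaneous elastic step is not
#' observable and the fitted E1 is a large nuisance value; tau and the fit
#' index are unaffected.
#'
#' @param frames list of frames (matrices), or a [gen_creep_sequence()] result
#' @param times frame times, min (ignored if \code{frames} carries times)
#' @param sigma0 applied constant stress, Pa
#' @param grid optional [build_grid()]; defaults to the package defaults for
#'   the frame shape
#' @param min_corr node validity threshold, as in [displacement_field()]
#' @param convention representative-strain convention
#' @return list with \code{curve} ([creep_curve()]) and \code{fit} ([fit_kv()])
#' @export
creep_analysis <- function(frames, times = NULL, sigma0,
                           grid = NULL, min_corr = 0.25,
                           convention = "euclidean") {
  if (is.list(frames) && !is.null(frames$frames)) {
    times <- times %||% frames$times
    frames <- frames$frames
  }
  if (length(frames) < 5) stop("need at least 5 frames")
  if (is.null(times) || length(times) != length(frames))
    stop("times must match the number of frames")
  if (is.null(grid)) grid <- build_grid(dim(frames[[1]]))
  gamma <- numeric(length(frames))
  for (k in seq_along(frames)[-1]) {
    df <- displacement_field(frames[[1]], frames[[k]], grid, min_corr = min_corr)
    st <- green_lagrange(df)
    gamma[k] <- representative_strain(st, convention = convention)
  }
  curve <- creep_curve(times, gamma)
  list(curve = curve, fit = fit_kv(curve, sigma0 = sigma0))
}

#' Batch creep analysis with median summaries
#'
#' Runs [creep_analysis()] on each sequence and reports per-sample fit rows
#' plus the median delay time and median fit index across samples, the
#' batch statistics used to summarize replicate creep tests.
#'
#' @param sequences list of sequences (each as accepted by [creep_analysis()])
#' @param sigma0 applied constant stress, Pa
#' @param ... passed to [creep_analysis()]
#' @return list with \code{per_sample} data.frame (E1, E2, eta, tau_min,
#'   pearson_r, converged) and \code{summary} (median tau, median r, n)
#' @export
creep_batch <- function(sequences, sigma0, ...) {
  fits <- lapply(sequences, function(s) creep_analysis(s, sigma0 = sigma0, ...)$fit)
  per_sample <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(sample = i, E1 = f$params$E1, E2 = f$params$E2,
               eta = f$params$eta, tau_min = f$tau,
               pearson_r = f$fit_index, converged = f$converged)
  }))
  list(per_sample = per_sample,
       summary = data.frame(n = nrow(per_sample),
                            median_tau_min = median(per_sample$tau_min),
                            median_pearson_r = median(per_sample$pearson_r)),
       fits = fits)
}
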