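## Relative expression by the 2^-ddCt method and Dunnett many-to-one
## comparisons. Technical replicates are averaged on the Ct (log) scale;
## the family-wise Dunnett adjustment integrates the equicorrelated
## multivariate t distribution by seeded Monte Carlo, which keeps results
## reproducible and platform-independent.

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are first averaged per (group, sample, gene) on the
#' Ct scale. Then, per biological replicate, dCt = Ct(target) -
#' Ct(reference); ddCt = dCt - mean dCt of the calibrator group; fold =
#' 2^-ddCt. The calibrator group's mean fold is 1 by construction (its mean
#' ddCt is 0).
#'
#' @param ct_table data.frame with columns group, sample, gene, ct
#' @param target target gene name (e.g. "Mmp14")
#' @param reference reference gene name (e.g. "Gapdh")
#' @param calibrator calibrator (control) group name
#' @return object of class \code{fold_change_result}: \code{per_sample}
#'   data.frame (group, sample, delta_ct, delta_delta_ct, fold) and
#'   \code{summary} (per-group mean and sd of fold)
#' @export
fold_change <- function(ct_table, target, reference, calibrator) {
  ct_table <- validate_ct_table(ct_table)
  if (!calibrator %in% ct_table$group) stop("calibrator group not in table: ", calibrator)
  for (g in c(target, reference))
    if (!g %in% ct_table$gene) stop("gene not in table: ", g)
  agg <- aggregate(ct ~ group + sample + gene, data = ct_table, FUN = mean)
  tgt <- agg[agg$gene == target, ]
  ref <- agg[agg$gene == reference, ]
  m <- merge(tgt, ref, by = c("group", "sample"), suffixes = c("_target", "_reference"),
             all.x = TRUE)
  if (anyNA(m$ct_reference)) {
    bad <- m$sample[is.na(m$ct_reference)]
    stop("missing reference gene Ct for replicate(s): ", paste(bad, collapse = ", "))
  }
  missing_tgt <- setdiff(unique(ref$sample), unique(tgt$sample))
  if (length(missing_tgt))
    stop("missing target gene Ct for replicate(s): ", paste(missing_tgt, collapse = ", "))
  m$delta_ct <- m$ct_target - m$ct_reference
  cal_mean <- mean(m$delta_ct[m$group == calibrator])
  m$delta_delta_ct <- m$delta_ct - cal_mean
  m$fold <- 2^(-m$delta_delta_ct)
  per_sample <- m[order(m$group, m$sample),
                  c("group", "sample", "delta_ct", "delta_delta_ct", "fold")]
  rownames(per_sample) <- NULL
  summ <- aggregate(fold ~ group, data = per_sample,
                    FUN = function(x) c(mean = mean(x), sd = sd(x)))
  summary_df <- data.frame(group = summ$group,
                           mean_fold = summ$fold[, "mean"],
                           sd_fold = summ$fold[, "sd"])
  structure(list(per_sample = per_sample, summary = summary_df,
                 target = target, reference = reference, calibrator = calibrator),
            class = "fold_change_result")
}

#' Dunnett many-to-one comparison against a control
#'
#' Pooled-variance t statistics of each treatment group against the control
#' with the family-wise adjustment from the equicorrelated multivariate t
#' distribution (correlations \code{sqrt(n_i n_j / ((n_i+n0)(n_j+n0)))}),
#' evaluated two-sided by seeded Monte-Carlo integration. With a single
#' comparison the adjusted p-value reduces to the two-sided pooled
#' two-sample t-test p-value (up to Monte-Carlo error).
#'
#' @param groups named list of numeric vectors, one per treatment group
#'   (each with >= 2 observations)
#' @param control numeric vector of control observations (>= 2)
#' @param alpha significance level used for the star annotation; the
#'   conventional thresholds 0.05 (*) and 0.001 (***) are always annotated
#' @param n_draws Monte-Carlo draws from the multivariate t (>= 1e4)
#' @param seed integer seed making the integration deterministic
#' @return object of class \code{dunnett_result}: data.frame \code{table}
#'   with group, mean_diff, t, df, p_unadjusted, p_adjusted, significance
#' @export
dunnett_test <- function(groups, control, alpha = 0.05, n_draws = 1e5, seed = 1L) {
  if (!is.list(groups) || !length(groups)) stop("groups must be a non-empty list")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2) || length(control) < 2)
    stop("every group (and the control) needs at least 2 observations")
  if (n_draws < 1e4) stop("n_draws must be >= 1e4")
  k <- length(groups)
  n0 <- length(control)
  all_obs <- c(list(control), groups)
  N <- sum(vapply(all_obs, length, integer(1)))
  df <- N - (k + 1)
  s2 <- sum(vapply(all_obs, function(x) sum((x - mean(x))^2), numeric(1))) / df
  mean_diff <- vapply(groups, mean, numeric(1)) - mean(control)
  se <- sqrt(s2 * (1 / sizes + 1 / n0))
  tstat <- mean_diff / se
  # equicorrelated MVT null: T_i = (Z_i - lambda-share Z_0 construction)
  lam <- sqrt(sizes / (sizes + n0))
  maxT <- with_seed(seed, {
    z0 <- rnorm(n_draws)
    zi <- matrix(rnorm(n_draws * k), n_draws, k)
    # Corr(T_i, T_j) = lam_i lam_j via shared control variate
    num <- sweep(zi, 2, sqrt(1 - lam^2), `*`) + outer(z0, lam)
    tt <- abs(num / sqrt(rchisq(n_draws, df) / df))
    m <- tt[, 1]
    for (j in seq_len(k)[-1]) m <- pmax(m, tt[, j])
    m
  })
  p_adj <- vapply(abs(tstat), function(tt) mean(maxT >= tt), numeric(1))
  p_un <- 2 * pt(-abs(tstat), df)
  stars <- ifelse(p_adj < 0.001, "***", ifelse(p_adj < 0.05, "*", ""))
  structure(list(table = data.frame(group = names(groups),
                                    mean_diff = unname(mean_diff),
                                    t = unname(tstat), df = df,
                                    p_unadjusted = unname(p_un),
                                    p_adjusted = unname(p_adj),
                                    significance = stars,
                                    row.names = NULL),
                 alpha = alpha, n_draws = n_draws, seed = seed,
                 pooled_sd = sqrt(s2)),
            class = "dunnett_result")
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("Dunnett many-to-one test (two-sided, %d MC draws, df = %d)\n",
              x$n_draws, x$table$df[1]))
  print(x$table, digits = 4)
  cat("significance: * p < 0.05, *** p < 0.001 (family-wise adjusted)\n")
  invisible(x)
}
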