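#' Log reduction of viable concentration
#'
#' L = log10(C0 / C), the order-of-magnitude drop in viable cells. When the
#' post-exposure count is zero the true concentration lies below the plating
#' detection limit and L is reported as the lower bound
#' log10(C0 / detection_limit) with `censored = TRUE`.
#'
#' @param C0 initial concentration, CFU/mL (> 0).
#' @param C post-exposure concentration, CFU/mL (>= 0). Vectorized.
#' @param detection_limit concentration equivalent of one colony on the least
#'   diluted plate, CFU/mL.
#' @return data.frame with columns `L` and `censored`.
#' @examples
#' log_reduction(1e8, 1e4)$L # 4
#' log_reduction(1e8, 0, detection_limit = 1) # >= 8, censored
#' @export
log_reduction <- function(C0, C, detection_limit = 1) {
  if (!is.numeric(C0) || any(C0 <= 0)) stop("C0 must be > 0")
  if (any(C < 0)) stop("C must be >= 0")
  if (detection_limit <= 0) stop("detection_limit must be > 0")
  censored <- C < detection_limit
  L <- ifelse(censored, log10(C0 / detection_limit), log10(C0 / C))
  data.frame(L = L, censored = censored)
}

#' Log-reduction series from a survival curve
#'
#' Converts per-replicate concentrations into L = log10(C0/C) against fluence,
#' using each replicate's own fluence-zero concentration as C0.
#'
#' @param curve a `survival_curve` data.frame (see [simulate_survival_curve()]
#'   or [read_survival_csv()]).
#' @param detection_limit CFU/mL; passed to [log_reduction()].
#' @return data.frame of class `log_reduction_series` with columns
#'   `fluence_mJcm2`, `replicate`, `L`, `censored`.
#' @export
log_reduction_series <- function(curve, detection_limit = 1) {
  stopifnot(is.data.frame(curve),
            all(c("fluence_mJcm2", "replicate", "concentration") %in% names(curve)))
  if (!any(curve$fluence_mJcm2 == 0)) stop("survival curve must contain fluence 0")
  out <- do.call(rbind, lapply(split(curve, curve$replicate), function(rep_df) {
    c0 <- rep_df$concentration[rep_df$fluence_mJcm2 == 0]
    if (length(c0) != 1L || c0 <= 0) {
      stop("each replicate needs a single positive concentration at fluence 0")
    }
    lr <- log_reduction(c0, rep_df$concentration, detection_limit)
    data.frame(fluence_mJcm2 = rep_df$fluence_mJcm2,
               replicate = rep_df$replicate,
               L = lr$L, censored = lr$censored)
  }))
  rownames(out) <- NULL
  class(out) <- c("log_reduction_series", "data.frame")
  out
}

#' Fit linear inactivation kinetics
#'
#' Ordinary least-squares regression of log reduction on fluence over the
#' initial, log-linear part of the survival curve (default up to 6 mJ/cm2,
#' before tailing sets in). The fluence-based inactivation rate constant kf
#' (cm2/mJ) is the mean of per-replicate slopes; its uncertainty is the sample
#' standard deviation across replicates. R2 is taken from the pooled fit over
#' all replicates. Censored points (counts below the detection limit) are
#' excluded rather than substituted.
#'
#' @param series a `log_reduction_series` (or data.frame with columns
#'   `fluence_mJcm2`, `replicate`, `L`, `censored`).
#' @param fluence_cutoff mJ/cm2; only points with fluence <= cutoff enter the
#'   fit.
#' @return object of class `linear_kinetic_fit`: list with `kf`, `kf_sd`,
#'   `intercept`, `r_squared`, `fluence_cutoff`, `n_points`,
#'   `replicate_slopes`.
#' @export
fit_linear_kinetics <- function(series, fluence_cutoff = 6) {
  stopifnot(fluence_cutoff > 0)
  d <- series[!series$censored & series$fluence_mJcm2 <= fluence_cutoff, ]
  if (length(unique(d$fluence_mJcm2)) < 3L) {
    stop("need at least 3 distinct uncensored fluences at or below the cutoff")
  }
  slopes <- vapply(split(d, d$replicate), function(rep_df) {
    if (length(unique(rep_df$fluence_mJcm2)) < 2L) return(NA_real_)
    unname(stats::coef(stats::lm(L ~ fluence_mJcm2, data = rep_df))[2L])
  }, numeric(1))
  slopes <- slopes[!is.na(slopes)]
  if (length(slopes) == 0L) stop("no replicate has two distinct usable fluences")
  pooled <- stats::lm(L ~ fluence_mJcm2, data = d)
  ss_res <- sum(stats::residuals(pooled)^2)
  ss_tot <- sum((d$L - mean(d$L))^2)
  structure(list(
    kf = mean(slopes),
    kf_sd = if (length(slopes) >= 2L) stats::sd(slopes) else 0,
    intercept = unname(stats::coef(pooled)[1L]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    fluence_cutoff = fluence_cutoff,
    n_points = nrow(d),
    replicate_slopes = slopes
  ), class = "linear_kinetic_fit")
}

#' @export
print.linear_kinetic_fit <- function(x, ...) {
  cat(sprintf("Linear inactivation kinetics (fluence <= %g mJ/cm2)\n",
              x$fluence_cutoff))
  cat(sprintf("  kf = %.3f +/- %.3f cm2/mJ  [R2 = %.3f]  (%d points, %d replicates)\n",
              x$kf, x$kf_sd, x$r_squared, x$n_points, length(x$replicate_slopes)))
  invisible(x)
}

#' Fit origin-constrained quadratic kinetics
#'
#' Least-squares fit of L = a*F^2 + b*F over the full fluence range (default
#' up to 14 mJ/cm2). The curve is constrained through the origin because
#' L(0) = 0 by definition. Tailing survival curves (a shielded subpopulation
#' flattening the log-survival) give a < 0.
#'
#' @param series a `log_reduction_series`.
#' @param fluence_max mJ/cm2; upper fluence bound of the fit window.
#' @return object of class `poly_kinetic_fit`: list with `a` (cm4/mJ2),
#'   `b` (cm2/mJ), `r_squared`, `fluence_max`, `n_points`.
#' @export
fit_polynomial_kinetics <- function(series, fluence_max = 14) {
  d <- series[!series$censored & series$fluence_mJcm2 <= fluence_max, ]
  if (length(unique(d$fluence_mJcm2)) < 3L) {
    stop("need at least 3 distinct uncensored fluences")
  }
  fit <- stats::lm(L ~ 0 + I(fluence_mJcm2^2) + fluence_mJcm2, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("rank-deficient polynomial fit")
  # R2 on centred totals so linear and quadratic fits are comparable
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((d$L - mean(d$L))^2)
  structure(list(
    a = unname(cf[1L]),
    b = unname(cf[2L]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    fluence_max = fluence_max,
    n_points = nrow(d)
  ), class = "poly_kinetic_fit")
}

#' @export
print.poly_kinetic_fit <- function(x, ...) {
  cat(sprintf("Quadratic kinetics through origin (fluence <= %g mJ/cm2)\n",
              x$fluence_max))
  cat(sprintf("  L = %.4f F^2 + %.4f F  [R2 = %.3f]\n", x$a, x$b, x$r_squared))
  invisible(x)
}

#' Evaluate a fitted quadratic at given fluences
#' @param fit a `poly_kinetic_fit`.
#' @param fluence mJ/cm2 vector.
#' @return predicted log reductions (0 at fluence 0 by construction).
#' @export
predict_poly_kinetics <- function(fit, fluence) {
  stopifnot(inherits(fit, "poly_kinetic_fit"))
  fit$a * fluence^2 + fit$b * fluence
}

#' Required fluence for a target log reduction
#'
#' Inverts a first-order rate constant: F = target / kf, rounded half-up to
#' one decimal, the convention of published required-fluence tables.
#'
#' @param kf fluence-based inactivation rate constant, cm2/mJ (> 0).
#' @param target_log target log reduction (> 0); vectorized.
#' @return data.frame with `target_log` and `required_fluence` (mJ/cm2, one
#'   decimal).
#' @examples
#' required_fluence(1.624, c(2, 4, 6)) # 1.2, 2.5, 3.7 mJ/cm2
#' @export
required_fluence <- function(kf, target_log = c(2, 4, 6)) {
  if (!is.numeric(kf) || length(kf) != 1L || kf <= 0) stop("kf must be a single value > 0")
  if (any(target_log <= 0)) stop("target_log must be > 0")
  data.frame(target_log = target_log,
             required_fluence = round_half_up(target_log / kf, 1))
}

#' Build a required-fluence table from a set of linear fits
#'
#' One row per (wavelength, organism, strain) with the rounded fluence needed
#' for each target log reduction; fluences are monotone in the target.
#'
#' @param fits data.frame with columns `wavelength_nm`, `organism`, `strain`,
#'   `kf` (cm2/mJ) — e.g. the rate-constant table shipped in
#'   `system.file("extdata", "environmental_rate_constants.csv", package = "uvcled")`
#'   — or a named list of `linear_kinetic_fit` objects plus matching metadata
#'   columns.
#' @param targets target log reductions.
#' @return data.frame with metadata columns and one `log<t>_mJcm2` column per
#'   target.
#' @export
build_fluence_table <- function(fits, targets = c(2, 4, 6)) {
  stopifnot(is.data.frame(fits),
            all(c("wavelength_nm", "organism", "strain", "kf") %in% names(fits)))
  if (any(!is.finite(fits$kf) | fits$kf <= 0)) stop("all kf must be finite and > 0")
  out <- fits[, c("wavelength_nm", "organism", "strain")]
  for (t in sort(targets)) {
    out[[sprintf("log%g_mJcm2", t)]] <-
      vapply(fits$kf, function(k) required_fluence(k, t)$required_fluence, numeric(1))
  }
  out
}
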