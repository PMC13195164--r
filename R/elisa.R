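#' Simulate an ELISA standard curve
#'
#' Absorbances for a CPD-DNA standard dilution series under a linear or
#' four-parameter logistic (4PL) response, optionally with Gaussian
#' read noise. Noiseless output is strictly monotone in concentration.
#'
#' @param model_params list. Linear: `list(model = "linear", intercept,
#'   slope)` with slope > 0. 4PL: `list(model = "4pl", a, b, c, d)` for
#'   y = d + (a - d) / (1 + (x / c)^b) with a = zero-dose asymptote,
#'   d = saturation asymptote, c = inflection concentration (> 0), b = slope
#'   factor (> 0); increasing requires d > a.
#' @param standard_concentrations positive, sorted concentrations.
#' @param noise_sd absorbance noise sd (0 = noiseless).
#' @param seed RNG seed (needed when noise_sd > 0).
#' @return data.frame with columns `concentration`, `absorbance`.
#' @export
simulate_standard_curve <- function(model_params, standard_concentrations,
                                    noise_sd = 0, seed = NULL) {
  x <- standard_concentrations
  if (length(x) == 0L || any(x <= 0) || is.unsorted(x)) {
    stop("standard concentrations must be positive and sorted")
  }
  y <- eval_elisa_model(model_params, x)
  if (any(diff(eval_elisa_model(model_params, sort(unique(c(x, max(x) * 2))))) <= 0)) {
    stop("non-monotone model parameters")
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0")
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }
  data.frame(concentration = x, absorbance = y)
}

# internal: evaluate a linear or 4PL response
eval_elisa_model <- function(mp, x) {
  if (mp$model == "linear") {
    if (mp$slope <= 0) stop("non-monotone model parameters: slope must be > 0")
    mp$intercept + mp$slope * x
  } else if (mp$model == "4pl") {
    if (mp$b <= 0 || mp$c <= 0 || mp$d <= mp$a) {
      stop("non-monotone model parameters: need b > 0, c > 0, d > a")
    }
    mp$d + (mp$a - mp$d) / (1 + (x / mp$c)^mp$b)
  } else {
    stop("unknown model: ", mp$model)
  }
}

#' Fit a CPD ELISA standard calibration curve
#'
#' Least-squares fit of absorbance against standard concentration, either
#' linear or four-parameter logistic (the standard sigmoid for immunoassays;
#' default). The fitted response must be strictly monotone over the standard
#' range so that inverse prediction is unique.
#'
#' @param points data.frame with columns `concentration`, `absorbance` (or
#'   two numeric vectors via `concentration` and `absorbance` arguments).
#' @param model "4pl" or "linear".
#' @param concentration,absorbance alternative vector interface.
#' @return object of class `standard_curve`: list with `model`, `coef`,
#'   `residual_sd`, `r_squared`, `conc_range`, `abs_range`, `n`.
#' @export
fit_standard_curve <- function(points = NULL, model = c("4pl", "linear"),
                               concentration = points$concentration,
                               absorbance = points$absorbance) {
  model <- match.arg(model)
  x <- concentration
  y <- absorbance
  stopifnot(length(x) == length(y), all(x >= 0))
  if (length(unique(x)) < if (model == "4pl") 4L else 2L) {
    stop("insufficient distinct standard concentrations for a ", model, " fit")
  }
  if (model == "linear") {
    fit <- stats::lm(y ~ x)
    cf <- stats::coef(fit)
    if (cf[2L] <= 0) stop("non-monotone fit: estimated slope <= 0")
    coef_out <- list(intercept = unname(cf[1L]), slope = unname(cf[2L]))
    fitted_y <- stats::fitted(fit)
    resid <- stats::residuals(fit)
  } else {
    if (any(x <= 0)) stop("4PL fit needs strictly positive concentrations")
    start <- list(a = min(y), d = max(y), c = stats::median(x), b = 1)
    fit <- minpack.lm::nlsLM(
      y ~ d + (a - d) / (1 + (x / c)^b),
      start = start,
      lower = c(a = -Inf, d = -Inf, c = 1e-12, b = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- as.list(stats::coef(fit))
    if (cf$d <= cf$a || cf$b <= 0) stop("non-monotone 4PL fit")
    coef_out <- cf
    fitted_y <- stats::fitted(fit)
    resid <- stats::residuals(fit)
  }
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    model = model,
    coef = coef_out,
    residual_sd = sqrt(sum(resid^2) / max(1, length(y) - length(coef_out))),
    r_squared = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 1,
    conc_range = range(x),
    abs_range = range(fitted_y),
    n = length(y)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("ELISA standard curve (%s), n = %d, R2 = %.4f\n",
              x$model, x$n, x$r_squared))
  cat("  coefficients:",
      paste(sprintf("%s = %.5g", names(x$coef), unlist(x$coef)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Invert a standard curve to CPD concentrations
#'
#' Unique inverse prediction on the monotone range of the fitted response.
#' Absorbances at or below `blank` are reported as not detected
#' (concentration 0), the convention for dark controls. Absorbances outside
#' the fitted response range (for 4PL, outside the asymptotes) are flagged
#' `out_of_range` and not extrapolated (concentration NA).
#'
#' @param curve a `standard_curve`.
#' @param absorbance numeric vector of sample absorbances.
#' @param sample_id optional ids.
#' @param blank blank absorbance; NULL disables the not-detected rule.
#' @return data.frame of class `cpd_measurements`: `sample_id`, `absorbance`,
#'   `cpd_concentration` (standard-curve units per assay DNA input),
#'   `out_of_range`, `detected`.
#' @export
invert_standard_curve <- function(curve, absorbance,
                                  sample_id = seq_along(absorbance),
                                  blank = NULL) {
  stopifnot(inherits(curve, "standard_curve"))
  y <- absorbance
  nd <- if (!is.null(blank)) y <= blank else rep(FALSE, length(y))
  if (curve$model == "linear") {
    eps <- 1e-8 * diff(curve$abs_range)
    oor <- y < curve$abs_range[1L] - eps | y > curve$abs_range[2L] + eps
    x <- (y - curve$coef$intercept) / curve$coef$slope
  } else {
    a <- curve$coef$a; b <- curve$coef$b; cc <- curve$coef$c; d <- curve$coef$d
    oor <- y <= a | y >= d
    x <- rep(NA_real_, length(y))
    ok <- !oor
    x[ok] <- cc * ((a - d) / (y[ok] - d) - 1)^(1 / b)
  }
  x[oor] <- NA_real_
  oor <- oor & !nd
  x[nd] <- 0
  out <- data.frame(sample_id = sample_id, absorbance = y,
                    cpd_concentration = x, out_of_range = oor,
                    detected = !nd & !is.na(x) & x > 0)
  class(out) <- c("cpd_measurements", "data.frame")
  out
}
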