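#' Two-population inactivation model parameters
#'
#' Survival under UV fluence F is modelled as a mixture of a sensitive
#' majority and a shielded (e.g. aggregated) subpopulation:
#' C(F) = C0 * ((1 - p) * 10^(-kf * F) + p * 10^(-rho * kf * F)).
#' With p = 0 this reduces to exact first-order kinetics; p > 0 with rho < 1
#' produces the tailing commonly seen in high-titre disinfection assays.
#'
#' @param kf_sensitive rate constant of the sensitive population, cm2/mJ (> 0).
#' @param resistant_fraction p, fraction of shielded cells, in [0, 1).
#' @param resistance_factor rho in [0, 1); the shielded population is
#'   inactivated at rho * kf.
#' @param C0 initial concentration, CFU/mL (> 0).
#' @return object of class `inactivation_params`.
#' @export
inactivation_params <- function(kf_sensitive,
                                resistant_fraction = 1e-6,
                                resistance_factor = 0.1,
                                C0 = 1e8) {
  stopifnot(is.numeric(kf_sensitive), length(kf_sensitive) == 1L, kf_sensitive > 0,
            resistant_fraction >= 0, resistant_fraction < 1,
            resistance_factor >= 0, resistance_factor < 1,
            C0 > 0)
  structure(list(kf_sensitive = kf_sensitive,
                 resistant_fraction = resistant_fraction,
                 resistance_factor = resistance_factor,
                 C0 = C0),
            class = "inactivation_params")
}

#' Expected concentration under the two-population model
#' @param params an `inactivation_params`.
#' @param fluence mJ/cm2 vector.
#' @return expected CFU/mL at each fluence.
#' @export
expected_concentration <- function(params, fluence) {
  stopifnot(inherits(params, "inactivation_params"), all(fluence >= 0))
  p <- params$resistant_fraction
  kf <- params$kf_sensitive
  params$C0 * ((1 - p) * 10^(-kf * fluence) +
                 p * 10^(-params$resistance_factor * kf * fluence))
}

#' Plate-count protocol
#'
#' Serial-dilution plating in the usual drop/spread-plate style: counts are
#' Poisson with expectation concentration * plated_volume / dilution; plates
#' with more than `tntc` colonies are "too numerous to count" and the next
#' dilution is used. The detection limit is the concentration equivalent of a
#' single colony on the least diluted plate.
#'
#' @param dilution_factors powers of ten, ascending (1 = undiluted).
#' @param plated_volume mL plated per plate.
#' @param replicate_plates plates per sample (counts averaged).
#' @param tntc colony count above which a plate is uncountable.
#' @return object of class `plating_protocol` (detection_limit included).
#' @export
plating_protocol <- function(dilution_factors = 10^(0:6),
                             plated_volume = 0.1,
                             replicate_plates = 2L,
                             tntc = 300) {
  stopifnot(plated_volume > 0, replicate_plates >= 1L,
            all(dilution_factors >= 1), !is.unsorted(dilution_factors))
  structure(list(dilution_factors = dilution_factors,
                 plated_volume = plated_volume,
                 replicate_plates = as.integer(replicate_plates),
                 tntc = tntc,
                 detection_limit = min(dilution_factors) / plated_volume),
            class = "plating_protocol")
}

# internal: one plated observation; returns estimated concentration, the
# counted dilution and the (mean) colony count. Draw order: for each dilution
# in ascending order, replicate_plates Poisson draws, until countable.
plate_sample <- function(concentration, plating) {
  for (d in plating$dilution_factors) {
    lambda <- concentration * plating$plated_volume / d
    counts <- stats::rpois(plating$replicate_plates, lambda)
    if (mean(counts) <= plating$tntc) {
      return(list(concentration = mean(counts) * d / plating$plated_volume,
                  count = mean(counts), dilution = d,
                  censored = mean(counts) == 0))
    }
  }
  # still uncountable at the highest dilution: use it anyway
  list(concentration = mean(counts) * d / plating$plated_volume,
       count = mean(counts), dilution = d, censored = FALSE)
}

#' Simulate a UV survival curve
#'
#' Generates viable concentrations at each fluence for `n_replicates`
#' independent biological replicates under the two-population model, observed
#' either exactly (`noise = FALSE`) or through Poisson plate counts.
#'
#' @param params an `inactivation_params`.
#' @param fluences mJ/cm2, sorted, non-negative, must include 0.
#' @param plating a `plating_protocol`.
#' @param n_replicates biological replicates (the assays are run in duplicate
#'   by default).
#' @param noise logical; `FALSE` returns the model expectation exactly.
#' @param seed integer RNG seed (required when `noise = TRUE`).
#' @param organism,strain,wavelength_nm metadata carried into the output.
#' @return data.frame of class `survival_curve` with columns `organism`,
#'   `strain`, `wavelength_nm`, `fluence_mJcm2`, `replicate`, `concentration`,
#'   `count`, `dilution`, `censored`.
#' @export
simulate_survival_curve <- function(params, fluences, plating = plating_protocol(),
                                    n_replicates = 2L, noise = TRUE, seed = NULL,
                                    organism = "E. coli", strain = "environmental",
                                    wavelength_nm = 265) {
  stopifnot(inherits(params, "inactivation_params"),
            inherits(plating, "plating_protocol"))
  if (length(fluences) == 0L) stop("empty fluence list")
  if (is.unsorted(fluences) || any(fluences < 0) || !any(fluences == 0)) {
    stop("fluences must be sorted, non-negative and include 0")
  }
  if (noise) {
    if (is.null(seed)) stop("seed required when noise = TRUE")
    set.seed(as.integer(seed))
  }
  rows <- list()
  for (r in seq_len(n_replicates)) {
    for (f in fluences) {
      c_true <- expected_concentration(params, f)
      if (noise) {
        obs <- plate_sample(c_true, plating)
      } else {
        obs <- list(concentration = c_true, count = NA_real_,
                    dilution = NA_real_,
                    censored = c_true < plating$detection_limit)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        organism = organism, strain = strain, wavelength_nm = wavelength_nm,
        fluence_mJcm2 = f, replicate = r,
        concentration = obs$concentration, count = obs$count,
        dilution = obs$dilution, censored = obs$censored)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Simulate post-UV reactivation counts
#'
#' Concentrations immediately after exposure (0 h) and after incubation under
#' light (photoreactivation) or dark (dark repair) conditions. Repair restores
#' 10^recovery_log of the inactivated population at each time listed in
#' `recovery_times` (repair in indicator bacteria saturates within hours, so
#' by default the full configured recovery applies at both 2 h and 18 h).
#'
#' @param params an `inactivation_params` describing the pre-UV suspension.
#' @param fluence UV fluence applied before incubation, mJ/cm2.
#' @param recovery_log log10 units regained (>= 0).
#' @param condition "light" or "dark".
#' @param times sampling times, h.
#' @param recovery_times subset of `times` at which the recovery has occurred.
#' @param plating a `plating_protocol`.
#' @param n_replicates,noise,seed as in [simulate_survival_curve()].
#' @param organism,strain,wavelength_nm metadata.
#' @return data.frame of class `reactivation_counts` with columns `organism`,
#'   `strain`, `wavelength_nm`, `condition`, `time_h`, `replicate`,
#'   `concentration`, `count`, `dilution`, `censored`.
#' @export
simulate_reactivation_counts <- function(params, fluence = 14, recovery_log = 0,
                                         condition = c("light", "dark"),
                                         times = c(0, 2, 18),
                                         recovery_times = times[times > 0],
                                         plating = plating_protocol(),
                                         n_replicates = 2L, noise = TRUE,
                                         seed = NULL,
                                         organism = "E. coli",
                                         strain = "environmental",
                                         wavelength_nm = 265) {
  condition <- match.arg(condition)
  if (recovery_log < 0) stop("recovery_log must be >= 0")
  stopifnot(all(recovery_times %in% times))
  c_post <- expected_concentration(params, fluence)
  if (noise) {
    if (is.null(seed)) stop("seed required when noise = TRUE")
    set.seed(as.integer(seed))
  }
  rows <- list()
  for (r in seq_len(n_replicates)) {
    for (t in times) {
      c_true <- c_post * if (t %in% recovery_times) 10^recovery_log else 1
      if (noise) {
        obs <- plate_sample(c_true, plating)
      } else {
        obs <- list(concentration = c_true, count = NA_real_,
                    dilution = NA_real_,
                    censored = c_true < plating$detection_limit)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        organism = organism, strain = strain, wavelength_nm = wavelength_nm,
        condition = condition, time_h = t, replicate = r,
        concentration = obs$concentration, count = obs$count,
        dilution = obs$dilution, censored = obs$censored)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "C0_pre_UV") <- params$C0
  class(out) <- c("reactivation_counts", "data.frame")
  out
}

#' Write / read survival or reactivation tables as CSV
#'
#' Long-format CSV with header
#' `organism,strain,wavelength_nm,fluence_mJcm2,replicate,condition,time_h,count,dilution,plated_volume_mL,concentration,censored`.
#' Columns absent from the object (e.g. `condition` for a plain survival
#' curve) are written as NA so a single schema covers both table types.
#'
#' @param x a `survival_curve` or `reactivation_counts` data.frame.
#' @param path CSV path.
#' @param plated_volume_mL recorded plating volume.
#' @return `path`, invisibly (writer); data.frame (reader).
#' @export
write_survival_csv <- function(x, path, plated_volume_mL = 0.1) {
  cols <- c("organism", "strain", "wavelength_nm", "fluence_mJcm2", "replicate",
            "condition", "time_h", "count", "dilution", "plated_volume_mL",
            "concentration", "censored")
  df <- as.data.frame(x)
  df$plated_volume_mL <- plated_volume_mL
  for (col in setdiff(cols, names(df))) df[[col]] <- NA
  utils::write.csv(df[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("organism", "strain", "wavelength_nm", "replicate", "concentration")
  if (!all(needed %in% names(df))) {
    stop("survival CSV missing columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  cls <- if (!all(is.na(df$time_h))) "reactivation_counts" else "survival_curve"
  class(df) <- c(cls, "data.frame")
  df
}
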