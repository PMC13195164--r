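#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1 at one decimal), the
#' convention used for published required-fluence tables. Base [round()] uses
#' round-half-even, which would turn 2.25 into 2.2.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(2.25, 1) # 2.3
#' round_half_up(1.664, 1) # 1.7
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # small epsilon guards against representation error, e.g. 4.992 * 10
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Otsu threshold of a numeric vector
#'
#' Maximizes between-class variance over a histogram of the values. Used to
#' separate PI-positive from PI-negative per-cell mean intensities; works on
#' any 1-D sample, unlike image-specific implementations.
#'
#' @param x numeric vector (length >= 2, non-constant).
#' @param n_bins number of histogram bins.
#' @return threshold value; values strictly greater are in the upper class.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0) {
    stop("otsu_threshold() needs at least two distinct finite values")
  }
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  total_w <- w[n_bins]
  total_m <- m[n_bins]
  w_bg <- w[-n_bins]
  m_bg <- m[-n_bins]
  w_fg <- total_w - w_bg
  valid <- w_bg > 0 & w_fg > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- w_bg[valid] * w_fg[valid] *
    (m_bg[valid] / w_bg[valid] - (total_m - m_bg[valid]) / w_fg[valid])^2
  breaks[which.max(between) + 1L]
}

#' Pixel-intensity skewness (population g1)
#'
#' Third standardized moment m3 / m2^(3/2) with population moments
#' m_k = mean((x - mean(x))^k), i.e. no Bessel correction — the definition
#' used by common image-measurement platforms. Constant input has zero
#' variance; the skewness is then reported as 0 with `zero_variance = TRUE`
#' rather than NaN.
#'
#' @param pixels numeric vector of intensities (length >= 1).
#' @return list with `g1` (numeric) and `zero_variance` (logical).
#' @examples
#' intensity_skewness(c(1, 2, 3))$g1       # 0
#' intensity_skewness(c(0, 0, 0, 10))$g1   # 2/sqrt(3) = 1.1547
#' @export
intensity_skewness <- function(pixels) {
  if (length(pixels) == 0L) stop("empty pixel vector")
  if (!is.numeric(pixels) || anyNA(pixels)) stop("pixels must be numeric, no NA")
  d <- pixels - mean(pixels)
  m2 <- mean(d^2)
  if (m2 == 0) {
    return(list(g1 = 0, zero_variance = TRUE))
  }
  list(g1 = mean(d^3) / m2^1.5, zero_variance = FALSE)
}

# internal: sample sd that returns NA for n < 2 without warning
sample_sd <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)
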