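#' Specification of a synthetic microscopy scene
#'
#' Describes a field of stained bacterial cells to render: geometry, nucleoid
#' condensation, viability states and noise. The condensation parameter kappa
#' interpolates between a spatially homogeneous nucleoid (kappa = 0) and a
#' single bright sub-cellular DNA focus with a dim remainder (kappa = 1), the
#' staining pattern seen when UV stress condenses the nucleoid. Cells are
#' placed by rejection sampling without overlap and fully inside the frame.
#'
#' @param image_shape c(rows, cols) in pixels.
#' @param pixel_size micrometres per pixel.
#' @param n_cells number of cells to place (>= 0).
#' @param morphology list: `shape = "rod"` with `length_um`, `width_um`, or
#'   `shape = "coccus"` with `diameter_um`.
#' @param kappa nucleoid condensation in [0, 1].
#' @param pi_positive_prob probability a cell is membrane-compromised
#'   (PI-positive, SYTO9-quenched), in [0, 1].
#' @param background_level camera background, intensity units.
#' @param gaussian_noise_sd additive read-noise standard deviation.
#' @param shot_noise logical; Poisson noise on expected photon counts.
#' @param seed integer RNG seed (placement and noise).
#' @param amplitudes optional named overrides of per-channel signal amplitudes
#'   (`dna`, `membrane`, `syto9`, `pi`, `phase_bg`, `phase_cell`).
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(512L, 512L),
                       pixel_size = 0.1,
                       n_cells = 400L,
                       morphology = list(shape = "rod", length_um = 2.0,
                                         width_um = 0.7),
                       kappa = 0,
                       pi_positive_prob = 0,
                       background_level = 100,
                       gaussian_noise_sd = 20,
                       shot_noise = TRUE,
                       seed = 1L,
                       amplitudes = list()) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16L),
            pixel_size > 0, n_cells >= 0L,
            kappa >= 0, kappa <= 1,
            pi_positive_prob >= 0, pi_positive_prob <= 1,
            background_level >= 0, gaussian_noise_sd >= 0)
  morphology$shape <- match.arg(morphology$shape, c("rod", "coccus"))
  if (morphology$shape == "rod") {
    stopifnot(morphology$length_um >= morphology$width_um, morphology$width_um > 0)
  } else {
    stopifnot(morphology$diameter_um > 0)
  }
  amp <- utils::modifyList(
    list(dna = 600, membrane = 500, syto9 = 600, pi = 600,
         phase_bg = 600, phase_cell = 250),
    amplitudes)
  structure(list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
                 n_cells = as.integer(n_cells), morphology = morphology,
                 kappa = kappa, pi_positive_prob = pi_positive_prob,
                 background_level = background_level,
                 gaussian_noise_sd = gaussian_noise_sd,
                 shot_noise = isTRUE(shot_noise), seed = as.integer(seed),
                 amplitudes = amp),
            class = "scene_spec")
}

# internal: pixels within distance `radius` of the segment from p1 to p2
# (capsule). p1 == p2 gives a disc. Returns linear indices into a
# shape[1] x shape[2] matrix plus the distance of each pixel to the axis.
capsule_pixels <- function(shape, center, theta, length_px, width_px) {
  r <- width_px / 2
  h <- max(0, (length_px - width_px) / 2)
  ax <- c(cos(theta), sin(theta))
  p1 <- center + h * ax
  p2 <- center - h * ax
  rmin <- max(1L, floor(min(p1[1], p2[1]) - r - 1))
  rmax <- min(shape[1], ceiling(max(p1[1], p2[1]) + r + 1))
  cmin <- max(1L, floor(min(p1[2], p2[2]) - r - 1))
  cmax <- min(shape[2], ceiling(max(p1[2], p2[2]) + r + 1))
  if (rmin > rmax || cmin > cmax) {
    return(list(idx = integer(0), dist = numeric(0), row = integer(0),
                col = integer(0)))
  }
  rows <- rmin:rmax
  cols <- cmin:cmax
  gr <- rep(rows, times = length(cols))
  gc <- rep(cols, each = length(rows))
  # distance from each grid point to the segment p2->p1
  vx <- p1 - p2
  len2 <- sum(vx^2)
  if (len2 == 0) {
    d <- sqrt((gr - p1[1])^2 + (gc - p1[2])^2)
  } else {
    t <- pmin(1, pmax(0, ((gr - p2[1]) * vx[1] + (gc - p2[2]) * vx[2]) / len2))
    d <- sqrt((gr - (p2[1] + t * vx[1]))^2 + (gc - (p2[2] + t * vx[2]))^2)
  }
  keep <- d <= r
  list(idx = (gc[keep] - 1L) * shape[1] + gr[keep],
       dist = d[keep], row = gr[keep], col = gc[keep])
}

#' Render a synthetic multi-channel scene
#'
#' Draws every cell into five registered channels (phase, membrane, dna,
#' syto9, pi) and returns them with the ground-truth label mask and per-cell
#' truth table. The DNA channel of each cell deposits a fraction kappa of its
#' signal into a Gaussian focus covering roughly 10% of the cell area, so the
#' per-cell intensity skewness increases in expectation with kappa.
#' PI-positive cells are bright in the pi channel and quenched in syto9.
#'
#' Draw order under the scene seed: (1) cell placement (position, orientation,
#' rejection retries), (2) per-cell focus location, (3) per-cell PI state,
#' (4) shot noise, (5) read noise. Same seed, same scene, bit for bit.
#'
#' @param spec a [scene_spec()].
#' @param max_attempts_per_cell placement retries before giving up.
#' @return object of class `synthetic_scene`: list with `channels` (named list
#'   of matrices), `truth_mask` (integer matrix, 0 = background), `truth_table`
#'   (data.frame: label, kappa, pi_state, row, col, theta, area_px), `spec`.
#' @export
render_scene <- function(spec, max_attempts_per_cell = 1000L) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  shape <- spec$image_shape
  px <- spec$pixel_size
  morph <- spec$morphology
  if (morph$shape == "rod") {
    len_px <- morph$length_um / px
    wid_px <- morph$width_um / px
  } else {
    len_px <- wid_px <- morph$diameter_um / px
  }
  gap <- 2 # minimum clearance between cells, px
  margin <- len_px / 2 + gap + 2
  if (2 * margin >= min(shape)) stop("cells too large for the frame")

  occupied <- matrix(FALSE, shape[1], shape[2])
  truth_mask <- matrix(0L, shape[1], shape[2])
  cells <- vector("list", spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (a in seq_len(max_attempts_per_cell)) {
      center <- c(stats::runif(1, margin, shape[1] - margin),
                  stats::runif(1, margin, shape[2] - margin))
      theta <- stats::runif(1, 0, pi)
      dil <- capsule_pixels(shape, center, theta, len_px + 2 * gap,
                            wid_px + 2 * gap)
      if (any(occupied[dil$idx])) next
      cell <- capsule_pixels(shape, center, theta, len_px, wid_px)
      occupied[dil$idx] <- TRUE
      truth_mask[cell$idx] <- i
      cells[[i]] <- list(label = i, center = center, theta = theta,
                         pixels = cell)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf("failed to place cell %d after %d attempts; lower n_cells",
                   i, max_attempts_per_cell))
    }
  }

  amp <- spec$amplitudes
  bg <- spec$background_level
  chan <- list(phase = matrix(amp$phase_bg, shape[1], shape[2]),
               membrane = matrix(bg, shape[1], shape[2]),
               dna = matrix(bg, shape[1], shape[2]),
               syto9 = matrix(bg, shape[1], shape[2]),
               pi = matrix(bg, shape[1], shape[2]))

  n <- spec$n_cells
  # focus positions, then PI states, in documented draw order
  focus_t <- stats::runif(max(n, 0), -1, 1)       # position along the axis
  pi_state <- stats::runif(max(n, 0)) < spec$pi_positive_prob

  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- cells[[i]]
    pxs <- cl$pixels
    npx <- length(pxs$idx)
    r <- wid_px / 2
    # DNA: uniform share plus Gaussian focus normalized to conserve total
    dna_val <- rep(amp$dna * (1 - spec$kappa), npx)
    if (spec$kappa > 0) {
      h <- max(0, (len_px - wid_px) / 2)
      ax <- c(cos(cl$theta), sin(cl$theta))
      fc <- cl$center + focus_t[i] * h * ax
      sigma <- sqrt(0.1 * npx / pi)
      g <- exp(-((pxs$row - fc[1])^2 + (pxs$col - fc[2])^2) / (2 * sigma^2))
      dna_val <- dna_val + amp$dna * spec$kappa * g * npx / sum(g)
    }
    chan$dna[pxs$idx] <- chan$dna[pxs$idx] + dna_val
    # membrane: bright rim, dim interior
    rim <- pxs$dist > r - 1.5
    chan$membrane[pxs$idx] <- chan$membrane[pxs$idx] +
      ifelse(rim, amp$membrane, 0.3 * amp$membrane)
    # viability stains: PI quenches SYTO9
    if (pi_state[i]) {
      chan$syto9[pxs$idx] <- chan$syto9[pxs$idx] + 0.08 * amp$syto9
      chan$pi[pxs$idx] <- chan$pi[pxs$idx] + amp$pi
    } else {
      chan$syto9[pxs$idx] <- chan$syto9[pxs$idx] + amp$syto9
      chan$pi[pxs$idx] <- chan$pi[pxs$idx] + 0.04 * amp$pi
    }
    chan$phase[pxs$idx] <- amp$phase_cell
    truth[[i]] <- data.frame(label = i, kappa = spec$kappa,
                             pi_state = pi_state[i],
                             row = cl$center[1], col = cl$center[2],
                             theta = cl$theta, area_px = npx)
  }

  if (spec$shot_noise) {
    for (nm in names(chan)) {
      chan[[nm]][] <- stats::rpois(length(chan[[nm]]), lambda = chan[[nm]])
    }
  }
  if (spec$gaussian_noise_sd > 0) {
    for (nm in names(chan)) {
      chan[[nm]][] <- pmax(0, chan[[nm]] +
                             stats::rnorm(length(chan[[nm]]),
                                          sd = spec$gaussian_noise_sd))
    }
  }

  truth_table <- if (n > 0) do.call(rbind, truth) else
    data.frame(label = integer(0), kappa = numeric(0), pi_state = logical(0),
               row = numeric(0), col = numeric(0), theta = numeric(0),
               area_px = integer(0))
  structure(list(channels = chan, truth_mask = truth_mask,
                 truth_table = truth_table, spec = spec),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d x %d px, %d cells (kappa = %g, PI prob = %g)\n",
              nrow(x$truth_mask), ncol(x$truth_mask), nrow(x$truth_table),
              x$spec$kappa, x$spec$pi_positive_prob))
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' Per-channel 16-bit grayscale TIFFs (`<name>.tif`), a 16-bit label TIFF
#' (`truth_mask.tif`), the truth table as CSV and a channel-map JSON so
#' [read_channel_stack()] can reload the directory.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(scene$channels)) {
    write_uint16_tiff(scene$channels[[nm]], file.path(dir, paste0(nm, ".tif")))
  }
  write_uint16_tiff(scene$truth_mask, file.path(dir, "truth_mask.tif"))
  utils::write.csv(scene$truth_table, file.path(dir, "truth_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(pixel_size = scene$spec$pixel_size,
         channels = as.list(stats::setNames(paste0(names(scene$channels), ".tif"),
                                            names(scene$channels)))),
    file.path(dir, "channels.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

# internal: 16-bit grayscale TIFF writer/reader; tiff stores [0,1] floats
write_uint16_tiff <- function(mat, path) {
  m <- pmin(pmax(round(mat), 0), 65535) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

read_uint16_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  round(m * 65535)
}
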