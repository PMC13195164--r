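# Shared fixture builders. Everything is generated in code at test time.

# exact log-linear series: L = slope_r * F per replicate, with free choice of
# slopes per replicate
linear_series <- function(slopes, fluences = c(0, 2, 4, 6)) {
  do.call(rbind, lapply(seq_along(slopes), function(r) {
    data.frame(fluence_mJcm2 = fluences, replicate = r,
               L = slopes[r] * fluences, censored = FALSE)
  }))
}

# phase-contrast image of hand-placed capsules (cells dark on bright field)
capsule_phase_image <- function(shape, centers, theta, length_px = 20,
                                width_px = 7, bg = 600, cell = 250) {
  img <- matrix(bg, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    px <- uvcled:::capsule_pixels(shape, as.numeric(centers[i, ]),
                                  theta[i], length_px, width_px)
    img[px$idx] <- cell
  }
  img
}

# small rendered scene reused across image-analysis tests
small_scene <- function(n_cells = 40L, kappa = 0, pi_prob = 0, seed = 1L,
                        shape = c(256L, 256L), ...) {
  render_scene(scene_spec(image_shape = shape, n_cells = n_cells,
                          kappa = kappa, pi_positive_prob = pi_prob,
                          seed = seed, ...))
}
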