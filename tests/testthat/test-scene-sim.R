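test_that("empty scene has empty truth outputs", {
  sc <- render_scene(scene_spec(n_cells = 0L, seed = 1))
  expect_equal(sum(sc$truth_mask), 0)
  expect_equal(nrow(sc$truth_table), 0L)
  expect_named(sc$channels, c("phase", "membrane", "dna", "syto9", "pi"))
})

test_that("truth mask and truth table labels are a bijection, no overlaps", {
  sc <- small_scene(n_cells = 60L, seed = 8)
  mask_labels <- sort(setdiff(unique(as.vector(sc$truth_mask)), 0L))
  expect_equal(mask_labels, sc$truth_table$label)
  # areas recorded in the truth table match the mask exactly
  expect_equal(as.integer(table(sc$truth_mask[sc$truth_mask > 0])),
               sc$truth_table$area_px)
  # placement margin: no label touches the border
  expect_equal(sum(sc$truth_mask[c(1, nrow(sc$truth_mask)), ]), 0)
  expect_equal(sum(sc$truth_mask[, c(1, ncol(sc$truth_mask))]), 0)
})

test_that("same seed renders bit-identical scenes, different seeds differ", {
  a <- small_scene(n_cells = 20L, kappa = 0.4, pi_prob = 0.1, seed = 3)
  b <- small_scene(n_cells = 20L, kappa = 0.4, pi_prob = 0.1, seed = 3)
  c <- small_scene(n_cells = 20L, kappa = 0.4, pi_prob = 0.1, seed = 4)
  expect_identical(a$channels, b$channels)
  expect_identical(a$truth_table, b$truth_table)
  expect_false(identical(a$channels$dna, c$channels$dna))
})

test_that("kappa = 0 noiseless cells are homogeneous; skewness ~ 0", {
  sc <- render_scene(scene_spec(n_cells = 300L, kappa = 0,
                                shot_noise = FALSE, gaussian_noise_sd = 0,
                                seed = 5))
  st <- as_channel_stack(sc)
  rec <- per_cell_stats(st, import_label_mask(sc$truth_mask))
  expect_lt(abs(mean(rec$dna_skewness)), 0.1)
  expect_true(all(rec$dna_zero_variance))
})

test_that("mean DNA skewness increases with condensation kappa", {
  mean_skew <- vapply(c(0, 0.25, 0.5, 0.75, 1.0), function(k) {
    sc <- small_scene(n_cells = 200L, kappa = k, seed = 12,
                      shape = c(384L, 384L))
    rec <- per_cell_stats(as_channel_stack(sc),
                          import_label_mask(sc$truth_mask))
    mean(rec$dna_skewness)
  }, numeric(1))
  expect_false(is.unsorted(mean_skew))
  # paired scenes with the same seed: strict increase from 0 to 0.8
  s0 <- small_scene(n_cells = 150L, kappa = 0, seed = 21, shape = c(384L, 384L))
  s8 <- small_scene(n_cells = 150L, kappa = 0.8, seed = 21, shape = c(384L, 384L))
  m0 <- mean(per_cell_stats(as_channel_stack(s0),
                            import_label_mask(s0$truth_mask))$dna_skewness)
  m8 <- mean(per_cell_stats(as_channel_stack(s8),
                            import_label_mask(s8$truth_mask))$dna_skewness)
  expect_gt(m8, m0)
})

test_that("PI-positive cells are bright in pi and quenched in syto9", {
  sc <- small_scene(n_cells = 60L, pi_prob = 0.3, seed = 6)
  rec <- per_cell_stats(as_channel_stack(sc), import_label_mask(sc$truth_mask))
  pos <- sc$truth_table$pi_state
  expect_gt(min(rec$pi_mean[pos]), max(rec$pi_mean[!pos]))
  expect_lt(max(rec$syto9_mean[pos]), min(rec$syto9_mean[!pos]))
})

test_that("placement failure is a bounded, informative error", {
  expect_error(render_scene(scene_spec(image_shape = c(64L, 64L),
                                       n_cells = 500L, seed = 1),
                            max_attempts_per_cell = 10L),
               "failed to place")
})

test_that("scene export/import round-trips channels, mask and truth table", {
  sc <- small_scene(n_cells = 15L, kappa = 0.5, pi_prob = 0.2, seed = 9,
                    shape = c(128L, 128L))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  expect_setequal(list.files(dir),
                  c("phase.tif", "membrane.tif", "dna.tif", "syto9.tif",
                    "pi.tif", "truth_mask.tif", "truth_table.csv",
                    "channels.json"))
  stack <- read_channel_stack(dir)
  # intensities quantized to integers on write; otherwise identical
  expect_equal(stack$channels$dna, round(sc$channels$dna), tolerance = 1e-12)
  mask <- import_label_mask(file.path(dir, "truth_mask.tif"))
  expect_equal(as.integer(mask), as.integer(sc$truth_mask))
  tt <- read.csv(file.path(dir, "truth_table.csv"))
  expect_equal(tt$label, sc$truth_table$label)
  expect_equal(tt$pi_state, sc$truth_table$pi_state)
})

test_that("ELISA standard simulator is monotone and validates parameters", {
  lin <- simulate_standard_curve(list(model = "linear", intercept = 0.1,
                                      slope = 0.002), 100)
  expect_equal(lin$absorbance, 0.3)
  four <- simulate_standard_curve(list(model = "4pl", a = 0.05, b = 1.3,
                                       c = 100, d = 2.4),
                                  c(5, 10, 50, 100, 500, 1000))
  expect_false(is.unsorted(four$absorbance, strictly = TRUE))
  expect_error(simulate_standard_curve(list(model = "linear", intercept = 0.1,
                                            slope = -1), c(1, 2)),
               "non-monotone")
  expect_error(simulate_standard_curve(list(model = "4pl", a = 2, b = 1,
                                            c = 10, d = 0.1), c(1, 2)),
               "non-monotone")
  expect_error(simulate_standard_curve(list(model = "linear", intercept = 0,
                                            slope = 1), c(-1, 2)), "positive")
})
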