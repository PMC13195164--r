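test_that("skewness matches a brute-force moment oracle on random vectors", {
  skip_if_not_installed("e1071")
  set.seed(100)
  for (i in 1:1000) {
    x <- switch(1 + i %% 3,
                rnorm(30, 100, 15),
                rpois(25, 40),
                rexp(40, 0.05))
    got <- intensity_skewness(x)
    expect_false(got$zero_variance)
    expect_equal(got$g1, e1071::skewness(x, type = 1), tolerance = 1e-9)
  }
})

test_that("skewness handles the canonical exact cases", {
  expect_equal(intensity_skewness(c(1, 2, 3))$g1, 0)
  expect_equal(intensity_skewness(c(0, 0, 0, 10))$g1, 2 / sqrt(3),
               tolerance = 1e-12)
  flat <- intensity_skewness(c(5, 5, 5))
  expect_equal(flat$g1, 0)
  expect_true(flat$zero_variance)
  expect_error(intensity_skewness(numeric(0)), "empty")
})

test_that("skewness is invariant under affine rescaling a*x + b, a > 0", {
  set.seed(200)
  for (i in 1:50) {
    x <- rgamma(40, shape = 2, rate = 0.1)
    a <- runif(1, 0.01, 100)
    b <- runif(1, -50, 50)
    expect_equal(intensity_skewness(a * x + b)$g1, intensity_skewness(x)$g1,
                 tolerance = 1e-9)
  }
})

test_that("segmentation recovers well-separated cells with high IoU", {
  sc <- small_scene(n_cells = 10L, seed = 14, shape = c(200L, 200L))
  st <- as_channel_stack(sc)
  mask <- segment_cells(st)
  expect_equal(max(mask), 10L)
  acc <- segmentation_accuracy(mask, sc$truth_mask, iou_threshold = 0.7)
  expect_equal(acc$n_matched, 10L)
  expect_gte(acc$mean_iou, 0.7)
})

test_that("segmentation meets recall/precision/IoU floors at default density", {
  for (seed in c(1L, 2L)) {
    sc <- render_scene(scene_spec(n_cells = 300L, kappa = 0.5,
                                  pi_positive_prob = 0.05, seed = seed))
    acc <- segmentation_accuracy(segment_cells(as_channel_stack(sc)),
                                 sc$truth_mask)
    expect_gte(acc$recall, 0.9)
    expect_gte(acc$precision, 0.9)
    expect_gte(acc$mean_iou, 0.7)
  }
})

test_that("blank image segments to an empty mask, missing channel errors", {
  st <- channel_stack(list(dna = matrix(50, 64, 64)))
  expect_equal(max(segment_cells(st, "dna")), 0L)
  expect_error(segment_cells(st, "pi"), "not present")
})

test_that("watershed splits touching rods only when splitting is enabled", {
  img <- capsule_phase_image(c(128L, 128L),
                             centers = rbind(c(60, 40), c(60, 60)),
                             theta = c(pi / 2, pi / 2))
  st <- channel_stack(list(phase = img))
  expect_equal(max(segment_cells(st, "phase", split = TRUE)), 2L)
  expect_equal(max(segment_cells(st, "phase", split = FALSE)), 1L)
})

test_that("border and area filters drop the intended objects", {
  img <- capsule_phase_image(c(128L, 128L),
                             centers = rbind(c(5, 64), c(64, 64)),
                             theta = c(0, 0))
  st <- channel_stack(list(phase = img))
  kept <- segment_cells(st, "phase", exclude_border = TRUE)
  expect_equal(max(kept), 1L)
  both <- segment_cells(st, "phase", exclude_border = FALSE)
  expect_equal(max(both), 2L)
  none <- segment_cells(st, "phase", min_area = 1e5)
  expect_equal(max(none), 0L)
})

test_that("imported masks are relabeled contiguously and validated", {
  m <- matrix(0L, 32, 32)
  m[5:8, 5:8] <- 3L
  m[20:25, 20:23] <- 7L
  lm <- import_label_mask(m)
  expect_equal(sort(setdiff(unique(as.vector(lm)), 0L)), c(1L, 2L))
  expect_equal(sum(lm == 1L), 16)
  # disconnected label warns (or errors in strict mode)
  bad <- matrix(0L, 32, 32)
  bad[2:4, 2:4] <- 1L
  bad[20:22, 20:22] <- 1L
  expect_warning(import_label_mask(bad), "connected components")
  expect_error(import_label_mask(bad, strict_connectivity = TRUE),
               "connected components")
  # float-valued files are rejected
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(64), 8, 8), path, bits.per.sample = 32L)
  expect_error(import_label_mask(path), "non-integer")
  # all-zero masks are allowed
  expect_equal(max(import_label_mask(matrix(0L, 8, 8))), 0L)
})

test_that("per-cell statistics are exact on constructed masks", {
  img <- matrix(0, 16, 16)
  mask <- matrix(0L, 16, 16)
  mask[2:5, 2:5] <- 1L       # flat cell
  img[2:5, 2:5] <- 100
  mask[10:13, 10:13] <- 2L   # one bright pixel cell
  img[10:13, 10:13] <- 0
  img[10, 10] <- 10
  st <- channel_stack(list(dna = img), pixel_size = 0.5)
  rec <- per_cell_stats(st, import_label_mask(mask))
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$dna_mean[1], 100)
  expect_equal(rec$dna_sd[1], 0)
  expect_equal(rec$dna_skewness[1], 0)
  expect_true(rec$dna_zero_variance[1])
  expect_equal(rec$area_um2[1], 16 * 0.25)
  # 16 pixels, one at 10: same shape as the canonical 4-pixel case family
  ref <- intensity_skewness(c(rep(0, 15), 10))$g1
  expect_equal(rec$dna_skewness[2], ref, tolerance = 1e-12)
  expect_error(per_cell_stats(st, matrix(0L, 8, 8)), "shape")
})

test_that("kappa = 1 noiseless cells all have positive DNA skewness", {
  sc <- render_scene(scene_spec(image_shape = c(256L, 256L), n_cells = 50L,
                                kappa = 1, shot_noise = FALSE,
                                gaussian_noise_sd = 0, seed = 4))
  rec <- per_cell_stats(as_channel_stack(sc), import_label_mask(sc$truth_mask))
  expect_true(all(rec$dna_skewness > 0))
})

test_that("PI classification recovers ground-truth states on truth masks", {
  sc <- render_scene(scene_spec(n_cells = 400L, kappa = 0.3,
                                pi_positive_prob = 0.05, seed = 9))
  st <- as_channel_stack(sc)
  rec <- classify_pi_positive(per_cell_stats(st, import_label_mask(sc$truth_mask)))
  truth <- sc$truth_table[match(rec$label, sc$truth_table$label), "pi_state"]
  expect_equal(rec$pi_positive, truth)
  # all-negative field stays at 0%
  neg <- small_scene(n_cells = 80L, pi_prob = 0, seed = 10)
  nrec <- classify_pi_positive(per_cell_stats(as_channel_stack(neg),
                                              import_label_mask(neg$truth_mask)))
  expect_equal(sum(nrec$pi_positive), 0L)
  expect_error(classify_pi_positive(data.frame(dna_mean = 1)), "pi channel")
})

test_that("image and condition summaries compute mean +/- sample sd", {
  rec <- data.frame(label = 1:100, dna_skewness = rnorm(100),
                    pi_positive = c(rep(TRUE, 2), rep(FALSE, 98)))
  s <- summarize_image(rec)
  expect_equal(s$pi_fraction, 2.0)
  expect_equal(s$n_cells, 100L)
  # per-image fractions 0.5/0.8/1.1 percent -> 0.8 +/- 0.3
  imgs <- data.frame(n_cells = c(200, 250, 300),
                     skewness_mean = c(0.1, 0.2, 0.3),
                     skewness_median = 0, skewness_sd = 0.1,
                     pi_fraction = c(0.5, 0.8, 1.1))
  cond <- summarize_condition(imgs)
  expect_equal(cond$pi_fraction_mean, 0.8)
  expect_equal(cond$pi_fraction_sd, 0.3, tolerance = 1e-12)
  expect_true(cond$sd_defined)
  single <- summarize_condition(imgs[1L, ])
  expect_false(single$sd_defined)
  expect_true(is.na(single$pi_fraction_sd))
  expect_error(summarize_image(rec[0L, ]), "no cell records")
})
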