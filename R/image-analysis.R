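#' Multi-channel image stack
#'
#' A named set of registered 2-D intensity arrays (any subset of phase,
#' membrane, dna, syto9, pi) plus acquisition metadata.
#'
#' @param channels named list of numeric matrices sharing one shape.
#' @param pixel_size micrometres per pixel.
#' @param metadata list (condition, fluence, wavelength, ...).
#' @return object of class `channel_stack`.
#' @export
channel_stack <- function(channels, pixel_size = 0.1, metadata = list()) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  shp <- dim(channels[[1L]])
  for (nm in names(channels)) {
    m <- channels[[nm]]
    if (!is.matrix(m) || !identical(dim(m), shp)) {
      stop("all channels must be matrices with identical shape")
    }
    if (any(m < 0)) stop("intensities must be non-negative (channel ", nm, ")")
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 metadata = metadata),
            class = "channel_stack")
}

#' @rdname channel_stack
#' @param scene a `synthetic_scene` to wrap without going through disk.
#' @export
as_channel_stack <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  channel_stack(scene$channels, pixel_size = scene$spec$pixel_size,
                metadata = list(kappa = scene$spec$kappa,
                                pi_positive_prob = scene$spec$pi_positive_prob))
}

#' Read a channel stack from per-channel TIFFs
#'
#' Loads the channel-name-to-file mapping from `channels.json` (as written by
#' [write_scene()]) or from an explicit mapping.
#'
#' @param dir directory holding the TIFFs and `channels.json`.
#' @param mapping optional named character vector channel -> file, overriding
#'   the JSON.
#' @param metadata list passed through.
#' @return a `channel_stack`.
#' @export
read_channel_stack <- function(dir, mapping = NULL, metadata = list()) {
  pixel_size <- 0.1
  if (is.null(mapping)) {
    cfg_path <- file.path(dir, "channels.json")
    if (!file.exists(cfg_path)) stop("no channels.json in ", dir)
    cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    mapping <- unlist(cfg$channels)
    if (!is.null(cfg$pixel_size)) pixel_size <- cfg$pixel_size
  }
  channels <- lapply(mapping, function(f) read_uint16_tiff(file.path(dir, f)))
  names(channels) <- names(mapping)
  channel_stack(channels, pixel_size = pixel_size, metadata = metadata)
}

#' Segment cells in a channel
#'
#' Classical pipeline standing in for learned segmentation: Gaussian
#' smoothing, global Otsu threshold, hole filling, optional
#' distance-transform watershed to split touching objects, area filtering and
#' border-object exclusion, then contiguous relabeling. For the phase channel
#' (cells darker than background) the image is inverted before thresholding.
#'
#' The default channel is "phase": it delineates the whole cell regardless of
#' how the fluorescent stains partition. Thresholding the dna channel instead
#' shrinks the mask towards the bright focus once the nucleoid condenses, so
#' use a non-dna channel whenever per-cell DNA statistics are the goal.
#'
#' @param stack a `channel_stack`.
#' @param channel channel name to segment.
#' @param sigma Gaussian smoothing sd, px.
#' @param min_area,max_area retained object area bounds, px.
#' @param split logical; watershed-split touching objects.
#' @param exclude_border drop objects touching the frame edge.
#' @param watershed_tolerance minimum object-height separation for a split.
#' @return a `label_mask`: integer matrix, labels 1..n contiguous, with
#'   attributes `border_labels` (always empty after exclusion) and `params`.
#' @export
segment_cells <- function(stack, channel = "phase", sigma = 1,
                          min_area = 20, max_area = Inf, split = TRUE,
                          exclude_border = TRUE, watershed_tolerance = 1) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!channel %in% names(stack$channels)) {
    stop("channel '", channel, "' not present in stack")
  }
  img <- stack$channels[[channel]]
  if (channel == "phase") img <- max(img) - img
  if (diff(range(img)) == 0) {
    return(new_label_mask(matrix(0L, nrow(img), ncol(img))))
  }
  # EBImage works on [0,1] grayscale
  eb <- EBImage::Image(img / max(img))
  if (sigma > 0) eb <- EBImage::gblur(eb, sigma = sigma)
  thr <- EBImage::otsu(eb, range = range(eb))
  binary <- eb > thr
  binary <- EBImage::fillHull(binary)
  if (sum(binary) == 0) {
    return(new_label_mask(matrix(0L, nrow(img), ncol(img))))
  }
  lab <- if (split) {
    EBImage::watershed(EBImage::distmap(binary),
                       tolerance = watershed_tolerance, ext = 1)
  } else {
    EBImage::bwlabel(binary)
  }
  lab <- EBImage::imageData(lab)
  storage.mode(lab) <- "integer"
  filter_relabel(lab, min_area = min_area, max_area = max_area,
                 exclude_border = exclude_border,
                 params = list(channel = channel, sigma = sigma,
                               threshold = as.numeric(thr),
                               min_area = min_area, max_area = max_area,
                               split = split))
}

new_label_mask <- function(mat, border_labels = integer(0), params = list()) {
  structure(mat, border_labels = border_labels, params = params,
            class = c("label_mask", class(mat)))
}

# internal: area filter + border exclusion + contiguous relabel
filter_relabel <- function(lab, min_area = 0, max_area = Inf,
                           exclude_border = TRUE, params = list()) {
  labs <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(labs) == 0L) return(new_label_mask(lab, params = params))
  areas <- tabulate(lab[lab > 0L], nbins = max(labs))
  keep <- labs[areas[labs] >= min_area & areas[labs] <= max_area]
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- setdiff(border, 0L)
  if (exclude_border) keep <- setdiff(keep, border)
  remap <- integer(max(labs) + 1L) # index by old label + 1
  remap[keep + 1L] <- seq_along(keep)
  out <- matrix(remap[lab + 1L], nrow(lab), ncol(lab))
  new_label_mask(out,
                 border_labels = if (exclude_border) integer(0) else
                   remap[intersect(border, keep) + 1L],
                 params = params)
}

#' Import an externally produced label mask
#'
#' Reads an integer-valued label image (e.g. from a learned segmentation
#' tool), validates that the stored values are integral and that each label
#' forms a single connected component, and relabels to contiguous 1..n.
#' Labels touching the image border are recorded in the `border_labels`
#' attribute (not dropped: external masks may deliberately keep them).
#'
#' @param path TIFF file, or an integer matrix already in memory.
#' @param strict_connectivity error (TRUE) or warn (FALSE) when a label has
#'   multiple connected components.
#' @return a `label_mask`.
#' @export
import_label_mask <- function(path, strict_connectivity = FALSE) {
  mat <- if (is.matrix(path)) {
    path
  } else {
    # normalized read then rescale by the sample depth recovers the stored
    # integer labels for 8/16-bit files; float-valued files land on
    # non-integral values and are rejected below
    m <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(m, "bits.per.sample")
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m * (2^bits - 1)
  }
  if (any(abs(mat - round(mat)) > 1e-3)) {
    stop("label image contains non-integer values")
  }
  mat <- matrix(as.integer(round(mat)), nrow(mat), ncol(mat))
  if (any(mat < 0)) stop("negative labels")
  labs <- setdiff(sort(unique(as.vector(mat))), 0L)
  # connectivity check per label
  for (l in labs) {
    comp <- EBImage::bwlabel(EBImage::Image(mat == l))
    if (max(comp) > 1L) {
      msg <- sprintf("label %d has %d connected components", l, max(comp))
      if (strict_connectivity) stop(msg) else warning(msg)
    }
  }
  remap <- integer(if (length(labs)) max(labs) + 1L else 1L)
  remap[labs + 1L] <- seq_along(labs)
  out <- matrix(remap[mat + 1L], nrow(mat), ncol(mat))
  border <- setdiff(unique(c(out[1L, ], out[nrow(out), ], out[, 1L],
                             out[, ncol(out)])), 0L)
  new_label_mask(out, border_labels = border)
}

#' Per-cell intensity statistics
#'
#' One record per label with area, centroid and, for every channel, the mean,
#' standard deviation and population skewness g1 of the intensities over all
#' pixels of the label (the whole-cell mask, not a sub-region). Zero-variance
#' cells get skewness 0 with the corresponding `<channel>_zero_variance` flag.
#'
#' @param stack a `channel_stack`.
#' @param mask a `label_mask` of matching shape.
#' @param min_area drop labels smaller than this many pixels.
#' @return data.frame of class `cell_records`: label, area_px, area_um2,
#'   centroid_row, centroid_col, then `<channel>_mean`, `<channel>_sd`,
#'   `<channel>_skewness`, `<channel>_zero_variance` per channel.
#' @export
per_cell_stats <- function(stack, mask, min_area = 0) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!identical(dim(stack$channels[[1L]]), dim(mask))) {
    stop("mask shape does not match channel shape")
  }
  labv <- as.integer(mask)
  sel <- labv > 0L
  labs <- sort(unique(labv[sel]))
  if (length(labs) == 0L) {
    return(empty_cell_records(names(stack$channels)))
  }
  f <- factor(labv[sel], levels = labs)
  areas <- as.integer(table(f))
  rows <- row(mask)[sel]
  cols <- col(mask)[sel]
  rec <- data.frame(label = labs,
                    area_px = areas,
                    area_um2 = areas * stack$pixel_size^2,
                    centroid_row = as.numeric(tapply(rows, f, mean)),
                    centroid_col = as.numeric(tapply(cols, f, mean)))
  for (nm in names(stack$channels)) {
    v <- stack$channels[[nm]][sel]
    mu <- tapply(v, f, mean)
    m2 <- tapply((v - mu[f])^2, f, mean)
    m3 <- tapply((v - mu[f])^3, f, mean)
    zv <- m2 == 0
    rec[[paste0(nm, "_mean")]] <- as.numeric(mu)
    rec[[paste0(nm, "_sd")]] <- sqrt(as.numeric(m2))
    rec[[paste0(nm, "_skewness")]] <-
      ifelse(zv, 0, as.numeric(m3) / as.numeric(m2)^1.5)
    rec[[paste0(nm, "_zero_variance")]] <- as.logical(zv)
  }
  rec <- rec[rec$area_px >= min_area, ]
  rownames(rec) <- NULL
  class(rec) <- c("cell_records", "data.frame")
  rec
}

empty_cell_records <- function(channel_names) {
  rec <- data.frame(label = integer(0), area_px = integer(0),
                    area_um2 = numeric(0), centroid_row = numeric(0),
                    centroid_col = numeric(0))
  for (nm in channel_names) {
    rec[[paste0(nm, "_mean")]] <- numeric(0)
    rec[[paste0(nm, "_sd")]] <- numeric(0)
    rec[[paste0(nm, "_skewness")]] <- numeric(0)
    rec[[paste0(nm, "_zero_variance")]] <- logical(0)
  }
  class(rec) <- c("cell_records", "data.frame")
  rec
}

#' Classify PI-positive (membrane-compromised) cells
#'
#' A cell is PI-positive when its mean pi-channel intensity exceeds a
#' data-driven threshold — Otsu over the per-cell pi means, with an absolute
#' floor — and, when a syto9 channel is present, its max-normalized pi mean
#' exceeds its max-normalized syto9 mean (PI quenches SYTO9 in compromised
#' cells, so the dominant stain flips). The floor defaults to twice the
#' median per-cell pi mean, which keeps all-negative fields at 0%.
#'
#' @param records a `cell_records` data.frame with a `pi_mean` column.
#' @param floor absolute intensity floor; `NULL` for the data-driven default.
#' @param require_syto9_dominance apply the channel-dominance criterion when
#'   syto9 means are available.
#' @return `records` with logical `pi_positive` column; the thresholds used
#'   are stored in the `pi_rule` attribute.
#' @export
classify_pi_positive <- function(records, floor = NULL,
                                 require_syto9_dominance = TRUE) {
  if (!"pi_mean" %in% names(records)) stop("records lack a pi channel")
  pim <- records$pi_mean
  if (nrow(records) == 0L) {
    records$pi_positive <- logical(0)
    return(records)
  }
  if (is.null(floor)) floor <- 2 * stats::median(pim)
  thr <- if (length(unique(pim)) >= 2L) {
    max(otsu_threshold(pim), floor)
  } else {
    floor
  }
  pos <- pim > thr
  if (require_syto9_dominance && "syto9_mean" %in% names(records)) {
    sm <- records$syto9_mean
    pos <- pos & (pim / max(pim) > sm / max(sm))
  }
  records$pi_positive <- pos
  attr(records, "pi_rule") <- list(threshold = thr, floor = floor,
                                   syto9_dominance = require_syto9_dominance)
  records
}

#' Summarize one image / one condition
#'
#' Per image: cell count, skewness summary of the chosen channel and the
#' PI-positive percentage. Per condition: mean and sample sd of the per-image
#' values (sd needs at least two images; otherwise NA with `sd_defined =
#' FALSE`).
#'
#' @param records a `cell_records` data.frame (with `pi_positive` if PI
#'   fractions are wanted).
#' @param skew_channel channel whose skewness is summarized.
#' @return `summarize_image()`: data.frame of class `image_summary` with
#'   n_cells, skewness_mean/median/sd, pi_fraction (percent, NA when no
#'   `pi_positive` column).
#' @export
summarize_image <- function(records, skew_channel = "dna") {
  if (nrow(records) == 0L) stop("no cell records to summarize")
  skew_col <- paste0(skew_channel, "_skewness")
  if (!skew_col %in% names(records)) {
    stop("no skewness column for channel '", skew_channel, "'")
  }
  s <- records[[skew_col]]
  out <- data.frame(
    n_cells = nrow(records),
    skewness_mean = mean(s),
    skewness_median = stats::median(s),
    skewness_sd = sample_sd(s),
    pi_fraction = if ("pi_positive" %in% names(records)) {
      100 * sum(records$pi_positive) / nrow(records)
    } else NA_real_)
  class(out) <- c("image_summary", "data.frame")
  out
}

#' @rdname summarize_image
#' @param summaries list of `image_summary` rows (or an rbind of them), all
#'   from one experimental condition.
#' @return `summarize_condition()`: one-row data.frame of class
#'   `condition_summary` with n_images and, for pi_fraction and
#'   skewness_mean, their across-image mean and sample sd.
#' @export
summarize_condition <- function(summaries) {
  df <- if (is.data.frame(summaries)) summaries else do.call(rbind, summaries)
  if (nrow(df) == 0L) stop("no image summaries")
  out <- data.frame(
    n_images = nrow(df),
    n_cells_total = sum(df$n_cells),
    pi_fraction_mean = mean(df$pi_fraction),
    pi_fraction_sd = sample_sd(df$pi_fraction),
    skewness_mean = mean(df$skewness_mean),
    skewness_sd = sample_sd(df$skewness_mean),
    sd_defined = nrow(df) >= 2L)
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Compare a computed mask against ground truth
#'
#' Greedy best-overlap matching of predicted to true labels; reports count
#' recall/precision and the mean intersection-over-union of matched pairs.
#'
#' @param predicted,truth label matrices of identical shape.
#' @param iou_threshold minimum IoU for a pair to count as a match.
#' @return list with `recall`, `precision`, `mean_iou`, `n_true`, `n_pred`,
#'   `n_matched`.
#' @export
segmentation_accuracy <- function(predicted, truth, iou_threshold = 0.5) {
  stopifnot(identical(dim(predicted), dim(truth)))
  pl <- as.integer(predicted)
  tl <- as.integer(truth)
  pt <- table(factor(pl[pl > 0 | tl > 0], exclude = NULL),
              factor(tl[pl > 0 | tl > 0], exclude = NULL))
  p_labs <- setdiff(as.integer(rownames(pt)), 0L)
  t_labs <- setdiff(as.integer(colnames(pt)), 0L)
  if (length(t_labs) == 0L || length(p_labs) == 0L) {
    return(list(recall = 0, precision = 0, mean_iou = 0,
                n_true = length(t_labs), n_pred = length(p_labs), n_matched = 0))
  }
  p_area <- tabulate(pl[pl > 0], nbins = max(p_labs))
  t_area <- tabulate(tl[tl > 0], nbins = max(t_labs))
  matched_iou <- numeric(0)
  used_pred <- integer(0)
  for (t in t_labs) {
    inter <- pt[match(p_labs, rownames(pt)), as.character(t)]
    cand <- setdiff(p_labs[inter > 0], used_pred)
    if (length(cand) == 0L) next
    ious <- vapply(cand, function(p) {
      i <- pt[as.character(p), as.character(t)]
      i / (p_area[p] + t_area[t] - i)
    }, numeric(1))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      matched_iou <- c(matched_iou, ious[best])
      used_pred <- c(used_pred, cand[best])
    }
  }
  n_match <- length(matched_iou)
  list(recall = n_match / length(t_labs),
       precision = n_match / length(p_labs),
       mean_iou = if (n_match > 0) mean(matched_iou) else 0,
       n_true = length(t_labs), n_pred = length(p_labs), n_matched = n_match)
}

#' Box plot of per-cell skewness by condition
#'
#' @param records_by_condition named list of `cell_records`.
#' @param skew_channel channel to plot.
#' @param file optional output file (pdf/png decided by extension); NULL plots
#'   to the active device.
#' @return invisibly, the list of skewness vectors plotted.
#' @export
plot_skewness <- function(records_by_condition, skew_channel = "dna",
                          file = NULL) {
  col <- paste0(skew_channel, "_skewness")
  vals <- lapply(records_by_condition, function(r) r[[col]])
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "png") grDevices::png(file, width = 800, height = 600) else
      grDevices::pdf(file, width = 7, height = 5)
    on.exit(grDevices::dev.off())
  }
  graphics::boxplot(vals, ylab = sprintf("per-cell %s skewness (g1)",
                                         skew_channel),
                    xlab = "condition", col = "lightsteelblue")
  invisible(vals)
}
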