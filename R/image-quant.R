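#' Two-channel microscopy frame
#'
#' A pair of co-registered 16-bit intensity images: a nuclear channel
#' staining every cell and a reporter channel staining the subset of
#' cells that took up the fluorescent molecule.
#'
#' @param nuclear_channel,reporter_channel Numeric matrices of equal
#'   dimensions with intensities in `[0, 65535]`.
#' @param pixel_size Optional pixel size in um/px.
#' @param provenance `"synthetic"` or `"file"`.
#' @return An object of class `two_channel_frame`.
#' @export
two_channel_frame <- function(nuclear_channel, reporter_channel,
                              pixel_size = NA_real_,
                              provenance = c("synthetic", "file")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(nuclear_channel), is.matrix(reporter_channel),
            all(dim(nuclear_channel) == dim(reporter_channel)))
  rng <- range(nuclear_channel, reporter_channel)
  if (rng[1] < 0 || rng[2] > 65535)
    stop("intensities must lie in [0, 65535]")
  structure(list(nuclear_channel = nuclear_channel,
                 reporter_channel = reporter_channel,
                 pixel_size = pixel_size,
                 provenance = provenance),
            class = "two_channel_frame")
}

#' Threshold and counting specification
#'
#' Settings for the reproducible stand-in of the manual
#' threshold-and-count workflow: global Otsu threshold (default) or a
#' fixed intensity, small-component removal as background denoising,
#' and the pixel connectivity used for component labeling.
#'
#' @param method `"otsu"` (threshold from the channel histogram) or
#'   `"fixed"`.
#' @param fixed_value Threshold intensity when `method = "fixed"`; may
#'   be length 2 as `c(nuclear, reporter)`.
#' @param min_component_px Components smaller than this many pixels are
#'   discarded.
#' @param connectivity 4 (edge neighbours) or 8 (edge + diagonal).
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(method = c("otsu", "fixed"),
                           fixed_value = NULL,
                           min_component_px = 20,
                           connectivity = 8) {
  method <- match.arg(method)
  if (method == "fixed") {
    stopifnot(is.numeric(fixed_value), length(fixed_value) %in% 1:2,
              all(fixed_value >= 0), all(fixed_value <= 65535))
    if (length(fixed_value) == 1) fixed_value <- rep(fixed_value, 2)
  }
  stopifnot(min_component_px >= 0, connectivity %in% c(4, 8))
  structure(list(method = method, fixed_value = fixed_value,
                 min_component_px = min_component_px,
                 connectivity = as.integer(connectivity)),
            class = "threshold_spec")
}

otsu_threshold <- function(channel) {
  if (diff(range(channel)) == 0) {
    warning("constant-intensity channel: degenerate Otsu threshold")
    return(channel[1])
  }
  # EBImage expects intensities in [0, 1]
  65535 * EBImage::otsu(channel / 65535, range = c(0, 1), levels = 65536)
}

#' Threshold a channel to a binary mask
#'
#' Pixels strictly above the threshold become foreground. With the Otsu
#' method the threshold is computed from the channel's own histogram; a
#' constant-intensity channel yields a degenerate-threshold warning and
#' an empty mask.
#'
#' @param channel Numeric matrix of 16-bit intensities.
#' @param spec A [threshold_spec()].
#' @param which For `method = "fixed"`, whether to use the nuclear (1)
#'   or reporter (2) fixed value.
#' @return Logical matrix mask.
#' @export
threshold_channel <- function(channel, spec = threshold_spec(), which = 1) {
  stopifnot(inherits(spec, "threshold_spec"), is.matrix(channel))
  thr <- if (spec$method == "otsu") otsu_threshold(channel)
         else spec$fixed_value[which]
  channel > thr
}

label_components <- function(mask, connectivity) {
  storage.mode(mask) <- "integer"
  .Call("cc_label", mask, as.integer(connectivity), PACKAGE = "sonopore")
}

#' Count connected components in a binary mask
#'
#' Labels foreground components under the configured connectivity,
#' drops components smaller than `min_component_px`, and returns the
#' count with component centroids.
#'
#' @param mask Logical or 0/1 matrix.
#' @param spec A [threshold_spec()].
#' @return List with `n` (component count), `centroids` (matrix with
#'   columns `x`, `y` in pixel coordinates: x = column, y = row), and
#'   `labels` (the filtered label matrix).
#' @export
count_cells <- function(mask, spec = threshold_spec()) {
  stopifnot(is.matrix(mask))
  lab <- label_components(mask, spec$connectivity)
  if (max(lab) == 0)
    return(list(n = 0L, centroids = matrix(numeric(0), 0, 2,
                                           dimnames = list(NULL, c("x", "y"))),
                labels = lab))
  sizes <- tabulate(lab, nbins = max(lab))
  keep <- which(sizes >= spec$min_component_px)
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  cent <- t(vapply(seq_along(keep), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    c(x = mean(idx[, 2]), y = mean(idx[, 1]))
  }, numeric(2)))
  list(n = length(keep), centroids = cent, labels = lab)
}

#' Quantify a two-channel frame
#'
#' The nuclear channel is thresholded and labeled to count all cells; a
#' nuclear component is called reporter-stained when its mean reporter
#' intensity exceeds the reporter threshold. The fraction is the
#' count-based fluorescent fraction in percent. With no nuclear
#' component the fraction is reported as missing (`NA`), not zero.
#'
#' @param frame A [two_channel_frame()].
#' @param spec A [threshold_spec()].
#' @return An object of class `quant_result`: list with `n_total`,
#'   `n_stained`, `fraction` (percent or `NA`), `component_centroids`.
#' @export
quantify_frame <- function(frame, spec = threshold_spec()) {
  stopifnot(inherits(frame, "two_channel_frame"))
  nuc_mask <- threshold_channel(frame$nuclear_channel, spec, which = 1)
  cells <- count_cells(nuc_mask, spec)
  rep_thr <- if (spec$method == "otsu") {
    withCallingHandlers(otsu_threshold(frame$reporter_channel),
                        warning = function(w) invokeRestart("muffleWarning"))
  } else spec$fixed_value[2]
  n_stained <- 0L
  if (cells$n > 0) {
    mean_rep <- vapply(seq_len(cells$n), function(i)
      mean(frame$reporter_channel[cells$labels == i]), numeric(1))
    n_stained <- sum(mean_rep > rep_thr)
  }
  fraction <- if (cells$n > 0)
    fraction_fluorescent_count(n_stained, cells$n) else NA_real_
  structure(list(n_total = cells$n, n_stained = n_stained,
                 fraction = fraction,
                 component_centroids = cells$centroids),
            class = "quant_result")
}

#' Quantify a batch of frames into replicate-level measurements
#'
#' Runs [quantify_frame()] on every frame and pools per-frame fractions
#' into replicate-level values (mean over the frames of each
#' replicate), the acquisition scheme in which several fields of view
#' are imaged per biological replicate.
#'
#' @param frames List of [two_channel_frame()] objects (>= 1).
#' @param spec A [threshold_spec()].
#' @param replicate_ids Optional vector assigning each frame to a
#'   replicate; by default every frame is its own replicate.
#' @param group_label Group label for the returned measurements.
#' @return List with `per_frame` (data frame of per-frame results) and
#'   `measurements` (a [group_measurements()] of replicate means).
#' @export
quantify_batch <- function(frames, spec = threshold_spec(),
                           replicate_ids = seq_along(frames),
                           group_label = "sham") {
  if (!is.list(frames) || length(frames) == 0)
    stop("need at least one frame")
  stopifnot(length(replicate_ids) == length(frames))
  res <- lapply(frames, quantify_frame, spec = spec)
  per_frame <- data.frame(
    frame = seq_along(frames),
    replicate = replicate_ids,
    n_total = vapply(res, `[[`, numeric(1), "n_total"),
    n_stained = vapply(res, `[[`, numeric(1), "n_stained"),
    fraction = vapply(res, `[[`, numeric(1), "fraction"))
  rep_means <- tapply(per_frame$fraction, per_frame$replicate, mean,
                      na.rm = TRUE)
  list(per_frame = per_frame,
       measurements = group_measurements(group_label, as.numeric(rep_means)))
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("quant_result: %d cells, %d stained (%s)\n",
              x$n_total, x$n_stained,
              if (is.na(x$fraction)) "fraction undefined"
              else sprintf("%.1f%%", x$fraction)))
  invisible(x)
}

#' Read / write a two-channel frame as 16-bit TIFF
#'
#' One grayscale TIFF per channel.
#'
#' @param nuclear_path,reporter_path File paths for the two channels.
#' @return `read_frame_tiff()` returns a [two_channel_frame()];
#'   `write_frame_tiff()` returns the paths invisibly.
#' @export
read_frame_tiff <- function(nuclear_path, reporter_path) {
  rd <- function(p) round(65535 * tiff::readTIFF(p))
  two_channel_frame(rd(nuclear_path), rd(reporter_path),
                    provenance = "file")
}

#' @rdname read_frame_tiff
#' @param frame A [two_channel_frame()].
#' @export
write_frame_tiff <- function(frame, nuclear_path, reporter_path) {
  stopifnot(inherits(frame, "two_channel_frame"))
  wr <- function(m, p) tiff::writeTIFF(m / 65535, p, bits.per.sample = 16)
  wr(frame$nuclear_channel, nuclear_path)
  wr(frame$reporter_channel, reporter_path)
  invisible(c(nuclear_path, reporter_path))
}
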