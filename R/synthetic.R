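#' Registry of published group summary statistics
#'
#' Loads the read-only registry of group means and SDs (in percent)
#' that the synthetic replicate generator targets, keyed by molecule,
#' metric and timepoint. The registry ships as a versioned YAML file
#' under `inst/extdata`.
#'
#' @param path Registry YAML path; defaults to the shipped registry.
#' @return An object of class `uptake_registry` (named list of
#'   experiment entries, each with `molecule`, `metric`, `timepoint_h`
#'   and per-group `mean`/`sd`).
#' @export
uptake_registry <- function(path = system.file("extdata",
                                               "uptake_registry.yaml",
                                               package = "sonopore",
                                               mustWork = TRUE)) {
  reg <- yaml::read_yaml(path)$experiments
  structure(reg, class = "uptake_registry")
}

# Truncated-normal draws on [lower, upper] by rejection sampling; the
# published summaries are percentages, so mass outside [0, 100] is
# excluded rather than clipped.
rtruncated_norm <- function(n, mean, sd, lower = 0, upper = 100) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(max(2 * n, 10), mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Synthesize replicate-level group measurements
#'
#' Draws replicate percentages from a normal distribution with the
#' target mean and SD, truncated to `[0, 100]`. With `target_sd = 0`
#' every replicate equals the mean exactly. Identical seeds give
#' identical output.
#'
#' @param group_label Treatment group label (see
#'   [group_measurements()]).
#' @param target_mean,target_sd Target mean and SD in percent.
#' @param n_replicates Number of replicates (default 3, the triplicate
#'   design).
#' @param seed Optional integer seed for reproducibility.
#' @return A [group_measurements()].
#' @export
synth_replicates <- function(group_label, target_mean, target_sd,
                             n_replicates = 3, seed = NULL) {
  stopifnot(target_mean >= 0, target_mean <= 100, target_sd >= 0,
            n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  group_measurements(group_label,
                     rtruncated_norm(n_replicates, target_mean, target_sd))
}

#' Synthesize an experiment table from the registry
#'
#' Builds an [experiment_table()] whose groups are drawn around the
#' registry's published means and SDs for the requested molecule,
#' metric and timepoint.
#'
#' @param registry An [uptake_registry()].
#' @param molecule,metric,timepoint_h Keys identifying the experiment.
#' @param n_replicates Replicates per group.
#' @param seed Optional integer seed.
#' @param sd_scale Multiplier applied to every registry SD; 0 makes the
#'   table deterministic at the registry means.
#' @return An [experiment_table()].
#' @export
synth_experiment <- function(registry, molecule, metric, timepoint_h,
                             n_replicates = 3, seed = NULL, sd_scale = 1) {
  stopifnot(inherits(registry, "uptake_registry"), sd_scale >= 0)
  hit <- Filter(function(e)
    e$molecule == molecule && e$metric == metric &&
      e$timepoint_h == timepoint_h,
    registry)
  if (length(hit) == 0)
    stop(sprintf("no registry entry for molecule '%s', metric '%s', %g h",
                 molecule, metric, timepoint_h))
  entry <- hit[[1]]
  if (!is.null(seed)) set.seed(seed)
  groups <- lapply(names(entry$groups), function(lab)
    group_measurements(lab, rtruncated_norm(
      n_replicates, entry$groups[[lab]]$mean,
      sd_scale * entry$groups[[lab]]$sd)))
  experiment_table(molecule, metric, timepoint_h, groups)
}

#' Synthetic two-channel frame specification
#'
#' @param width,height Frame size in pixels.
#' @param n_cells Number of cells (non-overlapping disks) to place.
#' @param stained_fraction Fraction of cells painted in the reporter
#'   channel, in `[0, 1]`; the stained count is
#'   `round(stained_fraction * n_cells)`.
#' @param disk_radius Cell disk radius in pixels.
#' @param nuclear_intensity,reporter_intensity Foreground levels on the
#'   16-bit scale.
#' @param noise_sd SD of the additive Gaussian noise (intensities are
#'   clamped back to `[0, 65535]`).
#' @param seed Optional integer seed.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(width = 256, height = 256, n_cells = 50,
                       stained_fraction = 0.3, disk_radius = 6,
                       nuclear_intensity = 30000,
                       reporter_intensity = 30000,
                       noise_sd = 0, seed = NULL) {
  stopifnot(width > 0, height > 0, n_cells >= 0,
            stained_fraction >= 0, stained_fraction <= 1,
            disk_radius >= 1, noise_sd >= 0,
            nuclear_intensity > 0, nuclear_intensity <= 65535,
            reporter_intensity > 0, reporter_intensity <= 65535)
  if (2 * disk_radius + 2 > min(width, height))
    stop("disks do not fit in the frame")
  structure(list(width = width, height = height, n_cells = n_cells,
                 stained_fraction = stained_fraction,
                 disk_radius = disk_radius,
                 nuclear_intensity = nuclear_intensity,
                 reporter_intensity = reporter_intensity,
                 noise_sd = noise_sd, seed = seed),
            class = "image_spec")
}

place_centers <- function(spec, max_tries = 200) {
  r <- spec$disk_radius
  min_sep2 <- (2 * r + 2)^2
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, r + 1, spec$width - r)
      y <- stats::runif(1, r + 1, spec$height - r)
      if (nrow(centers) == 0 ||
          all((centers[, 1] - x)^2 + (centers[, 2] - y)^2 >= min_sep2)) {
        centers <- rbind(centers, c(x, y))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", spec$n_cells, " non-overlapping disks; ",
           "use fewer or smaller disks")
  }
  centers
}

paint_disks <- function(mat, centers, radius, level) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]
    cy <- centers[i, 2]
    xs <- max(1, floor(cx - radius)):min(nc, ceiling(cx + radius))
    ys <- max(1, floor(cy - radius)):min(nr, ceiling(cy + radius))
    for (x in xs) for (y in ys)
      if ((x - cx)^2 + (y - cy)^2 <= radius^2) mat[y, x] <- level
  }
  mat
}

#' Generate a synthetic two-channel frame with ground truth
#'
#' Places `n_cells` non-overlapping disks (rejection sampling with a
#' bounded retry count) in the nuclear channel; a random subset of
#' `round(stained_fraction * n_cells)` disks is also painted in the
#' reporter channel. Additive Gaussian noise is applied to both
#' channels and clamped to the 16-bit range. Frames are deterministic
#' under a fixed seed.
#'
#' @param spec An [image_spec()].
#' @return List with `frame` (a [two_channel_frame()]) and `truth`
#'   (list with `n_cells`, `n_stained`, `stained_fraction_pct`,
#'   `centers`, `stained_idx`).
#' @export
synth_frame <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  nuc <- matrix(0, spec$height, spec$width)
  rep_ch <- matrix(0, spec$height, spec$width)
  n_stained <- round(spec$stained_fraction * spec$n_cells)
  centers <- if (spec$n_cells > 0) place_centers(spec)
             else matrix(numeric(0), 0, 2)
  stained_idx <- if (n_stained > 0) sample(spec$n_cells, n_stained)
                 else integer(0)
  if (spec$n_cells > 0) {
    nuc <- paint_disks(nuc, centers, spec$disk_radius,
                       spec$nuclear_intensity)
    if (n_stained > 0)
      rep_ch <- paint_disks(rep_ch, centers[stained_idx, , drop = FALSE],
                            spec$disk_radius, spec$reporter_intensity)
  }
  if (spec$noise_sd > 0) {
    nuc <- nuc + stats::rnorm(length(nuc), 0, spec$noise_sd)
    rep_ch <- rep_ch + stats::rnorm(length(rep_ch), 0, spec$noise_sd)
  }
  clamp <- function(m) pmin(pmax(m, 0), 65535)
  list(frame = two_channel_frame(clamp(nuc), clamp(rep_ch),
                                 provenance = "synthetic"),
       truth = list(n_cells = spec$n_cells,
                    n_stained = n_stained,
                    stained_fraction_pct =
                      if (spec$n_cells > 0) 100 * n_stained / spec$n_cells
                      else NA_real_,
                    centers = centers,
                    stained_idx = sort(stained_idx)))
}
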