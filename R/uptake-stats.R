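GROUP_LEVELS <- c("sham", "us_only", "tmb_only",
                  "tmb_us_100", "tmb_us_200", "tmb_us_300",
                  "tmb_us_500", "tmb_us_800")
MOLECULE_LEVELS <- c("7aad", "fitc4", "fitc20", "fitc70")
METRIC_LEVELS <- c("count_fraction", "area_fraction", "viability_percent")

#' Per-group replicate measurements
#'
#' Replicate-level percentage values (fluorescent fraction or viability)
#' for one treatment group. Group labels encode the treatment: `sham`
#' (no ultrasound, no microbubbles), `us_only`, `tmb_only` (targeted
#' microbubbles without ultrasound), and `tmb_us_<PNP>` for targeted
#' microbubbles insonated at the given peak negative pressure in kPa.
#'
#' @param group_label One of `"sham"`, `"us_only"`, `"tmb_only"`,
#'   `"tmb_us_100"`, `"tmb_us_200"`, `"tmb_us_300"`, `"tmb_us_500"`,
#'   `"tmb_us_800"`.
#' @param replicate_values Numeric vector of percentages in `[0, 100]`.
#' @return An object of class `group_measurements`.
#' @export
group_measurements <- function(group_label, replicate_values) {
  group_label <- match.arg(group_label, GROUP_LEVELS)
  stopifnot(is.numeric(replicate_values), length(replicate_values) >= 1,
            all(is.finite(replicate_values)))
  if (any(replicate_values < 0 | replicate_values > 100))
    stop("replicate values must lie in [0, 100] percent")
  structure(list(group_label = group_label,
                 replicate_values = as.numeric(replicate_values),
                 n_replicates = length(replicate_values)),
            class = "group_measurements")
}

group_pnp_kpa <- function(label) {
  m <- regmatches(label, regexec("^tmb_us_([0-9]+)$", label))
  vapply(m, function(x) if (length(x) == 2) as.numeric(x[2]) else NA_real_,
         numeric(1))
}

#' Experiment table for one molecule and metric
#'
#' Bundles the per-group replicate measurements of a single experiment:
#' one delivered molecule (7-AAD 1.2 kDa or FITC-dextran of 4/20/70
#' kDa), one metric (count-based fluorescent fraction, area-based
#' fluorescent fraction, or viability as percent of sham), and one
#' timepoint. Count fractions pair with 7-AAD (per-cell microscopy
#' counting) and area fractions with FITC (confluence-based); viability
#' applies to any molecule. Exactly one sham group must be present.
#'
#' @param molecule One of `"7aad"`, `"fitc4"`, `"fitc20"`, `"fitc70"`.
#' @param metric One of `"count_fraction"`, `"area_fraction"`,
#'   `"viability_percent"`.
#' @param timepoint_h Timepoint in hours after insonation.
#' @param groups List of [group_measurements()].
#' @return An object of class `experiment_table`.
#' @export
experiment_table <- function(molecule, metric, timepoint_h, groups) {
  molecule <- match.arg(molecule, MOLECULE_LEVELS)
  metric <- match.arg(metric, METRIC_LEVELS)
  stopifnot(is.numeric(timepoint_h), timepoint_h >= 0,
            is.list(groups), length(groups) >= 1,
            all(vapply(groups, inherits, logical(1), "group_measurements")))
  labels <- vapply(groups, `[[`, character(1), "group_label")
  if (sum(labels == "sham") != 1)
    stop("experiment table must contain exactly one sham group")
  if (anyDuplicated(labels))
    stop("duplicated group labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (metric == "count_fraction" && molecule != "7aad")
    stop("count_fraction is the 7-AAD counting metric")
  if (metric == "area_fraction" && molecule == "7aad")
    stop("area_fraction is the FITC confluence metric")
  names(groups) <- labels
  structure(list(molecule = molecule, metric = metric,
                 timepoint_h = timepoint_h, groups = groups),
            class = "experiment_table")
}

#' Convert an experiment table to a data frame
#'
#' Long format with one row per replicate, matching the CSV dialect of
#' [read_experiment_csv()].
#'
#' @param x An [experiment_table()].
#' @param ... Unused.
#' @return Data frame with columns `molecule`, `metric`, `timepoint_h`,
#'   `group`, `replicate`, `value`.
#' @export
as.data.frame.experiment_table <- function(x, ...) {
  do.call(rbind, lapply(x$groups, function(g)
    data.frame(molecule = x$molecule, metric = x$metric,
               timepoint_h = x$timepoint_h, group = g$group_label,
               replicate = seq_len(g$n_replicates),
               value = g$replicate_values,
               row.names = NULL)))
}

#' Read / write experiment tables as CSV
#'
#' The CSV dialect has columns `molecule, metric, timepoint_h, group,
#' replicate, value`; one file holds one experiment (single molecule,
#' metric and timepoint).
#'
#' @param path CSV file path.
#' @return [read_experiment_csv()] returns an [experiment_table()];
#'   `write_experiment_csv()` returns `path` invisibly.
#' @export
read_experiment_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule", "metric", "timepoint_h", "group", "value")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  if (length(unique(df$molecule)) != 1 || length(unique(df$metric)) != 1 ||
      length(unique(df$timepoint_h)) != 1)
    stop("one CSV must hold a single molecule/metric/timepoint experiment")
  groups <- lapply(split(df, df$group), function(d)
    group_measurements(d$group[1], d$value))
  experiment_table(df$molecule[1], df$metric[1], df$timepoint_h[1],
                   unname(groups))
}

#' @rdname read_experiment_csv
#' @param table An [experiment_table()].
#' @export
write_experiment_csv <- function(table, path) {
  stopifnot(inherits(table, "experiment_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Count-based fluorescent fraction
#'
#' Percentage of reporter-stained cells among all (nuclear-stained)
#' cells: `100 * stained / total`.
#'
#' @param stained Number of reporter-positive cells.
#' @param total Total number of cells (> 0).
#' @return Percentage in `[0, 100]`.
#' @export
fraction_fluorescent_count <- function(stained, total) {
  stopifnot(all(total > 0), all(stained >= 0))
  if (any(stained > total)) stop("stained count cannot exceed total count")
  100 * stained / total
}

#' Area-based fluorescent fraction
#'
#' Green (fluorescent) confluence normalized by phase (total cell)
#' confluence: `100 * green_area / phase_area`.
#'
#' @param green_area Fluorescent cell area (any consistent unit).
#' @param phase_area Total cell area (> 0, same unit).
#' @return Percentage in `[0, 100]`.
#' @export
fraction_fluorescent_area <- function(green_area, phase_area) {
  stopifnot(all(phase_area > 0), all(green_area >= 0))
  if (any(green_area > phase_area))
    stop("green area cannot exceed phase area")
  100 * green_area / phase_area
}

#' Fold uptake relative to sham
#'
#' Two modes. `"mean-ratio"` (default) divides the group mean by the
#' sham mean and returns a scalar. `"replicate"` divides replicate-wise
#' (pairing replicates by index) and returns the per-replicate ratios
#' with their mean and SD; this reflects how a fold with its own spread
#' is obtained from triplicate data.
#'
#' @param group A [group_measurements()] or a numeric vector/mean of
#'   percentages.
#' @param sham The sham [group_measurements()] or numeric equivalent.
#' @param mode `"mean-ratio"` or `"replicate"`.
#' @return Scalar fold for `"mean-ratio"`; list with `ratios`, `mean`,
#'   `sd` for `"replicate"`.
#' @export
fold_uptake <- function(group, sham, mode = c("mean-ratio", "replicate")) {
  mode <- match.arg(mode)
  gv <- if (inherits(group, "group_measurements")) group$replicate_values
        else as.numeric(group)
  sv <- if (inherits(sham, "group_measurements")) sham$replicate_values
        else as.numeric(sham)
  if (mean(sv) == 0) stop("fold uptake undefined: sham mean is zero")
  if (mode == "mean-ratio") return(mean(gv) / mean(sv))
  if (length(gv) != length(sv))
    stop("replicate mode requires equal replicate counts")
  if (any(sv == 0)) stop("fold uptake undefined: zero sham replicate")
  r <- gv / sv
  list(ratios = r, mean = mean(r), sd = stats::sd(r))
}

#' Viability as percent of sham
#'
#' `100 * group_count / sham_count`; may exceed 100 when a treated group
#' outgrows the sham.
#'
#' @param group_count Remaining cells in the treated group.
#' @param sham_count Remaining cells in the sham group (> 0).
#' @return Percentage (>= 0, possibly > 100).
#' @export
viability_percent <- function(group_count, sham_count) {
  if (any(sham_count <= 0)) stop("viability undefined: sham count must be > 0")
  stopifnot(all(group_count >= 0))
  100 * group_count / sham_count
}

group_values <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, inherits, logical(1), "group_measurements")))
  vals <- lapply(groups, `[[`, "replicate_values")
  if (any(lengths(vals) < 2))
    stop("each group needs at least 2 replicates")
  vals
}

#' One-way analysis of variance
#'
#' F statistic from the definitional between/within sums of squares and
#' its upper-tail p value from the F distribution.
#'
#' @param groups List of [group_measurements()] (>= 2 groups, each with
#'   >= 2 replicates).
#' @return An object of class `anova_result`: list with `F_statistic`,
#'   `p_value`, `df_between`, `df_within`, `ms_between`, `ms_within`.
#' @export
one_way_anova <- function(groups) {
  vals <- group_values(groups)
  all_v <- unlist(vals, use.names = FALSE)
  k <- length(vals)
  n <- length(all_v)
  grand <- mean(all_v)
  means <- vapply(vals, mean, numeric(1))
  ni <- lengths(vals)
  ss_b <- sum(ni * (means - grand)^2)
  ss_w <- sum(vapply(seq_len(k), function(i)
    sum((vals[[i]] - means[i])^2), numeric(1)))
  if (ss_w == 0)
    stop("degenerate input: zero within-group variance in every group")
  ms_b <- ss_b / (k - 1)
  ms_w <- ss_w / (n - k)
  f <- ms_b / ms_w
  structure(list(F_statistic = f,
                 p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
                 df_between = k - 1, df_within = n - k,
                 ms_between = ms_b, ms_within = ms_w),
            class = "anova_result")
}

significance_stars <- function(p) {
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 0.05, "*", "ns"))))
}

#' Tukey honestly-significant-difference multiple comparisons
#'
#' All unordered pairwise group comparisons with p values adjusted via
#' the studentized range distribution, using the Tukey-Kramer standard
#' error for unequal group sizes:
#' `q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))`, with the adjusted
#' p value the upper-tail probability of the studentized range with `k`
#' groups and the ANOVA within-group degrees of freedom. Two-sided.
#'
#' @param groups List of [group_measurements()] as in [one_way_anova()].
#' @param alpha Familywise significance level used for the `significant`
#'   flag.
#' @return An object of class `tukey_result`: data frame with one row
#'   per unordered pair and columns `group_a`, `group_b`, `mean_diff`,
#'   `adjusted_p`, `significant`, `stars`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  vals <- group_values(groups)
  av <- one_way_anova(groups)
  k <- length(vals)
  means <- vapply(vals, mean, numeric(1))
  ni <- lengths(vals)
  labels <- vapply(groups, `[[`, character(1), "group_label")
  pairs <- utils::combn(k, 2)
  i1 <- pairs[1, ]
  i2 <- pairs[2, ]
  se <- sqrt(av$ms_within / 2 * (1 / ni[i1] + 1 / ni[i2]))
  q <- abs(means[i1] - means[i2]) / se
  p <- stats::ptukey(q, k, av$df_within, lower.tail = FALSE)
  out <- data.frame(group_a = labels[i1], group_b = labels[i2],
                    mean_diff = means[i1] - means[i2],
                    adjusted_p = p, row.names = NULL)
  out$significant <- out$adjusted_p < alpha
  out$stars <- significance_stars(out$adjusted_p)
  class(out) <- c("tukey_result", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Dose-response summary of an experiment table
#'
#' Per-group mean, SD and fold versus sham (both fold modes), plus the
#' optimal delivery PNP: the insonated (`tmb_us_*`) group with the
#' highest mean, ties broken toward the lower pressure.
#'
#' @param table An [experiment_table()].
#' @param fold_mode Default fold mode for the `fold_vs_sham` column.
#' @return An object of class `uptake_summary`: list with `summary` (a
#'   data frame of per-group statistics), `optimal_pnp_kpa`, `molecule`,
#'   `metric`, `timepoint_h`.
#' @export
dose_response_summary <- function(table,
                                  fold_mode = c("mean-ratio", "replicate")) {
  stopifnot(inherits(table, "experiment_table"))
  fold_mode <- match.arg(fold_mode)
  sham <- table$groups[["sham"]]
  rows <- lapply(table$groups, function(g) {
    fold <- if (fold_mode == "mean-ratio") {
      fold_uptake(g, sham, "mean-ratio")
    } else {
      fold_uptake(g, sham, "replicate")$mean
    }
    data.frame(group = g$group_label,
               pnp_kpa = group_pnp_kpa(g$group_label),
               n = g$n_replicates,
               mean = mean(g$replicate_values),
               sd = stats::sd(g$replicate_values),
               fold_vs_sham = fold)
  })
  summ <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ins <- summ[!is.na(summ$pnp_kpa), , drop = FALSE]
  if (nrow(ins) == 0) stop("table has no insonated (tmb_us_*) group")
  ins <- ins[order(ins$pnp_kpa), , drop = FALSE]
  optimal <- ins$pnp_kpa[which.max(ins$mean)]
  structure(list(summary = summ, optimal_pnp_kpa = optimal,
                 molecule = table$molecule, metric = table$metric,
                 timepoint_h = table$timepoint_h,
                 fold_mode = fold_mode),
            class = "uptake_summary")
}

#' @export
print.uptake_summary <- function(x, ...) {
  cat(sprintf("Dose-response summary: %s, %s, %g h (fold mode: %s)\n",
              x$molecule, x$metric, x$timepoint_h, x$fold_mode))
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("optimal PNP: %g kPa\n", x$optimal_pnp_kpa))
  invisible(x)
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$F_statistic, x$p_value))
  invisible(x)
}
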