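make_groups <- function(values_by_label) {
  lapply(names(values_by_label), function(l)
    group_measurements(l, values_by_label[[l]]))
}

test_that("fluorescent fractions and viability are validated ratios", {
  expect_equal(fraction_fluorescent_count(0, 200), 0)
  expect_equal(fraction_fluorescent_count(200, 200), 100)
  expect_equal(fraction_fluorescent_count(115, 200), 57.5)
  expect_error(fraction_fluorescent_count(201, 200), "exceed")
  expect_error(fraction_fluorescent_count(10, 0))

  expect_equal(fraction_fluorescent_area(0, 5000), 0)
  expect_equal(fraction_fluorescent_area(1234, 1234), 100)
  expect_error(fraction_fluorescent_area(2, 1), "exceed")

  expect_equal(viability_percent(500, 500), 100)
  expect_equal(viability_percent(0, 500), 0)
  expect_equal(viability_percent(1281, 10000), 12.81)
  # treated groups may outgrow the sham
  expect_gt(viability_percent(600, 500), 100)
  expect_error(viability_percent(1, 0))
})

test_that("fold uptake supports mean-ratio and replicate-wise modes", {
  expect_equal(fold_uptake(13.23, 0.76), 17.4, tolerance = 1e-3)
  expect_equal(fold_uptake(29.39, 0.77), 38.2, tolerance = 1e-3)
  expect_equal(fold_uptake(42, 42), 1)

  g <- group_measurements("tmb_us_500", c(50, 60, 70))
  s <- group_measurements("sham", c(20, 20, 25))
  expect_equal(fold_uptake(g, s), 60 / mean(c(20, 20, 25)))
  rep_mode <- fold_uptake(g, s, mode = "replicate")
  expect_equal(rep_mode$ratios, c(2.5, 3, 2.8))
  expect_equal(rep_mode$mean, mean(c(2.5, 3, 2.8)))
  expect_equal(rep_mode$sd, sd(c(2.5, 3, 2.8)))
  expect_equal(fold_uptake(s, s, mode = "replicate")$mean, 1)

  expect_error(fold_uptake(10, 0), "sham")
  expect_error(fold_uptake(g, group_measurements("sham", c(1, 2)),
                           mode = "replicate"), "equal replicate")
})

test_that("experiment tables enforce their structural invariants", {
  groups <- make_groups(list(sham = c(20, 21, 22), tmb_us_500 = c(55, 58, 60)))
  tab <- experiment_table("7aad", "count_fraction", 0, groups)
  expect_s3_class(tab, "experiment_table")

  expect_error(experiment_table("7aad", "count_fraction", 0,
                                groups[2]), "sham")
  expect_error(experiment_table("7aad", "count_fraction", 0,
                                c(groups, groups[1])), "sham")
  expect_error(experiment_table("fitc4", "count_fraction", 0, groups),
               "7-AAD")
  expect_error(experiment_table("7aad", "area_fraction", 0, groups),
               "FITC")
  expect_error(group_measurements("sham", c(50, 120)), "\\[0, 100\\]")
  expect_error(group_measurements("mystery", c(1, 2)))

  # CSV round trip preserves the table
  path <- tempfile(fileext = ".csv")
  write_experiment_csv(tab, path)
  back <- read_experiment_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("one-way ANOVA matches the aov oracle and its invariances", {
  set.seed(101)
  labels <- c("sham", "us_only", "tmb_only", "tmb_us_100", "tmb_us_500")
  for (rep in 1:5) {
    vals <- lapply(labels, function(l) runif(3, 10, 90))
    names(vals) <- labels
    groups <- make_groups(vals)
    mine <- one_way_anova(groups)
    df <- data.frame(y = unlist(vals),
                     g = factor(rep(labels, each = 3)))
    ref <- summary(stats::aov(y ~ g, data = df))[[1]]
    expect_equal(mine$F_statistic, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(mine$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)

    # invariance to location shift and positive scaling
    shifted <- make_groups(lapply(vals, function(v) (v + 7) / 3))
    expect_equal(one_way_anova(shifted)$F_statistic, mine$F_statistic,
                 tolerance = 1e-10)
  }

  # equal group means with nonzero spread: F = 0, p = 1
  eq <- make_groups(list(sham = c(49, 50, 51), us_only = c(48, 50, 52)))
  expect_equal(one_way_anova(eq)$F_statistic, 0)
  expect_equal(one_way_anova(eq)$p_value, 1)

  expect_error(one_way_anova(make_groups(
    list(sham = c(5, 5, 5), us_only = c(9, 9, 9)))), "degenerate")
  expect_error(one_way_anova(make_groups(list(sham = c(1, 2)))))
})

test_that("Tukey HSD matches TukeyHSD, the two-group t-test identity, and conservativeness", {
  set.seed(202)
  labels <- c("sham", "us_only", "tmb_us_100", "tmb_us_500")
  vals <- lapply(labels, function(l) runif(3, 10, 90))
  names(vals) <- labels
  groups <- make_groups(vals)
  mine <- tukey_hsd(groups)
  df <- data.frame(y = unlist(vals),
                   g = factor(rep(labels, each = 3), levels = labels))
  ref <- TukeyHSD(stats::aov(y ~ g, data = df))$g
  key <- paste(mine$group_b, mine$group_a, sep = "-")
  expect_true(all(key %in% rownames(ref)))
  expect_equal(mine$adjusted_p, ref[key, "p adj"], tolerance = 1e-8,
               ignore_attr = TRUE)

  # adjusted p never below the unadjusted pooled-variance pairwise p
  av <- one_way_anova(groups)
  for (j in seq_len(nrow(mine))) {
    m1 <- mean(vals[[mine$group_a[j]]])
    m2 <- mean(vals[[mine$group_b[j]]])
    tstat <- abs(m1 - m2) / sqrt(av$ms_within * (2 / 3))
    p_lsd <- 2 * stats::pt(tstat, av$df_within, lower.tail = FALSE)
    expect_gte(mine$adjusted_p[j] + 1e-12, p_lsd)
  }

  # with two groups the adjusted p collapses to the pooled t-test p
  two <- make_groups(vals[1:2])
  tt <- stats::t.test(vals[[1]], vals[[2]], var.equal = TRUE)
  # ptukey is itself computed by quadrature, so allow its documented
  # accuracy rather than full double precision
  expect_equal(tukey_hsd(two)$adjusted_p, tt$p.value, tolerance = 1e-6)

  # a pair of identical groups embedded among others is non-significant
  same <- make_groups(list(sham = c(30, 31, 32), us_only = c(30, 31, 32),
                           tmb_us_500 = c(70, 72, 71)))
  tk <- tukey_hsd(same)
  p_same <- tk$adjusted_p[tk$group_a == "sham" & tk$group_b == "us_only"]
  expect_gt(p_same, 0.99)
  stars <- tk$stars[tk$group_a == "sham" & tk$group_b == "tmb_us_500"]
  expect_true(stars %in% c("***", "****"))
})

test_that("dose-response summary finds the optimal PNP with lower-pressure ties", {
  tab <- experiment_table("7aad", "count_fraction", 0, make_groups(list(
    sham = c(20, 21, 22), us_only = c(23, 24, 25),
    tmb_us_100 = c(21, 21.5, 22), tmb_us_500 = c(55, 58, 60),
    tmb_us_800 = c(50, 52, 54))))
  s <- dose_response_summary(tab)
  expect_equal(s$optimal_pnp_kpa, 500)
  expect_equal(s$summary$fold_vs_sham[s$summary$group == "sham"], 1)

  # exact tie broken toward the lower pressure
  tie <- experiment_table("7aad", "count_fraction", 0, make_groups(list(
    sham = c(20, 21, 22), tmb_us_300 = c(50, 51, 52),
    tmb_us_500 = c(50, 51, 52))))
  expect_equal(dose_response_summary(tie)$optimal_pnp_kpa, 300)

  single <- experiment_table("7aad", "count_fraction", 0, make_groups(list(
    sham = c(20, 21, 22), tmb_us_200 = c(30, 31, 32))))
  expect_equal(dose_response_summary(single)$optimal_pnp_kpa, 200)

  none <- experiment_table("7aad", "count_fraction", 0, make_groups(list(
    sham = c(20, 21, 22), us_only = c(23, 24, 25))))
  expect_error(dose_response_summary(none), "insonated")

  # replicate fold mode flows through the summary
  s2 <- dose_response_summary(tab, fold_mode = "replicate")
  g <- c(55, 58, 60) / c(20, 21, 22)
  expect_equal(s2$summary$fold_vs_sham[s2$summary$group == "tmb_us_500"],
               mean(g))
})
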