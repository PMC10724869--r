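test_that("level subsamples are the per-sex extremes, deterministic under ties", {
  meta <- data.frame(subject_id = sprintf("s%02d", 1:20),
                     sex = factor(rep(c("male", "female"), each = 10),
                                  levels = c("male", "female")),
                     age = 21, handedness = "right", stringsAsFactors = FALSE)
  q <- data.frame(subject_id = meta$subject_id,
                  CJV = c(10:1, 1:10) / 10, CNR = 3.5, EFC = 0.45,
                  INU = 0.95, WM2MAX = 0.7, stringsAsFactors = FALSE)
  sel <- select_level_subsamples(q, meta, "CJV", n_per_level = 3)
  expect_equal(sel$lower, sort(c("s08", "s09", "s10", "s11", "s12", "s13")))
  expect_equal(sel$upper, sort(c("s01", "s02", "s03", "s18", "s19", "s20")))
  expect_length(intersect(sel$lower, sel$upper), 0)
  # all-tied metric: selection falls back to subject-id order, reproducibly
  sel_tie1 <- select_level_subsamples(q, meta, "CNR", n_per_level = 4)
  sel_tie2 <- select_level_subsamples(q, meta, "CNR", n_per_level = 4)
  expect_identical(sel_tie1$lower, sel_tie2$lower)
  expect_identical(sel_tie1$upper, sel_tie2$upper)
  expect_error(select_level_subsamples(q, meta, "CJV", n_per_level = 50),
               "n_per_level")
})

test_that("sex-shifted IQMs are audited and can trigger a mismatch warning", {
  set.seed(2)
  meta <- data.frame(subject_id = sprintf("s%02d", 1:40),
                     sex = factor(rep(c("male", "female"), each = 20),
                                  levels = c("male", "female")),
                     age = 21, handedness = "right", stringsAsFactors = FALSE)
  q <- data.frame(subject_id = meta$subject_id,
                  CJV = c(rnorm(20, 0.6, 0.01), rnorm(20, 0.3, 0.01)),
                  CNR = 3.5, EFC = 0.45, INU = 0.95, WM2MAX = 0.7,
                  stringsAsFactors = FALSE)
  w <- testthat::capture_warnings(
    sel <- select_level_subsamples(q, meta, "CJV", n_per_level = 5))
  expect_true(any(grepl("matching is poor", w)))
  ach <- sel$achieved
  m_low <- ach$mean[ach$level == "lower" & ach$sex == "male"]
  f_low <- ach$mean[ach$level == "lower" & ach$sex == "female"]
  expect_gt(m_low, f_low)  # the shift survives into the audited means
})

test_that("significance tiers are a pure function of p with exact boundaries", {
  grid <- c(0, 1e-6, 0.0009999, 0.001, 0.01, 0.049999, 0.05, 0.5, 1)
  expect_equal(p_tier(grid),
               c("*", "*", "*", "x", "x", "x", "ns", "ns", "ns"))
  expect_true(is.na(p_tier(NA)))
})

test_that("profile t-test matches the textbook paired formula and trivial cases", {
  meta <- data.frame(subject_id = c("m1", "m2", "f1", "f2"),
                     sex = factor(c("male", "male", "female", "female"),
                                  levels = c("male", "female")),
                     age = 21, stringsAsFactors = FALSE)
  base <- matrix(rep(seq(0.1, 0.43, 0.01), each = 4), 4, 34,
                 dimnames = list(meta$subject_id, dk_atlas()))
  # identical profiles -> degenerate zero difference
  tt0 <- profile_ttest(base, meta)
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p, 1)
  expect_equal(tt0$tier, "ns")
  # constant male shift + tiny ROI-wise noise -> large positive t, tier "*"
  set.seed(14)
  noise <- rep(rnorm(34, 0, 1e-4), each = 4) * (row(base) <= 2)
  shifted <- base + 0.05 * (row(base) <= 2) + noise
  tt <- profile_ttest(shifted, meta)
  d <- colMeans(shifted[1:2, ]) - colMeans(shifted[3:4, ])
  t_ref <- mean(d) / (sd(d) / sqrt(34))
  expect_equal(tt$t, t_ref, tolerance = 1e-12)
  expect_equal(tt$tier, "*")
  expect_equal(tt$direction, 1)
  # exactly constant shift -> degenerate infinite-magnitude flag
  tt_inf <- profile_ttest(base + 0.05 * (row(base) <= 2), meta)
  expect_true(is.infinite(tt_inf$t) && tt_inf$t > 0)
  expect_equal(tt_inf$p, 0)
  expect_true(tt_inf$degenerate)
})

test_that("robustness report covers all cells and mirrors the planted regime", {
  cfg <- sim_config(n_male = 40, n_female = 40,
                    coherence_sd = c(male = 0.06, female = 0.015),
                    measures = "volume")
  coh <- generate_cohort(cfg, seed = 23)
  tables <- list(volume = compute_index_tables(coh$morphometry$volume))
  rb <- suppressWarnings(robustness_report(tables, coh$meta, coh$quality,
                                           n_per_level = 10, n_override = c(EFC = 5)))
  r <- rb$report
  expect_equal(nrow(r), 5 * 2 * 3)  # metrics x levels x indices
  expect_true(all(table(r$metric, r$level) == 3))
  expect_equal(unique(r$n_per_sex[r$metric == "EFC"]), 5)
  expect_true(all(r$tier == p_tier(r$p)))
  # strong coherence effect: DI rows significant at both levels of every metric
  expect_true(all(r$p[r$index == "DI"] < 0.05))
  expect_true(all(r$male_mean[r$index == "DI"] > r$female_mean[r$index == "DI"]))
})

test_that("verdicts follow the both/preferred-only/neither rule", {
  mk <- function(p_lower, p_upper, metric = "CNR") {
    structure(list(report = data.frame(
      metric = metric, level = c("lower", "upper"), index = "DI",
      measure = "volume", t = 1, p = c(p_lower, p_upper),
      tier = p_tier(c(p_lower, p_upper)), male_mean = 1, female_mean = 0,
      n_per_sex = 10, unreliable = FALSE, stringsAsFactors = FALSE)),
      class = "asym_robustness")
  }
  expect_equal(classify_outcome(mk(1e-4, 1e-4))$verdict, "robust")
  # CNR prefers the upper (high-quality) level
  expect_equal(classify_outcome(mk(0.5, 1e-3))$verdict, "quality-sensitive")
  expect_equal(classify_outcome(mk(1e-3, 0.5))$verdict, "not-robust")
  expect_equal(classify_outcome(mk(0.5, 0.5))$verdict, "not-robust")
  # CJV prefers the lower level
  expect_equal(classify_outcome(mk(1e-3, 0.5, "CJV"))$verdict, "quality-sensitive")
})
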