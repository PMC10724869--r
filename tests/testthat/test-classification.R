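test_that("stratified split honours fractions, stratification and seed", {
  labels <- factor(rep(c("male", "female"), each = 50), levels = c("male", "female"))
  sp <- split_train_test(labels, 0.8, seed = 4)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_equal(as.integer(table(labels[sp$train])), c(40L, 40L))
  expect_equal(as.integer(table(labels[sp$test])), c(10L, 10L))
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  expect_identical(sp, split_train_test(labels, 0.8, seed = 4))
  sp5 <- split_train_test(factor(rep(c("a", "b"), 5)), 0.5, seed = 1)
  expect_length(sp5$train, 5)
  expect_length(sp5$test, 5)
})

test_that("Cohen's kappa matches the closed form and brute-force oracle", {
  conf <- matrix(c(40, 20, 10, 30), 2)  # [[40,10],[20,30]] pred rows x target cols
  expect_equal(cohens_kappa(conf), 0.40, tolerance = 1e-12)
  expect_equal(cohens_kappa(diag(c(30, 70))), 1)
  set.seed(8)
  for (k in 1:50) {
    m <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (sum(m) == 0) next
    pe_one <- sum(rowSums(m) * colSums(m)) == sum(m)^2
    if (pe_one) next
    expect_equal(cohens_kappa(m), unname(naive_kappa(m)), tolerance = 1e-12)
    expect_equal(cohens_kappa(m), e1071::classAgreement(m)$kappa, tolerance = 1e-12)
    expect_true(cohens_kappa(m) >= -1 && cohens_kappa(m) <= 1)
  }
  # always-predict-majority: accuracy = NIR, kappa = 0
  maj <- matrix(c(60, 0, 40, 0), 2)
  expect_equal(sum(diag(maj)) / sum(maj), 0.6)  # = NIR
  expect_equal(cohens_kappa(maj), 0)
})

test_that("NIR binomial tail matches direct pmf summation and closed forms", {
  expect_equal(nir_test(60, 100, 0.5), naive_binom_tail(60, 100, 0.5),
               tolerance = 1e-12)
  expect_equal(nir_test(60, 100, 0.5), 0.0284, tolerance = 2e-3)
  expect_equal(nir_test(100, 100, 0.55), 0.55^100, tolerance = 1e-12)
  expect_gt(nir_test(50, 100, 0.5), 0.4)  # at the null center
  expect_error(nir_test(10, 20, 1), "nir")
  expect_error(nir_test(10, 20, 0), "nir")
})

test_that("a perfectly separating predictor yields accuracy 1 and plants rank first", {
  set.seed(5)
  n <- 120
  y <- factor(rep(c("male", "female"), each = n / 2), levels = c("male", "female"))
  x <- data.frame(matrix(rnorm(n * 5), n, 5))
  names(x) <- paste0("noise", 1:5)
  x$signal <- ifelse(y == "male", 1, 0) + rnorm(n, 0, 0.01)
  sp <- split_train_test(y, 0.8, seed = 5)
  fit <- train_random_forest(x[sp$train, ], y[sp$train], ntree = 200, seed = 5)
  ev <- evaluate_model(fit, x[sp$test, ], y[sp$test])
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$kappa, 1)
  expect_equal(ev$importances$predictor[1], "signal")
  expect_equal(ev$top6[1], "signal")
  expect_equal(sum(ev$confusion), length(sp$test))
})

test_that("duplicated informative predictors both rank near the top", {
  set.seed(6)
  n <- 150
  y <- factor(rep(c("male", "female"), each = n / 2))
  x <- data.frame(matrix(rnorm(n * 8), n, 8))
  names(x) <- paste0("noise", 1:8)
  x$sig_a <- ifelse(y == "male", 0.8, 0) + rnorm(n, 0, 0.3)
  x$sig_b <- x$sig_a
  fit <- train_random_forest(x, y, ntree = 300, seed = 6)
  ranks <- rank_predictors(fit)$importances
  expect_true(all(c("sig_a", "sig_b") %in% ranks$predictor[1:3]))
})

test_that("pure-noise labels give chance-level cross-validated behaviour", {
  set.seed(9)
  n <- 100
  y <- factor(rep(c("male", "female"), each = n / 2))
  x <- data.frame(matrix(rnorm(n * 10), n, 10))
  fit <- train_random_forest(x, y, cv_folds = 5, mtry_grid = c(2, 5), ntree = 150,
                             seed = 9)
  expect_true(all(abs(fit$cv_accuracy - 0.5) < 3 * sqrt(0.25 / n)))
  expect_true(fit$mtry %in% c(2, 5))
})

test_that("constant predictors are dropped with a warning; all-constant errors", {
  y <- factor(rep(c("male", "female"), each = 20))
  x <- data.frame(flat = rep(1, 40), ok = rnorm(40))
  expect_warning(fit <- train_random_forest(x, y, ntree = 50, seed = 1), "constant")
  expect_equal(fit$predictors, "ok")
  expect_error(
    suppressWarnings(train_random_forest(data.frame(flat = rep(1, 40)), y)),
    "constant")
})

test_that("classify_sex pipeline is deterministic and well-formed on an effect cohort", {
  cfg <- sim_config(n_male = 60, n_female = 60,
                    coherence_sd = c(male = 0.05, female = 0.015),
                    measures = "volume")
  coh <- generate_cohort(cfg, seed = 12)
  ix <- compute_index_tables(coh$morphometry$volume, kinds = "DI")
  a <- classify_sex(ix$DI, coh$meta, ntree = 200, seed = 3)
  b <- classify_sex(ix$DI, coh$meta, ntree = 200, seed = 3)
  expect_identical(a$confusion, b$confusion)
  expect_identical(a$importances, b$importances)
  expect_equal(a$accuracy, sum(diag(a$confusion)) / sum(a$confusion))
  expect_equal(a$nir, max(colSums(a$confusion)) / sum(a$confusion))
  expect_equal(nrow(a$importances), 35)  # 34 ROIs + age
  expect_gt(a$accuracy, a$nir)  # strong planted effect
  expect_equal(rownames(a$confusion), c("male", "female"))
})

test_that("age is not systematically top-ranked on null cohorts", {
  ranks <- vapply(1:8, function(sd) {
    coh <- small_cohort(n = 25, seed = 500 + sd)
    ix <- compute_index_tables(coh$morphometry$volume, kinds = "DI")
    cl <- classify_sex(ix$DI, coh$meta, ntree = 100, seed = sd)
    which(cl$importances$predictor == "age")
  }, 0L)
  expect_gt(mean(ranks), 5)  # age not consistently at the top of 35 predictors
})
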