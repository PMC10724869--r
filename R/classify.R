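#' Stratified train/test split
#'
#' Random split stratified by class label at the configured training fraction;
#' partitions are disjoint, exhaustive and reproducible from the seed.
#'
#' @param labels factor of class labels (one per subject).
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
split_train_test <- function(labels, train_frac = 0.8, seed = 1L) {
  stopifnot(is.factor(labels), train_frac > 0, train_frac < 1)
  if (any(table(labels) < 2L)) stop("need >= 2 subjects per class")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  # largest-remainder allocation so the overall training count is
  # round(train_frac * n) while staying stratified
  n_class <- table(labels)
  raw <- train_frac * as.numeric(n_class)
  n_tr <- floor(raw)
  short <- round(train_frac * length(labels)) - sum(n_tr)
  if (short > 0) {
    give <- order(-(raw - n_tr))[seq_len(short)]
    n_tr[give] <- n_tr[give] + 1L
  }
  n_tr <- pmax(1L, pmin(as.numeric(n_class) - 1L, n_tr))
  train <- integer(0)
  for (k in seq_along(levels(labels))) {
    idx <- which(labels == levels(labels)[k])
    train <- c(train, sample(idx, n_tr[k]))
  }
  train <- sort(train)
  test <- setdiff(seq_along(labels), train)
  if (!length(test) || length(unique(labels[test])) < 2L ||
      length(unique(labels[train])) < 2L)
    stop("a class is absent from one partition; adjust train_frac or n")
  list(train = train, test = test)
}

#' Train a random-forest classifier with optional grid-tuned mtry
#'
#' Bootstrap-aggregated forest on the training partition. When a grid of
#' candidate values for the per-split predictor-subset size (\code{mtry}) is
#' supplied, it is selected by k-fold cross-validation on the training
#' partition only, and the final forest is refit on the full training set.
#' Constant predictor columns are dropped with a warning.
#'
#' @param x numeric predictor matrix/data.frame (rows = subjects).
#' @param y factor of class labels.
#' @param cv_folds folds for the tuning cross-validation (default 10).
#' @param mtry_grid integer candidates for mtry; \code{NULL} (default) skips
#'   tuning and uses the forest default (sqrt(p)).
#' @param ntree number of trees (default 500).
#' @param seed integer seed.
#' @return list of class \code{asym_rf} with the fitted forest, the selected
#'   mtry, CV accuracies per grid value, and provenance fields.
#' @export
train_random_forest <- function(x, y, cv_folds = 10L, mtry_grid = NULL,
                                ntree = 500L, seed = 1L) {
  x <- as.data.frame(x)
  y <- droplevels(as.factor(y))
  stopifnot(nrow(x) == length(y))
  const <- vapply(x, function(col) length(unique(col)) <= 1L, TRUE)
  if (all(const)) stop("all predictor columns are constant")
  if (any(const)) {
    warning("dropping constant predictor column(s): ",
            paste(names(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  cv_acc <- NULL
  mtry <- max(1L, floor(sqrt(ncol(x))))
  if (!is.null(mtry_grid) && length(mtry_grid)) {
    mtry_grid <- sort(unique(pmin(as.integer(mtry_grid), ncol(x))))
    if (length(mtry_grid) > 1L && cv_folds >= 2L) {
      fold <- .stratified_folds(y, cv_folds)
      cv_acc <- vapply(mtry_grid, function(mt) {
        hits <- 0L
        for (f in seq_len(max(fold))) {
          tr <- fold != f
          fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                            mtry = mt, ntree = ntree)
          hits <- hits + sum(stats::predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
        }
        hits / length(y)
      }, 0)
      names(cv_acc) <- mtry_grid
      mtry <- mtry_grid[which.max(cv_acc)]  # ties -> smallest mtry
    } else {
      mtry <- mtry_grid[1]
    }
  }
  fit <- randomForest::randomForest(x, y, mtry = mtry, ntree = ntree,
                                    importance = TRUE)
  structure(list(fit = fit, mtry = mtry, cv_accuracy = cv_acc,
                 cv_folds = if (is.null(cv_acc)) NA_integer_ else as.integer(cv_folds),
                 grid = mtry_grid, ntree = as.integer(ntree),
                 seed = as.integer(seed), predictors = colnames(x)),
            class = "asym_rf")
}

.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' @export
print.asym_rf <- function(x, ...) {
  cat("Random forest (", x$ntree, " trees, mtry = ", x$mtry, ")\n", sep = "")
  if (!is.null(x$cv_accuracy)) {
    cat("CV accuracy over mtry grid:\n"); print(round(x$cv_accuracy, 4))
  }
  invisible(x)
}

#' Cohen's kappa from a 2x2 confusion matrix
#'
#' Chance-corrected agreement \code{(p_o - p_e) / (1 - p_e)} where \code{p_o}
#' is observed accuracy and \code{p_e} the agreement expected from the row and
#' column marginals.
#'
#' @param confusion square integer matrix, predictions in rows, targets in
#'   columns.
#' @return kappa in [-1, 1]; \code{NaN} when \code{p_e == 1}.
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  (po - pe) / (1 - pe)
}

#' One-sided exact binomial test of accuracy against the no-information rate
#'
#' \code{P(X >= correct)} for \code{X ~ Binomial(n_test, nir)}: the
#' probability of doing at least this well by always-guessing at the majority
#' class prevalence.
#'
#' @param correct_count correct test-set predictions.
#' @param n_test test-set size.
#' @param nir no-information rate (majority-class prevalence in the test set).
#' @return p-value.
#' @export
nir_test <- function(correct_count, n_test, nir) {
  stopifnot(correct_count >= 0, correct_count <= n_test)
  if (nir <= 0 || nir >= 1) stop("nir must be in (0, 1)")
  stats::pbinom(correct_count - 1L, n_test, nir, lower.tail = FALSE)
}

#' Evaluate a fitted classifier on a held-out test partition
#'
#' Builds the 2x2 confusion matrix (targets on columns, predictions on rows,
#' male first), with row/column percentages, accuracy, Cohen's kappa, the
#' no-information rate and the one-sided exact binomial p-value of accuracy
#' against it, plus the ranked predictor importances.
#'
#' @param model an \code{asym_rf}.
#' @param x_test,y_test held-out predictors and labels.
#' @return object of class \code{asym_classification}.
#' @export
evaluate_model <- function(model, x_test, y_test) {
  stopifnot(inherits(model, "asym_rf"))
  x_test <- as.data.frame(x_test)[, model$predictors, drop = FALSE]
  if (!nrow(x_test)) stop("empty test set")
  y_test <- factor(y_test, levels = levels(model$fit$y))
  prob <- stats::predict(model$fit, x_test, type = "prob")
  # deterministic 0.5 tie-break: lexicographically first class label
  first <- sort(levels(y_test))[1]
  pred <- ifelse(prob[, first] >= 0.5, first,
                 setdiff(levels(y_test), first))
  pred <- factor(pred, levels = levels(y_test))
  confusion <- table(prediction = pred, target = y_test)
  n <- sum(confusion)
  accuracy <- sum(diag(confusion)) / n
  nir <- max(colSums(confusion)) / n
  imp <- rank_predictors(model)
  structure(list(confusion = confusion,
                 col_pct = sweep(confusion, 2, colSums(confusion), "/"),
                 row_pct = sweep(confusion, 1, rowSums(confusion), "/"),
                 accuracy = accuracy,
                 kappa = cohens_kappa(confusion),
                 nir = nir,
                 p_value = nir_test(sum(diag(confusion)), n, nir),
                 importances = imp$importances, top6 = imp$top6,
                 split_seed = model$seed, cv_folds = model$cv_folds,
                 grid = model$grid),
            class = "asym_classification")
}

#' Rank predictors by permutation importance
#'
#' Out-of-bag permutation importance (mean decrease in accuracy) per
#' predictor, sorted descending with ties broken alphabetically for
#' determinism; the forest's impurity importance (mean decrease in Gini) is
#' carried alongside for comparison.
#'
#' @param model an \code{asym_rf}.
#' @return list with \code{importances} (data.frame: predictor,
#'   importance, gini, rank) and \code{top6} (character).
#' @export
rank_predictors <- function(model) {
  stopifnot(inherits(model, "asym_rf"))
  imp <- randomForest::importance(model$fit)
  df <- data.frame(predictor = rownames(imp),
                   importance = imp[, "MeanDecreaseAccuracy"],
                   gini = imp[, "MeanDecreaseGini"],
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(-df$importance, df$predictor), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  list(importances = df, top6 = utils::head(df$predictor, 6L))
}

#' @export
print.asym_classification <- function(x, ...) {
  cat("Confusion matrix (rows = prediction, cols = target):\n")
  print(x$confusion)
  cat(sprintf("Accuracy %.3f | NIR %.3f | P(Acc > NIR) %.4g | Kappa %.3f (%s)\n",
              x$accuracy, x$nir, x$p_value, x$kappa, kappa_label(x$kappa)))
  cat("Top predictors:", paste(x$top6, collapse = ", "), "\n")
  invisible(x)
}

#' Conventional qualitative label for a kappa value
#'
#' Rule-of-thumb bands: below 0 worse than chance, up to 0.20 poor, 0.20-0.40
#' fair, 0.40-0.60 good, above 0.60 very good. Reported as a label only; no
#' decision in the pipeline depends on it.
#' @param kappa numeric.
#' @export
kappa_label <- function(kappa) {
  cut(kappa, breaks = c(-Inf, 0, 0.20, 0.40, 0.60, Inf),
      labels = c("worse than chance", "poor", "fair", "good", "very good"),
      right = TRUE)
}

#' Sex classification from an asymmetry index table
#'
#' Convenience wrapper for the full per-(index, measure) evaluation: stratified
#' 80/20 split, forest training (optionally mtry-tuned by cross-validation on
#' the training partition), and held-out evaluation. Predictors are the 34
#' per-ROI index values plus age.
#'
#' @param index_matrix subjects x 34 matrix of index values.
#' @param meta participants data.frame (provides \code{sex} and \code{age},
#'   matched by \code{subject_id} to the matrix rownames).
#' @param train_frac training fraction.
#' @param cv_folds,mtry_grid,ntree forwarded to
#'   \code{\link{train_random_forest}}.
#' @param seed integer seed controlling split and forest.
#' @return an \code{asym_classification}.
#' @export
classify_sex <- function(index_matrix, meta, train_frac = 0.8,
                         cv_folds = 10L, mtry_grid = NULL, ntree = 500L,
                         seed = 1L) {
  idx <- match(rownames(index_matrix), meta$subject_id)
  if (anyNA(idx)) stop("subjects in index table missing from participants table")
  y <- droplevels(factor(meta$sex[idx], levels = c("male", "female")))
  x <- data.frame(index_matrix, age = meta$age[idx], check.names = TRUE)
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  sp <- split_train_test(y, train_frac, seed = seed)
  model <- train_random_forest(x[sp$train, , drop = FALSE], y[sp$train],
                               cv_folds = cv_folds, mtry_grid = mtry_grid,
                               ntree = ntree, seed = seed)
  evaluate_model(model, x[sp$test, , drop = FALSE], y[sp$test])
}
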