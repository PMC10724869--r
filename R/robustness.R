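#' Significance tier for a p-value
#'
#' The three-level convention used throughout the reports: \code{"*"} if
#' p < 0.001, \code{"x"} if 0.001 <= p < 0.05, \code{"ns"} otherwise
#' (boundaries fall in the weaker tier).
#' @param p numeric vector of p-values.
#' @return character vector of tiers.
#' @export
p_tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "*", ifelse(p < 0.05, "x", "ns")))
}

# preferred (better-quality) level per metric: CNR/INU/WM2MAX better high,
# CJV/EFC better low
.iqm_preferred_level <- c(CJV = "lower", CNR = "upper", EFC = "lower",
                          INU = "upper", WM2MAX = "upper")

#' Select lower/upper image-quality subsamples
#'
#' Within each sex, subjects are sorted ascending by the metric (ties broken
#' by subject id for determinism); the first \code{n_per_level} per sex form
#' the lower subsample and the last \code{n_per_level} the upper one, so both
#' levels are matched in per-sex size. Achieved per-sex metric means are
#' attached so matching quality is auditable; a warning is emitted when the
#' male and female means in a subsample differ by more than
#' \code{match_tol} SDs of the metric.
#'
#' @param quality IQM data.frame (from \code{\link{read_quality}} or the
#'   generator).
#' @param meta participants data.frame.
#' @param metric one of CJV, CNR, EFC, INU, WM2MAX.
#' @param n_per_level subjects per sex per level.
#' @param match_tol audit tolerance in metric SD units (default 1).
#' @return list with character vectors \code{lower}, \code{upper} (subject
#'   ids) and data.frame \code{achieved} (per level x sex metric means).
#' @export
select_level_subsamples <- function(quality, meta, metric, n_per_level = 80L,
                                    match_tol = 1) {
  stopifnot(metric %in% .iqm_names)
  df <- merge(quality[, c("subject_id", metric)],
              meta[, c("subject_id", "sex")], by = "subject_id")
  df <- df[is.finite(df[[metric]]), , drop = FALSE]
  pick <- function(sx) {
    sub <- df[df$sex == sx, , drop = FALSE]
    if (nrow(sub) < n_per_level)
      stop("only ", nrow(sub), " ", sx, " subjects available for ", metric,
           "; n_per_level = ", n_per_level)
    ord <- order(sub[[metric]], sub$subject_id)
    list(lower = sub$subject_id[ord[seq_len(n_per_level)]],
         upper = sub$subject_id[rev(ord)[seq_len(n_per_level)]])
  }
  male <- pick("male"); female <- pick("female")
  achieved <- expand.grid(level = c("lower", "upper"), sex = c("male", "female"),
                          stringsAsFactors = FALSE)
  achieved$mean <- mapply(function(lv, sx) {
    ids <- if (sx == "male") male[[lv]] else female[[lv]]
    mean(df[[metric]][match(ids, df$subject_id)])
  }, achieved$level, achieved$sex)
  sdm <- stats::sd(df[[metric]])
  for (lv in c("lower", "upper")) {
    gap <- abs(diff(achieved$mean[achieved$level == lv]))
    if (is.finite(sdm) && sdm > 0 && gap > match_tol * sdm)
      warning("male/female ", metric, " means differ by ",
              signif(gap, 3), " in the ", lv, " subsample (> ", match_tol,
              " SD); matching is poor")
  }
  list(lower = sort(c(male$lower, female$lower)),
       upper = sort(c(male$upper, female$upper)),
       achieved = achieved, metric = metric, n_per_level = as.integer(n_per_level))
}

#' Paired male-female t-test over per-ROI index profiles
#'
#' For the given subjects, the per-ROI mean index is computed within males and
#' within females, giving two 34-vectors paired by ROI; a paired t-test across
#' the 34 ROI pairs compares the sexes. ROIs undefined in either sex are
#' excluded pairwise.
#'
#' @param index_matrix subjects x 34 index matrix.
#' @param meta participants data.frame.
#' @param ids optional subject-id subset (default: all rows).
#' @return list: \code{t}, \code{p}, \code{df}, \code{tier},
#'   \code{male_profile}, \code{female_profile}, \code{n_male},
#'   \code{n_female}, \code{n_roi}, \code{direction}, \code{degenerate}.
#' @export
profile_ttest <- function(index_matrix, meta, ids = NULL) {
  if (is.null(ids)) ids <- rownames(index_matrix)
  ids <- intersect(ids, rownames(index_matrix))
  sex <- meta$sex[match(ids, meta$subject_id)]
  males <- ids[sex == "male"]; females <- ids[sex == "female"]
  if (length(males) < 1L || length(females) < 1L) stop("both sexes required")
  mp <- colMeans(index_matrix[males, , drop = FALSE], na.rm = TRUE)
  fp <- colMeans(index_matrix[females, , drop = FALSE], na.rm = TRUE)
  ok <- is.finite(mp) & is.finite(fp)
  d <- mp[ok] - fp[ok]
  if (length(d) < 3L) stop("fewer than 3 defined ROI pairs")
  if (.degenerate_diffs(d)) {
    # all ROI differences (numerically) identical: degenerate paired t
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
    return(list(t = t_stat, p = p, df = length(d) - 1L, tier = p_tier(p),
                male_profile = mp, female_profile = fp,
                n_male = length(males), n_female = length(females),
                n_roi = length(d), direction = sign(mean(d)), degenerate = TRUE))
  }
  tt <- stats::t.test(mp[ok], fp[ok], paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       tier = p_tier(tt$p.value), male_profile = mp, female_profile = fp,
       n_male = length(males), n_female = length(females),
       n_roi = length(d), direction = sign(mean(d)), degenerate = FALSE)
}

# paired differences with (numerically) zero spread; mirrors the guard
# stats::t.test applies before erroring on constant data
.degenerate_diffs <- function(d) {
  stats::sd(d) == 0 || stats::sd(d) < 1e-10 * abs(mean(d))
}

#' Image-quality stratified robustness report
#'
#' For every combination of quality metric, level (lower/upper extreme of the
#' metric), index and measure, runs the paired male-female profile t-test of
#' \code{\link{profile_ttest}} within the level's subsample and assigns the
#' significance tier. Rows where more than 20\% of ROI means are undefined are
#' flagged unreliable.
#'
#' @param index_tables named list: \code{tables[[measure]]} is an
#'   \code{asym_indices} object.
#' @param meta participants data.frame.
#' @param quality IQM data.frame.
#' @param n_per_level subjects per sex per level (default 80).
#' @param n_override named per-metric overrides, default \code{c(EFC = 35)}:
#'   the entropy-focus criterion typically needs strong polarization because
#'   its female distribution is much more homogeneous than the male one.
#' @param metrics which metrics to test.
#' @return object of class \code{asym_robustness}: data.frame \code{report}
#'   with columns metric, level, index, measure, t, p, tier, male_mean,
#'   female_mean, n_per_sex, unreliable; plus \code{subsamples}.
#' @export
robustness_report <- function(index_tables, meta, quality, n_per_level = 80L,
                              n_override = c(EFC = 35L), metrics = .iqm_names) {
  rows <- list(); subsamples <- list()
  for (metric in metrics) {
    n_lvl <- if (metric %in% names(n_override)) n_override[[metric]] else n_per_level
    sel <- select_level_subsamples(quality, meta, metric, n_per_level = n_lvl)
    subsamples[[metric]] <- sel
    for (level in c("lower", "upper")) {
      ids <- sel[[level]]
      for (measure in names(index_tables)) {
        ix <- index_tables[[measure]]
        for (kind in intersect(c("DI", "LI", "SI"), names(ix))) {
          tt <- profile_ttest(ix[[kind]], meta, ids = ids)
          rows[[length(rows) + 1L]] <- data.frame(
            metric = metric, level = level, index = kind, measure = measure,
            t = tt$t, p = tt$p, tier = tt$tier,
            male_mean = mean(tt$male_profile, na.rm = TRUE),
            female_mean = mean(tt$female_profile, na.rm = TRUE),
            n_per_sex = n_lvl,
            unreliable = tt$n_roi < 0.8 * 34,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(report = do.call(rbind, rows), subsamples = subsamples),
            class = "asym_robustness")
}

#' @export
print.asym_robustness <- function(x, ...) {
  r <- x$report
  cat("Robustness report:", nrow(r), "metric x level x index x measure tests\n")
  tab <- stats::xtabs(~ index + tier, data = r)
  print(tab)
  invisible(x)
}

#' Robustness verdict per (index, measure, metric)
#'
#' An index is a \code{robust} biomarker for a metric when the male-female
#' difference is significant at both quality extremes; \code{quality-sensitive}
#' when significant only at the metric's preferred (better-quality) level
#' (lower for CJV/EFC, upper for CNR/INU/WM2MAX); \code{not-robust} otherwise.
#'
#' @param x an \code{asym_robustness}.
#' @param alpha significance threshold (default 0.05, i.e. tier != "ns").
#' @return data.frame with columns index, measure, metric, verdict.
#' @export
classify_outcome <- function(x, alpha = 0.05) {
  r <- x$report
  key <- unique(r[, c("index", "measure", "metric")])
  key$verdict <- apply(key, 1L, function(k) {
    sub <- r[r$index == k[["index"]] & r$measure == k[["measure"]] &
               r$metric == k[["metric"]], ]
    sig <- stats::setNames(sub$p < alpha, sub$level)
    pref <- .iqm_preferred_level[[k[["metric"]]]]
    if (all(sig[c("lower", "upper")])) "robust"
    else if (sig[[pref]] && !sig[[setdiff(c("lower", "upper"), pref)]]) "quality-sensitive"
    else "not-robust"
  })
  rownames(key) <- NULL
  key
}
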