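#' Whole-cohort male-female group contrast for one index table
#'
#' Per-ROI group mean profiles by sex and the paired t-test across the 34 ROI
#' pairs, with significance tier and direction (sign of mean male - female).
#' Degenerate cases (all paired differences identical) are reported with an
#' infinite-magnitude t flag and p = 0 rather than a numeric overflow.
#'
#' @param index_matrix subjects x 34 index matrix.
#' @param meta participants data.frame.
#' @param index_kind,measure labels carried into the result.
#' @return object of class \code{asym_group_contrast}.
#' @export
group_contrast <- function(index_matrix, meta, index_kind = NA_character_,
                           measure = NA_character_) {
  tt <- profile_ttest(index_matrix, meta)
  structure(c(tt, list(index_kind = index_kind, measure = measure,
                       p_bonferroni = min(1, tt$p * 12))),
            class = "asym_group_contrast")
}

#' @export
print.asym_group_contrast <- function(x, ...) {
  dir_lab <- if (is.na(x$direction) || x$direction == 0) "male = female"
             else if (x$direction > 0) "male > female" else "male < female"
  cat(sprintf("Group contrast %s %s: paired t(%d) = %.3f, p = %.4g [%s], %s\n",
              x$index_kind, x$measure, x$df, x$t, x$p, x$tier, dir_lab))
  if (isTRUE(x$degenerate)) cat("  (degenerate: zero-variance paired differences)\n")
  invisible(x)
}

#' Per-ROI point-biserial sex correlation profile
#'
#' Pearson correlation of each ROI's values against the binary sex coding
#' (male = 0, female = 1), the per-measure grand mean over defined ROIs, and
#' the grand mean of absolute coefficients. Zero-variance ROI columns are
#' undefined and excluded.
#'
#' @param value_matrix subjects x 34 matrix (index values or one hemisphere's
#'   raw values).
#' @param meta participants data.frame.
#' @return list: \code{r} (named 34-vector, NA where undefined),
#'   \code{grand_mean}, \code{grand_mean_abs}, \code{n_defined}.
#' @export
sex_correlation_profile <- function(value_matrix, meta) {
  code <- .sex_code(meta, rownames(value_matrix))
  if (length(unique(code)) < 2L) stop("both sexes required")
  r <- apply(value_matrix, 2L, function(v) {
    ok <- is.finite(v)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0) return(NA_real_)
    stats::cor(v[ok], code[ok])
  })
  list(r = r, grand_mean = mean(r, na.rm = TRUE),
       grand_mean_abs = mean(abs(r), na.rm = TRUE),
       n_defined = sum(is.finite(r)))
}

.sex_code <- function(meta, ids) {
  sex <- meta$sex[match(ids, meta$subject_id)]
  if (anyNA(sex)) stop("subjects missing from participants table")
  ifelse(sex == "male", 0, 1)
}

#' Hemisphere contrast of sex-correlation profiles
#'
#' Computes the per-ROI sex-correlation profile separately from the raw left
#' and right hemisphere values and compares the two 34-vectors of coefficients
#' with a paired t-test. A non-significant result indicates that neither
#' hemisphere alone carries systematically stronger sex cues.
#'
#' @param morph a \code{\link{morph_table}}.
#' @param meta participants data.frame.
#' @return list: \code{left_r}, \code{right_r} (profiles), \code{left_mean},
#'   \code{right_mean}, \code{t}, \code{p}, \code{df}, \code{tier}.
#' @export
hemisphere_contrast <- function(morph, meta) {
  stopifnot(inherits(morph, "morph_table"))
  lr <- sex_correlation_profile(morph$left, meta)
  rr <- sex_correlation_profile(morph$right, meta)
  ok <- is.finite(lr$r) & is.finite(rr$r)
  d <- lr$r[ok] - rr$r[ok]
  if (.degenerate_diffs(d)) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- stats::t.test(lr$r[ok], rr$r[ok], paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  list(left_r = lr$r, right_r = rr$r,
       left_mean = lr$grand_mean, right_mean = rr$grand_mean,
       t = t_stat, p = p, df = sum(ok) - 1L, tier = p_tier(p))
}

#' Group-analysis summary over all indices and measures
#'
#' Runs \code{\link{group_contrast}} and the grand sex-correlation means for
#' every (index, measure) pair, mirroring the whole-cohort comparison stage of
#' the pipeline.
#'
#' @param index_tables named list of \code{asym_indices} by measure.
#' @param meta participants data.frame.
#' @return data.frame with one row per (index, measure): t, p, tier,
#'   direction, male_mean, female_mean, grand_r, grand_abs_r, p_bonferroni.
#' @export
group_summary <- function(index_tables, meta) {
  rows <- list()
  for (measure in names(index_tables)) {
    ix <- index_tables[[measure]]
    for (kind in intersect(c("DI", "LI", "SI"), names(ix))) {
      gc <- group_contrast(ix[[kind]], meta, kind, measure)
      sc <- sex_correlation_profile(ix[[kind]], meta)
      rows[[length(rows) + 1L]] <- data.frame(
        index = kind, measure = measure,
        t = gc$t, p = gc$p, tier = gc$tier, direction = gc$direction,
        male_mean = mean(gc$male_profile, na.rm = TRUE),
        female_mean = mean(gc$female_profile, na.rm = TRUE),
        grand_r = sc$grand_mean, grand_abs_r = sc$grand_mean_abs,
        p_bonferroni = gc$p_bonferroni, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
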