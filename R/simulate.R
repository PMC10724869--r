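#' Template per-ROI magnitudes for one cortical measure
#'
#' Fixed, realistic template means for the 34 atlas ROIs: gray-matter volume in
#' mm^3 (roughly 2e3--2.4e4), pial surface area in mm^2, average cortical
#' thickness in mm (2--3), and mean curvature in 1/mm (0.1--0.2). These anchor
#' the synthetic generator; the strong inter-ROI magnitude differences are what
#' make the distance index's difference profiles informative.
#'
#' @param measure cortical measure.
#' @return named numeric 34-vector in atlas order.
#' @export
dk_roi_means <- function(measure = c("volume", "area", "thickness", "meancurv")) {
  measure <- match.arg(measure)
  atlas <- dk_atlas()
  vol <- c(2500, 1900, 6200, 3200, 1900, 9500, 13500, 10500, 2600, 11500,
           7400, 6500, 5200, 11000, 2100, 3600, 4400, 2300, 3900, 2200,
           10500, 3100, 13000, 9800, 2400, 15500, 22500, 12500, 11500, 10000,
           1000, 2300, 1100, 6500)
  area <- c(1050, 700, 2300, 1400, 450, 3300, 5200, 3500, 1000, 4900,
            2700, 3100, 1900, 3500, 750, 1400, 1700, 900, 1600, 1400,
            4400, 1200, 5100, 3900, 800, 6000, 7500, 5400, 4000, 3800,
            300, 600, 450, 2300)
  thick <- c(2.5, 2.6, 2.6, 1.9, 3.3, 2.7, 2.4, 2.8, 2.4, 2.2,
             2.6, 2.0, 2.5, 2.9, 2.8, 2.4, 2.6, 2.7, 2.5, 1.7,
             2.1, 2.5, 2.6, 2.4, 2.9, 2.4, 2.7, 2.2, 2.8, 2.6,
             2.7, 3.6, 2.4, 3.0)
  curv <- c(0.11, 0.13, 0.12, 0.14, 0.12, 0.13, 0.13, 0.14, 0.15, 0.14,
            0.15, 0.14, 0.14, 0.12, 0.14, 0.12, 0.13, 0.17, 0.14, 0.15,
            0.11, 0.14, 0.11, 0.13, 0.14, 0.14, 0.12, 0.12, 0.12, 0.13,
            0.17, 0.16, 0.14, 0.11)
  v <- switch(measure, volume = vol, area = area, thickness = thick, meancurv = curv)
  names(v) <- atlas
  v
}

#' Configuration for the synthetic bilateral cohort generator
#'
#' Defines the generative model. For subject s of sex g and ROI i (template
#' mean \code{m_i}):
#' \deqn{a_{i,L} = m_i e^{u_s} + \epsilon_{i,s}, \quad u_s \sim N(0, subject\_scale\_sd^2),
#'   \ \epsilon \sim N(0, (roi\_noise\_cv \cdot m_i)^2)}
#' \deqn{a_{i,R} = a_{i,L} (1 + \delta_{i,g}) + \zeta_{i,s}, \quad
#'   \zeta \sim N(0, (\sigma_g m_i)^2)}
#' The cross-hemisphere coherence noise \eqn{\sigma_g} (\code{coherence_sd},
#' one value per sex) degrades the correlation of the two difference profiles
#' and so drives the distance index up for that sex; the fractional left-right
#' offsets \eqn{\delta_{i,g}} (\code{pairwise_shift}) drive the laterality and
#' subtraction indices without affecting DI (an exactly proportional right
#' hemisphere leaves DI at 0). Image-quality metrics are drawn
#' \eqn{N(mean_g, sd_g)} per metric and sex, independent of the morphometry;
#' ages are Uniform(\code{age_range}).
#'
#' @param n_male,n_female subjects per sex (>= 2).
#' @param subject_scale_sd SD of the per-subject log-scale factor.
#' @param roi_noise_cv coefficient of variation of per-ROI additive noise.
#' @param coherence_sd named numeric, \code{c(male = , female = )}: per-sex SD
#'   of the cross-hemisphere perturbation, as a fraction of each ROI's
#'   template mean.
#' @param pairwise_shift per-sex fractional left-right offsets: either a
#'   single number per sex (\code{c(male = , female = )}, applied to every
#'   ROI) or a 34 x 2 matrix with columns male/female.
#' @param iqm_params data.frame with columns metric, sex, mean, sd covering
#'   the five metrics for both sexes; default emulates a young-adult 3T
#'   T1-weighted cohort with sex-shifted distributions (and deliberately
#'   homogeneous female EFC).
#' @param age_range uniform age bounds in years.
#' @param measures which cortical measures to generate.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_male = 396, n_female = 430,
                       subject_scale_sd = 0.10,
                       roi_noise_cv = 0.03,
                       coherence_sd = c(male = 0.02, female = 0.02),
                       pairwise_shift = c(male = 0, female = 0),
                       iqm_params = default_iqm_params(),
                       age_range = c(19, 26),
                       measures = c("volume", "area", "thickness", "meancurv")) {
  stopifnot(n_male >= 2, n_female >= 2,
            subject_scale_sd >= 0, roi_noise_cv >= 0,
            all(coherence_sd >= 0), length(age_range) == 2)
  if (is.null(names(coherence_sd)) || !setequal(names(coherence_sd), c("male", "female")))
    stop("coherence_sd must be named c(male = , female = )")
  shift <- pairwise_shift
  if (is.matrix(shift)) {
    stopifnot(nrow(shift) == 34, setequal(colnames(shift), c("male", "female")))
    shift <- shift[, c("male", "female"), drop = FALSE]
  } else {
    if (is.null(names(shift)) || !setequal(names(shift), c("male", "female")))
      stop("pairwise_shift must be named c(male = , female = ) or a 34 x 2 matrix")
    shift <- cbind(male = rep(shift[["male"]], 34),
                   female = rep(shift[["female"]], 34))
  }
  rownames(shift) <- dk_atlas()
  structure(list(n_male = as.integer(n_male), n_female = as.integer(n_female),
                 subject_scale_sd = subject_scale_sd, roi_noise_cv = roi_noise_cv,
                 coherence_sd = coherence_sd[c("male", "female")],
                 pairwise_shift = shift, iqm_params = iqm_params,
                 age_range = sort(as.numeric(age_range)),
                 measures = match.arg(measures, several.ok = TRUE)),
            class = "sim_config")
}

#' Default per-sex image-quality-metric distributions
#'
#' Plausible MRIQC-scale values for a homogeneous young-adult 3T cohort, with
#' the male and female distributions shifted against each other (males
#' slightly noisier on CJV/EFC, females slightly higher CNR/INU/WM2MAX) and a
#' markedly smaller female EFC spread.
#' @return data.frame with columns metric, sex, mean, sd.
#' @export
default_iqm_params <- function() {
  data.frame(
    metric = rep(c("CJV", "CNR", "EFC", "INU", "WM2MAX"), each = 2),
    sex = rep(c("male", "female"), 5),
    mean = c(0.42, 0.38, 3.40, 3.60, 0.465, 0.445, 0.92, 0.95, 0.68, 0.72),
    sd = c(0.050, 0.050, 0.350, 0.350, 0.030, 0.012, 0.040, 0.040, 0.060, 0.060),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic bilateral cohort
#'
#' Draws a full cohort under the generative model of \code{\link{sim_config}}:
#' one \code{\link{morph_table}} per measure, a participants table (all
#' right-handed), and an image-quality table. All randomness derives from
#' \code{seed}; identical seeds give identical cohorts. Non-positive
#' volume/area/thickness draws are clipped to a small positive floor; if more
#' than 1\% of draws for a measure are non-positive the configuration is
#' rejected with advice to reduce the noise.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed.
#' @return list with elements \code{morphometry} (named list of
#'   \code{morph_table} by measure), \code{meta} (participants data.frame),
#'   \code{quality} (IQM data.frame), \code{config}, \code{seed}.
#' @export
generate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- config$n_male + config$n_female
  ids <- sprintf("sub-%04d", seq_len(n))
  sex <- factor(rep(c("male", "female"), c(config$n_male, config$n_female)),
                levels = c("male", "female"))
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  u <- stats::rnorm(n, 0, config$subject_scale_sd)
  sigma <- config$coherence_sd[as.character(sex)]
  morph <- list()
  for (meas in config$measures) {
    m <- dk_roi_means(meas)
    L <- outer(exp(u), m) +
      matrix(stats::rnorm(n * 34, 0, 1), n, 34) * rep(config$roi_noise_cv * m, each = n)
    delta <- t(config$pairwise_shift[, as.character(sex), drop = FALSE])  # n x 34
    Z <- matrix(stats::rnorm(n * 34, 0, 1), n, 34) * (sigma %o% m)
    R <- L * (1 + delta) + Z
    if (meas != "meancurv") {
      floor_val <- 1e-6 * m  # per-ROI positive floor
      bad <- sum(L <= 0) + sum(R <= 0)
      if (bad > 0.01 * 2 * n * 34)
        stop("more than 1% of ", meas,
             " draws non-positive; reduce roi_noise_cv / coherence_sd")
      if (bad > 0)
        message("clipped ", bad, " non-positive ", meas, " draws to the positive floor")
      L <- pmax(L, rep(floor_val, each = n))
      R <- pmax(R, rep(floor_val, each = n))
    }
    dimnames(L) <- dimnames(R) <- list(ids, dk_atlas())
    morph[[meas]] <- morph_table(L, R, meas)
  }
  quality <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (metric in .iqm_names) {
    pars <- config$iqm_params[config$iqm_params$metric == metric, ]
    mu <- pars$mean[match(as.character(sex), pars$sex)]
    sdv <- pars$sd[match(as.character(sex), pars$sex)]
    quality[[metric]] <- stats::rnorm(n, mu, sdv)
  }
  meta <- data.frame(subject_id = ids, sex = sex, age = age,
                     handedness = "right", stringsAsFactors = FALSE)
  list(morphometry = morph, meta = meta, quality = quality,
       config = config, seed = as.integer(seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a small canonical fixture suite
#'
#' Emits the plain-text fixtures used across the test surface: a 4-ROI toy
#' table matching the worked laterality/distance examples, a complete 34-ROI
#' mini-cohort in long and wide form with participants and IQM tables, and
#' deliberately broken tables (missing hemisphere, unknown ROI, missing IQM
#' column) for the validators. Deterministic: the same seed gives
#' byte-identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the mini-cohort.
#' @return character vector of file paths written.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_output_csv(df, p)
    paths <<- c(paths, p)
  }
  # 4-ROI toy used in the hand-worked index examples
  toy <- data.frame(subject = "toy-01",
                    hemisphere = rep(c("L", "R"), each = 4),
                    roi = rep(c("r1", "r2", "r3", "r4"), 2),
                    value = c(1, 2, 4, 8, 1, 2, 4, 7))
  emit(toy, "toy_4roi.csv")
  # complete mini-cohort
  cfg <- sim_config(n_male = 3, n_female = 3, measures = "volume")
  coh <- generate_cohort(cfg, seed = seed)
  long <- morph_to_long(coh$morphometry$volume)
  long$value <- signif(long$value, 8)
  emit(long, "mini_cohort_long.csv")
  wide <- data.frame(subject = coh$meta$subject_id, check.names = FALSE)
  for (h in c("lh", "rh")) {
    mat <- if (h == "lh") coh$morphometry$volume$left else coh$morphometry$volume$right
    for (roi in dk_atlas())
      wide[[paste(h, roi, "volume", sep = "_")]] <- signif(mat[, roi], 8)
  }
  emit(wide, "mini_cohort_wide.csv")
  emit(coh$meta, "mini_participants.csv")
  emit(coh$quality, "mini_iqm.csv")
  # broken fixtures for the validators
  emit(long[long$hemisphere == "L", ], "broken_missing_hemisphere.csv")
  bad_roi <- long; bad_roi$roi[1] <- "notaregion"
  emit(bad_roi, "broken_unknown_roi.csv")
  emit(coh$quality[, setdiff(names(coh$quality), "CNR")], "broken_iqm_missing_cnr.csv")
  invisible(paths)
}
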