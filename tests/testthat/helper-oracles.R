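# Naive reference implementations: explicit loops and textbook formulas,
# kept deliberately independent of the vectorized package code paths.

naive_distance_index <- function(left, right) {
  n <- length(left)
  di <- numeric(n)
  for (i in seq_len(n)) {
    vl <- numeric(0); vr <- numeric(0)
    for (j in seq_len(n)) {
      if (j == i) next
      vl <- c(vl, abs(left[i] - left[j]))
      vr <- c(vr, abs(right[i] - right[j]))
    }
    # textbook Pearson: centered cross-products over root sums of squares
    cx <- vl - mean(vl); cy <- vr - mean(vr)
    r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
    di[i] <- 1 - abs(r)
  }
  di
}

naive_laterality_index <- function(left, right) {
  out <- numeric(length(left))
  for (i in seq_along(left)) out[i] <- abs((left[i] - right[i]) / (left[i] + right[i]))
  out
}

naive_subtraction_index <- function(left, right) {
  out <- numeric(length(left))
  for (i in seq_along(left)) out[i] <- abs(left[i] - right[i])
  out
}

naive_kappa <- function(confusion) {
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  rows <- rowSums(confusion); cols <- colSums(confusion)
  pe <- 0
  for (k in seq_len(nrow(confusion))) pe <- pe + rows[k] * cols[k] / n^2
  (po - pe) / (1 - pe)
}

# exact binomial upper tail by direct pmf summation
naive_binom_tail <- function(correct, n, p) {
  total <- 0
  for (k in correct:n) total <- total + choose(n, k) * p^k * (1 - p)^(n - k)
  total
}

# random bilateral pair with realistic inter-ROI magnitude spread
random_hemi_pair <- function(n_roi = 34) {
  m <- exp(runif(n_roi, log(500), log(20000)))
  left <- m * (1 + rnorm(n_roi, 0, 0.05))
  right <- left * (1 + rnorm(n_roi, 0, 0.03)) + rnorm(n_roi, 0, 0.02 * m)
  list(left = left, right = right)
}

# small cohort shared across tests (volume only, fast)
small_cohort <- function(n = 30, seed = 42, ...) {
  generate_cohort(sim_config(n_male = n, n_female = n, measures = "volume", ...),
                  seed = seed)
}

# minimal FreeSurfer aparc.stats text for one hemisphere
write_fake_aparc_stats <- function(path, values, measure_col = "GrayVol") {
  atlas <- dk_atlas()
  hdr <- c("# Table of FreeSurfer cortical parcellation anatomical statistics",
           "# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd MeanCurv GausCurv FoldInd CurvInd")
  cols <- c(StructName = NA, NumVert = 1000, SurfArea = 1500, GrayVol = 3000,
            ThickAvg = 2.5, ThickStd = 0.4, MeanCurv = 0.13, GausCurv = 0.02,
            FoldInd = 10, CurvInd = 1.2)
  rows <- vapply(seq_along(atlas), function(i) {
    v <- cols; v[measure_col] <- values[i]
    paste(atlas[i], paste(v[-1], collapse = " "))
  }, "")
  writeLines(c(hdr, rows), path)
  path
}
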