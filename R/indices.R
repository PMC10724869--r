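#' Per-ROI distance index (global asymmetry)
#'
#' For each ROI i, a profile of absolute differences between that ROI and every
#' other ipsilateral ROI is built in each hemisphere (33 elements, identical
#' atlas order), the two profiles are correlated (Pearson), and
#' \code{DI_i = 1 - |r|}. A perfectly coherent pair of hemispheres -- right
#' values an exact mirror, or any exact proportional rescaling of the left --
#' gives DI = 0 for every ROI; DI rises as the inter-ROI proportional structure
#' diverges across hemispheres. DI is dimensionless, in [0, 1], and invariant
#' to a common positive rescaling of both hemispheres.
#'
#' @param left,right numeric vectors of the 34 raw ROI values (atlas order).
#' @param scheme \code{"all"} (default) uses all 33 differences j != i in both
#'   hemispheres; \code{"upper"} uses only j in i+1..34, a variable-length
#'   variant in which ROIs whose difference profile has fewer than 3 elements
#'   are undefined (\code{NA}).
#' @return numeric 34-vector of DI values; entries where either difference
#'   profile has zero variance are \code{NA}.
#' @export
#' @examples
#' a <- dk_roi_means("volume")
#' distance_index(a, a * 1.07)  # proportional hemispheres: all zero
distance_index <- function(left, right, scheme = c("all", "upper")) {
  scheme <- match.arg(scheme)
  .check_hemi_pair(left, right)
  n <- length(left)
  if (n < 4L) stop("need at least 4 ROIs")
  if (scheme == "upper") return(.distance_index_upper(left, right))
  DL <- abs(outer(left, left, "-"))    # DL[i, j] = |a_i - a_j|, diag 0
  DR <- abs(outer(right, right, "-"))
  m <- n - 1L                          # profile length, diagonal excluded
  sL <- rowSums(DL); sR <- rowSums(DR) # diag contributes 0
  mL <- sL / m; mR <- sR / m
  # centered sums over j != i; the diagonal term (0 - mean)^2 is removed
  sxy <- rowSums(DL * DR) - m * mL * mR
  sxx <- rowSums(DL * DL) - m * mL * mL
  syy <- rowSums(DR * DR) - m * mR * mR
  denom <- sqrt(sxx * syy)
  r <- ifelse(denom > 0, sxy / denom, NA_real_)
  di <- 1 - abs(r)
  di[di < 0 & !is.na(di)] <- 0  # guard tiny negative rounding
  names(di) <- names(left)
  di
}

.distance_index_upper <- function(left, right) {
  n <- length(left)
  di <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- if (i < n) (i + 1L):n else integer(0)
    if (length(j) < 3L) next
    vl <- abs(left[i] - left[j]); vr <- abs(right[i] - right[j])
    if (stats::sd(vl) == 0 || stats::sd(vr) == 0) next
    di[i] <- 1 - abs(stats::cor(vl, vr))
  }
  names(di) <- names(left)
  di
}

#' Per-ROI laterality index
#'
#' Absolute weighted pairwise asymmetry \code{|(L - R) / (L + R)|} for each
#' homologous ROI pair. Dimensionless; in [0, 1] when both raw values are
#' positive; may exceed 1 for sign-mixed inputs (mean curvature), which is
#' permitted and flagged downstream rather than clipped.
#'
#' @inheritParams distance_index
#' @return numeric 34-vector; \code{NA} where \code{L + R == 0}.
#' @export
laterality_index <- function(left, right) {
  .check_hemi_pair(left, right)
  s <- left + right
  li <- ifelse(s == 0, NA_real_, abs((left - right) / s))
  names(li) <- names(left)
  li
}

#' Per-ROI subtraction index
#'
#' Absolute raw pairwise asymmetry \code{|L - R|}, in measure units.
#'
#' @inheritParams distance_index
#' @return numeric 34-vector, non-negative.
#' @export
subtraction_index <- function(left, right) {
  .check_hemi_pair(left, right)
  si <- abs(left - right)
  names(si) <- names(left)
  si
}

.check_hemi_pair <- function(left, right) {
  if (!is.numeric(left) || !is.numeric(right) || length(left) != length(right))
    stop("left and right must be numeric vectors of equal length")
  if (anyNA(left) || anyNA(right) || any(!is.finite(left)) || any(!is.finite(right)))
    stop("hemisphere vectors must be complete and finite")
  invisible(TRUE)
}

#' Compute per-subject asymmetry index tables
#'
#' Applies the requested indices to every subject of a bilateral morphometry
#' table, producing one subjects x 34 matrix per index plus a QC summary
#' (counts of undefined entries and of laterality values above 1).
#'
#' @param morph a \code{\link{morph_table}}.
#' @param kinds character subset of \code{c("DI", "LI", "SI")}.
#' @param scheme difference-profile scheme for DI (see
#'   \code{\link{distance_index}}).
#' @return An object of class \code{asym_indices}: list with one subjects x 34
#'   matrix per requested index (elements \code{DI}, \code{LI}, \code{SI}),
#'   plus \code{measure} and \code{qc} (data.frame of undefined counts and
#'   LI > 1 occurrences).
#' @export
compute_index_tables <- function(morph, kinds = c("DI", "LI", "SI"),
                                 scheme = c("all", "upper")) {
  stopifnot(inherits(morph, "morph_table"))
  kinds <- match.arg(kinds, several.ok = TRUE)
  scheme <- match.arg(scheme)
  n <- length(morph$subjects)
  out <- list(measure = morph$measure)
  fns <- list(DI = function(l, r) distance_index(l, r, scheme = scheme),
              LI = laterality_index, SI = subtraction_index)
  for (k in kinds) {
    m <- matrix(NA_real_, n, 34, dimnames = list(morph$subjects, dk_atlas()))
    for (s in seq_len(n)) m[s, ] <- fns[[k]](morph$left[s, ], morph$right[s, ])
    out[[k]] <- m
  }
  qc <- data.frame(index = kinds,
                   n_undefined = vapply(kinds, function(k) sum(is.na(out[[k]])), 0L),
                   n_li_gt1 = vapply(kinds, function(k)
                     if (k == "LI") sum(out[[k]] > 1, na.rm = TRUE) else 0L, 0L),
                   row.names = NULL, stringsAsFactors = FALSE)
  out$qc <- qc
  class(out) <- "asym_indices"
  out
}

#' @export
print.asym_indices <- function(x, ...) {
  kinds <- intersect(c("DI", "LI", "SI"), names(x))
  cat("Asymmetry index tables (", x$measure, "): ",
      paste(kinds, collapse = ", "), "; ",
      nrow(x[[kinds[1]]]), " subjects x 34 ROIs\n", sep = "")
  if (any(x$qc$n_undefined > 0) || any(x$qc$n_li_gt1 > 0)) {
    cat("QC flags:\n"); print(x$qc)
  }
  invisible(x)
}

#' @export
summary.asym_indices <- function(object, ...) {
  kinds <- intersect(c("DI", "LI", "SI"), names(object))
  tab <- do.call(rbind, lapply(kinds, function(k) {
    v <- object[[k]]
    data.frame(index = k, measure = object$measure,
               mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
               min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE),
               n_undefined = sum(is.na(v)), stringsAsFactors = FALSE)
  }))
  tab
}

#' Write index tables as per-index CSV files
#'
#' One CSV per (index, measure): rows = subjects, columns = the 34 atlas ROI
#' labels, preceded by a \code{subject} column.
#'
#' @param ix an \code{asym_indices} object.
#' @param out_dir output directory.
#' @return paths written, invisibly.
#' @export
write_index_tables <- function(ix, out_dir) {
  stopifnot(inherits(ix, "asym_indices"))
  kinds <- intersect(c("DI", "LI", "SI"), names(ix))
  paths <- character(0)
  for (k in kinds) {
    df <- data.frame(subject = rownames(ix[[k]]), ix[[k]],
                     check.names = FALSE, stringsAsFactors = FALSE)
    p <- file.path(out_dir, sprintf("index_%s_%s.csv", k, ix$measure))
    write_output_csv(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
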