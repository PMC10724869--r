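#' Construct a validated bilateral morphometry table
#'
#' The central container for one cortical measure: a pair of numeric matrices
#' (subjects x 34 ROIs) holding the raw left- and right-hemisphere values in
#' canonical atlas order.
#'
#' @param left,right numeric matrices, subjects in rows, the 34 atlas ROIs in
#'   columns (any order; columns are reordered to \code{dk_atlas()} order).
#'   Rownames are subject ids.
#' @param measure one of \code{"volume"}, \code{"area"}, \code{"thickness"},
#'   \code{"meancurv"}.
#' @return An object of class \code{morph_table}: list with elements
#'   \code{left}, \code{right} (atlas-ordered matrices), \code{measure},
#'   \code{subjects}.
#' @export
morph_table <- function(left, right, measure = c("volume", "area", "thickness", "meancurv")) {
  measure <- match.arg(measure)
  atlas <- dk_atlas()
  left <- as.matrix(left); right <- as.matrix(right)
  for (nm in c("left", "right")) {
    m <- get(nm)
    canon <- normalize_roi_label(colnames(m))
    if (anyNA(canon))
      stop("unknown ROI label(s) in ", nm, " hemisphere: ",
           paste(colnames(m)[is.na(canon)], collapse = ", "))
    if (anyDuplicated(canon))
      stop("duplicated ROI label(s) in ", nm, " hemisphere")
    colnames(m) <- canon
    if (!setequal(canon, atlas))
      stop(nm, " hemisphere does not cover all 34 atlas ROIs; missing: ",
           paste(setdiff(atlas, canon), collapse = ", "))
    assign(nm, m[, atlas, drop = FALSE])
  }
  if (is.null(rownames(left))) rownames(left) <- paste0("sub-", seq_len(nrow(left)))
  if (is.null(rownames(right))) rownames(right) <- rownames(left)
  if (!identical(rownames(left), rownames(right)))
    stop("left and right hemisphere subject ids differ")
  storage.mode(left) <- "double"; storage.mode(right) <- "double"
  structure(list(left = left, right = right, measure = measure,
                 subjects = rownames(left)),
            class = "morph_table")
}

#' @export
print.morph_table <- function(x, ...) {
  cat("Bilateral morphometry table (", x$measure, "): ",
      length(x$subjects), " subjects x 34 ROIs x {L, R}\n", sep = "")
  invisible(x)
}

#' Read a bilateral morphometry table
#'
#' Accepts either a long table (columns \code{subject}, \code{hemisphere},
#' \code{roi}, \code{value}, optionally \code{measure}) or a wide table with
#' \code{{lh|rh}_{roi}} or \code{{lh|rh}_{roi}_{measure}} columns plus a
#' subject-id column. Input may be a CSV/TSV path or a data.frame. ROIs are
#' reordered to atlas order; unknown ROI labels are rejected; subjects with
#' incomplete ROI/hemisphere coverage are excluded and reported in the
#' \code{"excluded"} attribute.
#'
#' @param x file path (CSV or TSV, sniffed from content) or data.frame.
#' @param measure the cortical measure the table holds (required for wide
#'   tables without a measure suffix; used to select rows of a long table
#'   that carries a \code{measure} column).
#' @param format \code{"auto"} (default), \code{"long"} or \code{"wide"}.
#' @return A \code{\link{morph_table}}; attribute \code{"excluded"} lists
#'   subject ids dropped for incomplete coverage.
#' @export
read_morphometry <- function(x, measure = c("volume", "area", "thickness", "meancurv"),
                             format = c("auto", "long", "wide")) {
  measure <- match.arg(measure)
  format <- match.arg(format)
  df <- .read_delim_auto(x)
  names(df) <- tolower(names(df))
  if (format == "auto")
    format <- if (all(c("subject", "hemisphere", "roi", "value") %in% names(df))) "long" else "wide"
  if (format == "long") .morph_from_long(df, measure) else .morph_from_wide(df, measure)
}

.read_delim_auto <- function(x) {
  if (is.data.frame(x)) return(x)
  if (!is.character(x) || length(x) != 1L || !file.exists(x))
    stop("input must be a data.frame or an existing file path")
  header <- readLines(x, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "",
                    na.strings = c("NA", "n/a", "NaN", ""))
}

.norm_hemi <- function(h) {
  h <- tolower(as.character(h))
  out <- rep(NA_character_, length(h))
  out[h %in% c("l", "lh", "left")] <- "L"
  out[h %in% c("r", "rh", "right")] <- "R"
  if (anyNA(out)) stop("unrecognized hemisphere code(s): ",
                       paste(unique(h[is.na(out)]), collapse = ", "))
  out
}

.morph_from_long <- function(df, measure) {
  need <- c("subject", "hemisphere", "roi", "value")
  if (!all(need %in% names(df)))
    stop("long table must have columns: ", paste(need, collapse = ", "))
  if ("measure" %in% names(df)) df <- df[df$measure == measure, , drop = FALSE]
  if (!nrow(df)) stop("no rows for measure '", measure, "'")
  roi <- normalize_roi_label(df$roi)
  if (anyNA(roi))
    stop("unknown ROI label(s): ", paste(unique(df$roi[is.na(roi)]), collapse = ", "))
  if (!is.numeric(df$value))
    stop("unparseable numeric value(s) in 'value' column")
  hemi <- .norm_hemi(df$hemisphere)
  subj <- as.character(df$subject)
  atlas <- dk_atlas()
  ids <- unique(subj)
  build <- function(h) {
    sel <- hemi == h
    m <- matrix(NA_real_, length(ids), 34, dimnames = list(ids, atlas))
    m[cbind(match(subj[sel], ids), match(roi[sel], atlas))] <- df$value[sel]
    m
  }
  .finish_morph(build("L"), build("R"), measure)
}

.morph_from_wide <- function(df, measure) {
  idcol <- intersect(c("subject", "participant_id", "subject_id", "id"), names(df))[1]
  if (is.na(idcol)) stop("wide table needs a subject id column")
  ids <- as.character(df[[idcol]])
  cols <- setdiff(names(df), idcol)
  # parse {lh|rh}_{roi}[_{measure}]
  pat <- "^(lh|rh)_(.+)$"
  keep <- grepl(pat, cols)
  hemi <- ifelse(sub(pat, "\\1", cols) == "lh", "L", "R")
  rest <- sub(pat, "\\2", cols)
  meas_suffix <- sub(".*_([a-z]+)$", "\\1", rest)
  has_suffix <- meas_suffix %in% c("volume", "area", "thickness", "meancurv")
  roi_part <- ifelse(has_suffix, sub("_[a-z]+$", "", rest), rest)
  keep <- keep & (!has_suffix | meas_suffix == measure)
  roi <- normalize_roi_label(roi_part)
  bad <- keep & is.na(roi)
  if (any(bad))
    stop("unknown ROI label(s) in columns: ", paste(cols[bad], collapse = ", "))
  keep <- keep & !is.na(roi)
  atlas <- dk_atlas()
  build <- function(h) {
    m <- matrix(NA_real_, length(ids), 34, dimnames = list(ids, atlas))
    for (k in which(keep & hemi == h)) m[, roi[k]] <- as.numeric(df[[cols[k]]])
    m
  }
  .finish_morph(build("L"), build("R"), measure)
}

.finish_morph <- function(L, R, measure) {
  complete <- stats::complete.cases(L) & stats::complete.cases(R)
  excluded <- rownames(L)[!complete]
  if (length(excluded))
    message("excluding ", length(excluded), " subject(s) with incomplete ROI coverage: ",
            paste(excluded, collapse = ", "))
  if (!any(complete)) stop("no subject has complete bilateral ROI coverage")
  out <- morph_table(L[complete, , drop = FALSE], R[complete, , drop = FALSE], measure)
  attr(out, "excluded") <- excluded
  out
}

#' Read one subject's FreeSurfer aparc.stats pair
#'
#' Parses the whitespace tables written by \code{mris_anatomical_stats}
#' (\code{lh.aparc.stats} / \code{rh.aparc.stats}) and extracts one measure for
#' the 34 cortical ROIs.
#'
#' @param lh_path,rh_path paths to the left/right stats files.
#' @param measure cortical measure to extract.
#' @return list with numeric 34-vectors \code{left} and \code{right} in atlas
#'   order.
#' @export
read_aparc_stats <- function(lh_path, rh_path,
                             measure = c("volume", "area", "thickness", "meancurv")) {
  measure <- match.arg(measure)
  col <- c(volume = "GrayVol", area = "SurfArea", thickness = "ThickAvg",
           meancurv = "MeanCurv")[[measure]]
  read_one <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^# ColHeaders", lines, value = TRUE)
    if (!length(hdr)) stop("not an aparc.stats file (no ColHeaders): ", path)
    headers <- strsplit(sub("^# ColHeaders\\s+", "", hdr[1]), "\\s+")[[1]]
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    df <- utils::read.table(text = body, col.names = headers, stringsAsFactors = FALSE)
    roi <- normalize_roi_label(df$StructName)
    df <- df[!is.na(roi), , drop = FALSE]
    v <- df[[col]]
    names(v) <- roi[!is.na(roi)]
    if (!all(dk_atlas() %in% names(v)))
      stop("stats file ", path, " missing ROI(s): ",
           paste(setdiff(dk_atlas(), names(v)), collapse = ", "))
    v[dk_atlas()]
  }
  list(left = read_one(lh_path), right = read_one(rh_path))
}

#' Read a BIDS-style participants table
#'
#' @param path TSV/CSV path or data.frame with at least \code{participant_id},
#'   \code{sex} and \code{age} columns; \code{handedness} is used when present.
#' @param sex_map optional named vector mapping input sex codes to
#'   \code{"male"}/\code{"female"}, e.g. \code{c("0" = "male", "1" = "female")}.
#'   Codes M/F/male/female are always accepted.
#' @return data.frame with columns \code{subject_id}, \code{sex} (factor
#'   male/female), \code{age}, \code{handedness}.
#' @export
read_participants <- function(path, sex_map = NULL) {
  df <- .read_delim_auto(path)
  names(df) <- tolower(names(df))
  idcol <- intersect(c("participant_id", "subject_id", "subject", "id"), names(df))[1]
  if (is.na(idcol) || !"sex" %in% names(df) || !"age" %in% names(df))
    stop("participants table needs participant_id, sex and age columns")
  ids <- as.character(df[[idcol]])
  if (anyDuplicated(ids)) stop("duplicated subject ids in participants table")
  code <- tolower(as.character(df$sex))
  sex <- rep(NA_character_, length(code))
  sex[code %in% c("m", "male")] <- "male"
  sex[code %in% c("f", "female")] <- "female"
  if (!is.null(sex_map)) {
    mapped <- tolower(unname(sex_map[as.character(df$sex)]))
    sex[is.na(sex) & !is.na(mapped)] <- mapped[is.na(sex) & !is.na(mapped)]
  }
  if (anyNA(sex))
    stop("unknown sex code(s): ", paste(unique(df$sex[is.na(sex)]), collapse = ", "))
  hand <- if ("handedness" %in% names(df)) {
    h <- tolower(as.character(df$handedness))
    h[h %in% c("r", "right", "righthanded", "right-handed")] <- "right"
    h[h %in% c("l", "left", "lefthanded", "left-handed")] <- "left"
    h[h %in% c("a", "ambidextrous", "both")] <- "ambidextrous"
    h
  } else rep(NA_character_, length(ids))
  data.frame(subject_id = ids,
             sex = factor(sex, levels = c("male", "female")),
             age = as.numeric(df$age),
             handedness = hand,
             stringsAsFactors = FALSE)
}

#' Keep only right-handed subjects
#' @param meta data.frame from \code{\link{read_participants}}.
#' @export
filter_right_handed <- function(meta) {
  meta[!is.na(meta$handedness) & meta$handedness == "right", , drop = FALSE]
}

# canonical IQM names and accepted aliases (MRIQC-style lower case included)
.iqm_names <- c("CJV", "CNR", "EFC", "INU", "WM2MAX")
.iqm_alias <- c(cjv = "CJV", cnr = "CNR", efc = "EFC", inu = "INU",
                inu_med = "INU", inu_range = "INU", wm2max = "WM2MAX")

#' Read an image-quality-metrics table
#'
#' Reads a TSV/CSV with a subject-id column and the five scalar image-quality
#' metrics CJV, CNR, EFC, INU, WM2MAX (MRIQC-style lower-case aliases
#' accepted). Subjects with a missing/non-finite metric are flagged in the
#' \code{"flagged"} attribute so they can be excluded from the robustness stage
#' only.
#'
#' @param path TSV/CSV path or data.frame.
#' @param ids optional subject ids (e.g. from the participants table); subjects
#'   absent from the IQM table are reported in the \code{"missing"} attribute.
#' @return data.frame with columns \code{subject_id}, \code{CJV}, \code{CNR},
#'   \code{EFC}, \code{INU}, \code{WM2MAX}.
#' @export
read_quality <- function(path, ids = NULL) {
  df <- .read_delim_auto(path)
  idcol <- intersect(c("participant_id", "subject_id", "subject", "id",
                       "bids_name"), tolower(names(df)))[1]
  names(df) <- tolower(names(df))
  if (is.na(idcol)) stop("IQM table needs a subject id column")
  out <- data.frame(subject_id = as.character(df[[idcol]]), stringsAsFactors = FALSE)
  for (metric in .iqm_names) {
    src <- names(.iqm_alias)[.iqm_alias == metric]
    hit <- intersect(c(tolower(metric), src), names(df))[1]
    if (is.na(hit)) stop("missing IQM column: ", metric)
    out[[metric]] <- as.numeric(df[[hit]])
  }
  bad <- !stats::complete.cases(out) |
    !apply(as.matrix(out[.iqm_names]), 1L, function(r) all(is.finite(r)))
  attr(out, "flagged") <- out$subject_id[bad]
  if (any(bad))
    message(sum(bad), " subject(s) flagged for missing/non-finite IQM values")
  if (!is.null(ids)) attr(out, "missing") <- setdiff(ids, out$subject_id)
  out
}

#' Write a data.frame as deterministic UTF-8 CSV
#'
#' All pipeline outputs go through this writer: header row, fixed column
#' order as given, no row names, \code{"NA"} for missing.
#' @param df data.frame.
#' @param path output path.
#' @export
write_output_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Morphometry table to long data.frame (for round-trip CSV output)
#' @param x a \code{morph_table}.
#' @export
morph_to_long <- function(x) {
  stopifnot(inherits(x, "morph_table"))
  atlas <- dk_atlas()
  n <- length(x$subjects)
  data.frame(subject = rep(x$subjects, each = 2L * 34L),
             hemisphere = rep(rep(c("L", "R"), each = 34L), n),
             roi = rep(atlas, 2L * n),
             measure = x$measure,
             value = as.vector(rbind(t(x$left), t(x$right))),
             stringsAsFactors = FALSE)
}
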