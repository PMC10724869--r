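#' The 34-parcel bilateral cortical atlas
#'
#' Canonical, ordered labels of the 34 cortical regions of interest per
#' hemisphere in the FreeSurfer \code{aparc} parcellation
#' (Desikan--Killiany(-Tourville) cortical parcels). The ordering is fixed and
#' identical for the two hemispheres; every morphometry and index table in the
#' package uses this order.
#'
#' @return Character vector of 34 unique ROI labels in canonical order.
#' @export
#' @examples
#' length(dk_atlas())
#' dk_atlas()[25]  # "rostralanteriorcingulate"
dk_atlas <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
    "temporalpole", "transversetemporal", "insula")
}

#' Normalize ROI labels to the canonical atlas spelling
#'
#' Accepts the compact FreeSurfer spelling ("rostralanteriorcingulate") as well
#' as underscore/hyphen/space and case variants ("Rostral_Anterior_Cingulate")
#' found in derived spreadsheets, and maps them to the canonical label.
#'
#' @param x character vector of ROI labels.
#' @return character vector of canonical labels; labels that do not resolve are
#'   returned as \code{NA}.
#' @export
normalize_roi_label <- function(x) {
  atlas <- dk_atlas()
  key <- tolower(gsub("[-_ .]", "", as.character(x)))
  canon <- atlas[match(key, atlas)]
  # "bank of the superior temporal sulcus" style variants
  canon[is.na(canon) & key %in% c("banksofthesuperiortemporalsulcus", "banks")] <- "bankssts"
  canon
}

#' @rdname normalize_roi_label
#' @export
is_atlas_label <- function(x) !is.na(normalize_roi_label(x))
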