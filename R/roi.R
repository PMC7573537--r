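## ROI identifiers ----------------------------------------------------------

ROI_STRUCTURES <- c("preSMA", "IFG", "STR", "GPe", "GPi", "SN", "STN", "THAL")
ROI_SUBCORTICAL <- c("STR", "GPe", "GPi", "SN", "STN", "THAL")
ROI_HEMISPHERES <- c("L", "R")

CONDITIONS <- c("execution", "inhibition_pro", "inhibition_reac")
CONDITIONS_ALL <- c(CONDITIONS, "inhibition_all")

#' Lateralised ROI identifiers
#'
#' The analysis operates on 16 lateralised regions of interest: left and
#' right pre-supplementary motor area (preSMA), inferior frontal gyrus
#' (IFG), striatum (STR), globus pallidus externa (GPe) and interna (GPi),
#' substantia nigra (SN), subthalamic nucleus (STN) and thalamus (THAL).
#' The canonical string form is `"<hemisphere>_<structure>"`, e.g. `"R_STN"`.
#'
#' @param subcortical if `TRUE`, return only the 12 lateralised
#'   basal-ganglia/thalamic ROIs that enter the pathway evidence products.
#' @return character vector of canonical ROI identifiers, left hemisphere
#'   first, structures in anatomical listing order.
#' @examples
#' roi_ids()
#' roi_ids(subcortical = TRUE)
#' @export
roi_ids <- function(subcortical = FALSE) {
  structures <- if (subcortical) ROI_SUBCORTICAL else ROI_STRUCTURES
  as.vector(t(outer(ROI_HEMISPHERES, structures, paste, sep = "_")))
}

#' Parse ROI strings into canonical form
#'
#' Accepts `"<hemisphere>_<structure>"` case-insensitively (`"r_stn"`,
#' `"R_STN"`) and returns the canonical spelling. Unparseable input raises a
#' condition of class `pathwaybf_error_roi_parse`.
#'
#' @param x character vector of ROI labels.
#' @return character vector of canonical ROI identifiers.
#' @examples
#' parse_roi(c("r_stn", "L_presma"))
#' @export
parse_roi <- function(x) {
  x <- as.character(x)
  parts <- strsplit(x, "_", fixed = TRUE)
  bad <- function(i, why) {
    pbf_stop("roi_parse", sprintf("cannot parse ROI '%s': %s", x[i], why))
  }
  out <- character(length(x))
  for (i in seq_along(x)) {
    p <- parts[[i]]
    if (length(p) != 2L) bad(i, "expected '<L|R>_<structure>'")
    hemi <- match(toupper(p[1]), ROI_HEMISPHERES)
    if (is.na(hemi)) bad(i, sprintf("unknown hemisphere '%s'", p[1]))
    struct <- match(toupper(p[2]), toupper(ROI_STRUCTURES))
    if (is.na(struct)) bad(i, sprintf("unknown structure '%s'", p[2]))
    out[i] <- paste(ROI_HEMISPHERES[hemi], ROI_STRUCTURES[struct], sep = "_")
  }
  out
}

roi_hemisphere <- function(roi) sub("_.*$", "", roi)
roi_structure <- function(roi) sub("^[LR]_", "", roi)

check_condition <- function(condition, allow_all = TRUE) {
  levels <- if (allow_all) CONDITIONS_ALL else CONDITIONS
  if (length(condition) != 1L || !condition %in% levels) {
    pbf_stop("unknown_condition",
             sprintf("condition must be one of: %s (got '%s')",
                     paste(levels, collapse = ", "),
                     paste(condition, collapse = ", ")))
  }
  condition
}
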