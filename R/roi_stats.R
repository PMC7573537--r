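## Per-ROI activation tests -------------------------------------------------

roi_stat_row <- function(roi, label, res, holm_p = NA_real_) {
  data.frame(roi = roi, condition = label,
             t = res$t, df = res$df, p = res$p, bf10 = res$bf10,
             category = res$category,
             active = res$p < 0.05 || res$bf10 > 3,
             stringsAsFactors = FALSE)
}

#' Per-ROI activation table for one condition
#'
#' One-sample JZS t-test of each ROI's compound values against zero, with
#' an `active` flag marking ROIs where `p < 0.05` *or* `BF10 > 3` (the
#' criterion used to admit ROIs into the mediation screen). The tests are
#' exploratory and reported uncorrected by default; set `holm = TRUE` to
#' append Holm-Bonferroni adjusted p-values (the `active` flag always uses
#' the unadjusted p).
#'
#' @param est a [compound_estimates()] table.
#' @param condition condition label.
#' @param prior a [jzs_prior()].
#' @param rois ROI subset (default: all ROIs present).
#' @param holm append a `p_holm` column (default `FALSE`).
#' @return data frame with one row per ROI: `roi`, `condition`, `t`, `df`,
#'   `p`, `bf10`, `category`, `active` (and optionally `p_holm`).
#' @export
activation_table <- function(est, condition, prior = jzs_prior(),
                             rois = NULL, holm = FALSE) {
  m <- compound_matrix(est, condition, rois)
  rows <- do.call(rbind, lapply(colnames(m), function(roi) {
    roi_stat_row(roi, condition, jzs_one_sample(m[, roi], prior = prior))
  }))
  if (holm) rows$p_holm <- holm_adjust(rows$p)
  rownames(rows) <- NULL
  rows
}

#' Per-ROI paired condition difference table
#'
#' Paired JZS t-test of `a - b` for each ROI across participants; positive
#' t means condition `a` exceeds condition `b` (for the published analysis
#' analog, `a = "execution"`, `b = "inhibition_all"`).
#'
#' @param est a [compound_estimates()] table.
#' @param a,b condition labels.
#' @inheritParams activation_table
#' @return data frame as in [activation_table()], with `condition` set to
#'   `"<a> - <b>"`.
#' @export
condition_difference_table <- function(est, a, b, prior = jzs_prior(),
                                       rois = NULL, holm = FALSE) {
  ma <- compound_matrix(est, a, rois)
  mb <- compound_matrix(est, b, rois)
  stopifnot(identical(dimnames(ma), dimnames(mb)))
  label <- paste(a, "-", b)
  rows <- do.call(rbind, lapply(colnames(ma), function(roi) {
    roi_stat_row(roi, label, jzs_paired(ma[, roi], mb[, roi], prior = prior))
  }))
  if (holm) rows$p_holm <- holm_adjust(rows$p)
  rownames(rows) <- NULL
  rows
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts p-values ascending, multiplies the i-th smallest by (m - i + 1),
#' enforces monotone non-decrease, caps at 1 and returns the result in the
#' original order (delegating to [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.04)) # 0.03, 0.04, 0.04
#' @export
holm_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    pbf_stop("invalid_p", "p-values must be numbers in [0, 1]")
  }
  p.adjust(p_values, method = "holm")
}

#' ROIs flagged active in a statistics table
#'
#' @param rows output of [activation_table()] (one condition).
#' @return character vector of active ROI identifiers.
#' @export
active_rois <- function(rows) {
  stopifnot(is.data.frame(rows), all(c("roi", "active") %in% names(rows)))
  rows$roi[rows$active]
}
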