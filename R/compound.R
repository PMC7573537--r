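## Compound contrast estimates ----------------------------------------------

#' Collapse per-contrast %BOLD into compound point estimates
#'
#' For each participant, ROI and behavioural condition, the compound
#' estimate is the arithmetic mean of all observations whose contrast is
#' assigned to that condition. Differences between contrasts within a set
#' (e.g. different baselines) average out, leaving a point value dominated
#' by the condition's common signal.
#'
#' The pooled `inhibition_all` cell is, by default, the mean over the
#' *union* of proactive and reactive observations, so each contrast carries
#' equal weight regardless of how the inhibition set is subdivided. Set
#' `inhibition_all = "mean_of_means"` to average the two sub-means instead
#' (equal weight per subset).
#'
#' @param table a [bold_table()].
#' @param assignment a [contrast_assignment()] covering every contrast in
#'   `table`.
#' @param inhibition_all `"union"` (default) or `"mean_of_means"`.
#' @return data frame of class `compound_estimates` with columns
#'   `participant`, `roi`, `condition`, `value`, `n_contrasts`.
#' @examples
#' tab <- bold_table(rep("p1", 2), c("c1", "c2"), rep("L_STR", 2), c(1, 3))
#' asg <- contrast_assignment(c("c1", "c2"),
#'                            c("inhibition_pro", "inhibition_reac"))
#' compound_estimates(tab, asg)
#' @export
compound_estimates <- function(table, assignment,
                               inhibition_all = c("union", "mean_of_means")) {
  stopifnot(inherits(table, "bold_table"),
            inherits(assignment, "contrast_assignment"))
  inhibition_all <- match.arg(inhibition_all)

  idx <- match(table$contrast, assignment$contrast)
  if (anyNA(idx)) {
    missing <- unique(table$contrast[is.na(idx)])
    pbf_stop("unassigned_contrast",
             sprintf("contrast(s) with no condition assignment: %s",
                     paste(utils::head(missing, 5), collapse = ", ")))
  }
  cond <- assignment$condition[idx]

  cell_means <- function(sub, label) {
    if (nrow(sub) == 0L) return(NULL)
    agg <- aggregate(sub$value,
                     by = list(participant = sub$participant, roi = sub$roi),
                     FUN = mean)
    cnt <- aggregate(sub$value,
                     by = list(participant = sub$participant, roi = sub$roi),
                     FUN = length)
    data.frame(participant = agg$participant, roi = agg$roi,
               condition = label, value = agg$x, n_contrasts = cnt$x,
               stringsAsFactors = FALSE)
  }

  parts <- lapply(CONDITIONS, function(cn) {
    cell_means(table[cond == cn, , drop = FALSE], cn)
  })
  all_sub <- table[cond %in% c("inhibition_pro", "inhibition_reac"), ,
                   drop = FALSE]
  if (inhibition_all == "union") {
    parts <- c(parts, list(cell_means(all_sub, "inhibition_all")))
  } else {
    pro <- parts[[match("inhibition_pro", CONDITIONS)]]
    reac <- parts[[match("inhibition_reac", CONDITIONS)]]
    if (!is.null(pro) && !is.null(reac)) {
      m <- merge(pro, reac, by = c("participant", "roi"))
      parts <- c(parts, list(data.frame(
        participant = m$participant, roi = m$roi,
        condition = "inhibition_all",
        value = (m$value.x + m$value.y) / 2,
        n_contrasts = m$n_contrasts.x + m$n_contrasts.y,
        stringsAsFactors = FALSE)))
    }
  }
  est <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  est <- est[order(est$condition, est$roi, est$participant), ]
  rownames(est) <- NULL
  class(est) <- c("compound_estimates", "data.frame")
  est
}

#' Extract one condition's compound values as a participant x ROI matrix
#'
#' Completeness is enforced here: every requested ROI must have a value for
#' every participant under the condition, otherwise an
#' `pathwaybf_error_empty_cell` condition names the first missing cell.
#'
#' @param est a [compound_estimates()] table.
#' @param condition one of `"execution"`, `"inhibition_pro"`,
#'   `"inhibition_reac"`, `"inhibition_all"`.
#' @param rois ROIs to include (default: all ROIs present in `est`).
#' @return numeric matrix, rows = participants (sorted), cols = ROIs.
#' @export
compound_matrix <- function(est, condition, rois = NULL) {
  stopifnot(inherits(est, "compound_estimates"))
  check_condition(condition)
  sub <- est[est$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0L) {
    pbf_stop("empty_cell",
             sprintf("no compound estimates for condition '%s'", condition))
  }
  rois <- rois %||% intersect(roi_ids(), unique(sub$roi))
  participants <- sort(unique(est$participant))
  m <- matrix(NA_real_, nrow = length(participants), ncol = length(rois),
              dimnames = list(participants, rois))
  sub <- sub[sub$roi %in% rois, , drop = FALSE]
  m[cbind(match(sub$participant, participants), match(sub$roi, rois))] <-
    sub$value
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)[1, ]
    pbf_stop("empty_cell", sprintf(
      "no compound estimate for participant '%s', ROI %s, condition '%s'",
      participants[miss[1]], rois[miss[2]], condition))
  }
  m
}
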