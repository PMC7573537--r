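## Pathway models and evidence products -------------------------------------
##
## A pathway model names the lateralised subcortical structures expected to
## be active when the pathway is engaged. Evidence that observed activity
## matches the model is the product, over all 12 lateralised subcortical
## ROIs, of BF10 for member ROIs and 1/BF10 for non-member ROIs: activation
## evidence where the model predicts activity, and null evidence where it
## predicts none. Cortical ROIs (preSMA, IFG) never enter the product.

#' Construct a pathway membership model
#'
#' @param name pathway label (`"direct"`, `"indirect"` or `"hyperdirect"`,
#'   or any custom label for user-defined models).
#' @param hemisphere `"L"` or `"R"`; the hemisphere carrying the pathway.
#' @param members subcortical structures (subset of STR, GPe, GPi, SN, STN,
#'   THAL) expected active. Non-members are derived: the remaining
#'   same-hemisphere subcortical structures plus all six contralateral ones.
#' @return object of class `pathway_model` with fields `name`,
#'   `hemisphere`, `members` and `non_members` (both as lateralised ROI
#'   identifiers).
#' @examples
#' pathway_model("hyperdirect", "R", c("GPi", "STN", "SN", "THAL"))
#' @export
pathway_model <- function(name, hemisphere, members) {
  if (!hemisphere %in% ROI_HEMISPHERES) {
    pbf_stop("invalid_pathway", "hemisphere must be 'L' or 'R'")
  }
  bad <- setdiff(members, ROI_SUBCORTICAL)
  if (length(bad) || length(members) == 0L) {
    pbf_stop("invalid_pathway", sprintf(
      "members must be a non-empty subset of {%s}%s",
      paste(ROI_SUBCORTICAL, collapse = ", "),
      if (length(bad)) paste0(" (unknown: ", paste(bad, collapse = ", "), ")")
      else ""))
  }
  members <- unique(members)
  other <- setdiff(ROI_HEMISPHERES, hemisphere)
  lateralise <- function(hemi, structs) {
    if (length(structs)) paste(hemi, structs, sep = "_") else character(0)
  }
  member_ids <- lateralise(hemisphere, members)
  non_member_ids <- c(
    lateralise(hemisphere, setdiff(ROI_SUBCORTICAL, members)),
    lateralise(other, ROI_SUBCORTICAL))
  structure(list(name = name, hemisphere = hemisphere,
                 members = member_ids, non_members = non_member_ids),
            class = "pathway_model")
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("Pathway '%s' (%s hemisphere)\n  members: %s\n",
              x$name, x$hemisphere, paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Default direct / indirect / hyperdirect pathway models
#'
#' Membership maps for the three putative cortico-basal-ganglia-thalamic
#' routes, lateralised by the responding hand. For right-hand responses,
#' execution engages the contralateral (left) hemisphere and inhibition the
#' right hemisphere:
#' * direct (execution): left STR, GPi, SN, THAL;
#' * indirect (inhibition): all six right subcortical structures
#'   (STR, GPe, GPi, SN, STN, THAL);
#' * hyperdirect (inhibition): right GPi, STN, SN, THAL.
#'
#' `response_hand = "left"` mirrors every hemisphere.
#'
#' @param response_hand `"right"` (default) or `"left"`.
#' @return named list of three [pathway_model()] objects.
#' @export
default_pathway_models <- function(response_hand = c("right", "left")) {
  response_hand <- match.arg(response_hand)
  exec_hemi <- if (response_hand == "right") "L" else "R"
  inhib_hemi <- if (response_hand == "right") "R" else "L"
  list(
    direct = pathway_model("direct", exec_hemi,
                           c("STR", "GPi", "SN", "THAL")),
    indirect = pathway_model("indirect", inhib_hemi, ROI_SUBCORTICAL),
    hyperdirect = pathway_model("hyperdirect", inhib_hemi,
                                c("GPi", "STN", "SN", "THAL"))
  )
}

#' Per-ROI Bayes factors over the subcortical set
#'
#' One-sample JZS Bayes factor for each of the 12 lateralised subcortical
#' ROIs from the participants' compound values under one condition. To
#' score externally supplied Bayes factors (e.g. values printed in a
#' published table), bypass this function and pass a named vector straight
#' to [evidence_product()].
#'
#' @param est a [compound_estimates()] table.
#' @param condition condition label.
#' @param prior a [jzs_prior()].
#' @return named numeric vector of BF10, names = subcortical ROI ids.
#' @export
roi_bf_table <- function(est, condition, prior = jzs_prior()) {
  m <- compound_matrix(est, condition, rois = roi_ids(subcortical = TRUE))
  vapply(colnames(m), function(roi) jzs_one_sample(m[, roi], prior)$bf10,
         numeric(1))
}

#' Evidence product for one pathway model
#'
#' Multiplies BF10 for every member ROI and 1/BF10 for every non-member
#' subcortical ROI. The computation runs in log space, and a per-ROI
#' contribution ledger is kept so the product can be audited.
#'
#' @param bfs named numeric vector of BF10 covering all 12 lateralised
#'   subcortical ROIs (extra entries, e.g. cortical ROIs, are ignored).
#' @param pathway a [pathway_model()].
#' @return object of class `evidence_score`: list with `pathway`,
#'   `bf_product`, `log10_bf_product` and `ledger` (data frame with
#'   columns `roi`, `role`, `bf10`, `contribution`, `log10_contribution`).
#' @examples
#' bfs <- setNames(rep(1, 12), roi_ids(subcortical = TRUE))
#' bfs["R_STN"] <- 4
#' evidence_product(bfs, pathway_model("hyperdirect", "R",
#'                                     c("GPi", "STN", "SN", "THAL")))
#' @export
evidence_product <- function(bfs, pathway) {
  stopifnot(inherits(pathway, "pathway_model"))
  needed <- roi_ids(subcortical = TRUE)
  missing <- setdiff(needed, names(bfs))
  if (length(missing)) {
    pbf_stop("missing_roi",
             sprintf("Bayes factor map lacks ROI(s): %s",
                     paste(missing, collapse = ", ")))
  }
  bfs <- bfs[needed]
  if (any(!is.finite(bfs)) || any(bfs <= 0)) {
    pbf_stop("nonpositive_bf", "all Bayes factors must be finite and positive")
  }
  role <- ifelse(needed %in% pathway$members, "member", "non_member")
  signed_log <- ifelse(role == "member", log10(bfs), -log10(bfs))
  ledger <- data.frame(roi = needed, role = role, bf10 = unname(bfs),
                       contribution = ifelse(role == "member", bfs, 1 / bfs),
                       log10_contribution = signed_log,
                       stringsAsFactors = FALSE)
  log10_total <- sum(signed_log)
  structure(list(pathway = pathway,
                 bf_product = 10^log10_total,
                 log10_bf_product = log10_total,
                 ledger = ledger),
            class = "evidence_score")
}

#' @export
print.evidence_score <- function(x, ...) {
  cat(sprintf("Pathway '%s' (%s): BF product = %.4g (log10 = %.3f)\n",
              x$pathway$name, x$pathway$hemisphere,
              x$bf_product, x$log10_bf_product))
  invisible(x)
}

matched_cell <- function(condition, pathway_name) {
  (pathway_name == "direct" & condition == "execution") |
    (pathway_name %in% c("indirect", "hyperdirect") &
       startsWith(condition, "inhibition"))
}

#' Condition x pathway evidence grid
#'
#' Scores every pathway model under every condition — behaviourally matched
#' *and* mismatched, so theoretically inappropriate assignments are always
#' computed as an overfitting control. Matched cells (direct x execution;
#' indirect/hyperdirect x any inhibition condition) are flagged.
#'
#' @param est a [compound_estimates()] table, or `NULL` when `bf_tables`
#'   supplies precomputed per-ROI Bayes factors.
#' @param models list of [pathway_model()]s, e.g.
#'   [default_pathway_models()].
#' @param prior a [jzs_prior()].
#' @param conditions condition labels forming the grid rows.
#' @param bf_tables optional named list (by condition) of named BF10
#'   vectors, bypassing `est` — e.g. Bayes factors transcribed from a
#'   published activation table.
#' @return data frame of class `evidence_grid`: `condition`, `pathway`,
#'   `hemisphere`, `bf_product`, `log10_bf_product`, `matched`. The
#'   underlying `evidence_score` objects are kept in attribute `scores`.
#' @export
evidence_table <- function(est = NULL, models = default_pathway_models(),
                           prior = jzs_prior(),
                           conditions = c("execution", "inhibition_all",
                                          "inhibition_pro", "inhibition_reac"),
                           bf_tables = NULL) {
  if (is.null(bf_tables)) {
    if (is.null(est)) {
      pbf_stop("invalid_input",
               "either compound estimates or bf_tables must be supplied")
    }
    bf_tables <- lapply(conditions, function(cn) roi_bf_table(est, cn, prior))
    names(bf_tables) <- conditions
  } else {
    missing <- setdiff(conditions, names(bf_tables))
    if (length(missing)) {
      pbf_stop("empty_cell",
               sprintf("bf_tables lacks condition(s): %s",
                       paste(missing, collapse = ", ")))
    }
  }
  cells <- expand.grid(pathway = names(models), condition = conditions,
                       stringsAsFactors = FALSE)[, c("condition", "pathway")]
  scores <- lapply(seq_len(nrow(cells)), function(i) {
    evidence_product(bf_tables[[cells$condition[i]]],
                     models[[cells$pathway[i]]])
  })
  out <- data.frame(
    condition = cells$condition,
    pathway = cells$pathway,
    hemisphere = vapply(scores, function(s) s$pathway$hemisphere, character(1)),
    bf_product = vapply(scores, function(s) s$bf_product, numeric(1)),
    log10_bf_product = vapply(scores, function(s) s$log10_bf_product,
                              numeric(1)),
    matched = matched_cell(cells$condition, cells$pathway),
    stringsAsFactors = FALSE)
  attr(out, "scores") <- scores
  class(out) <- c("evidence_grid", "data.frame")
  out
}

#' Reference per-ROI Bayes factors from the published ROI analysis
#'
#' Per-ROI one-sample Bayes factors, as printed (2 decimals) in a published
#' fMRI study of response execution and inhibition in 30 right-handed
#' participants, for the 16 lateralised ROIs under the execution and
#' pooled-inhibition compound conditions. Feeding these through
#' [evidence_product()] with [default_pathway_models()] reproduces that
#' study's published pathway evidence scores, which is used as an
#' arithmetic cross-check of the product rule.
#'
#' @return data frame with columns `roi`, `execution`, `inhibition`
#'   (BF10 values).
#' @export
published_roi_bf <- function() {
  path <- system.file("extdata", "published_roi_bf10.tsv",
                      package = "pathwaybf", mustWork = TRUE)
  df <- read_stats_table(path)
  df$roi <- parse_roi(df$roi)
  df
}
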