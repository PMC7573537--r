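## Partial moderator/mediator analysis --------------------------------------
##
## For every ordered pair of active ROIs, the target's compound values are
## regressed on the covariate's, and the regression intercept is tested
## against zero: a significant intercept means the target remains active
## once the covariate is taken into account. Comparing the adjusted result
## with the target's original one-sample result classifies the covariate's
## influence as mediating, moderating, or neither.

#' Intercept test after simple regression on a covariate
#'
#' Ordinary least squares fit of `target = b0 + b1 * covariate + e`; returns
#' the intercept t-statistic (`t = b0 / SE(b0)`, `df = N - 2`), its
#' two-sided p-value and the JZS Bayes factor derived from that t with
#' effective sample size N.
#'
#' @param target_values,covariate_values numeric vectors of equal length
#'   (N >= 4); the covariate must have positive standard deviation.
#' @param prior a [jzs_prior()].
#' @return a `bayes_result` for the intercept.
#' @export
partial_intercept_test <- function(target_values, covariate_values,
                                   prior = jzs_prior()) {
  n <- length(target_values)
  if (length(covariate_values) != n) {
    pbf_stop("length_mismatch",
             sprintf("target and covariate differ in length (%d vs %d)",
                     n, length(covariate_values)))
  }
  if (n < 4L) {
    pbf_stop("insufficient_data",
             sprintf("need at least 4 pairs for the intercept test (got %d)", n))
  }
  if (sd(covariate_values) == 0) {
    pbf_stop("degenerate_covariate",
             "covariate has zero variance; regression undefined")
  }
  fit <- lm(target_values ~ covariate_values)
  ## summary.lm warns on an exactly collinear fit; that case is handled below
  sm <- suppressWarnings(summary(fit))$coefficients
  t0 <- sm["(Intercept)", "t value"]
  if (!is.finite(t0)) {
    ## exact linear dependence: zero residual variance. A zero intercept is
    ## the perfect-mediation limit (t = 0); a nonzero one is unscorable.
    b0 <- unname(coef(fit)[1])
    if (abs(b0) < 1e-10) t0 <- 0
    else pbf_stop("degenerate_sample",
                  "exact linear fit with nonzero intercept; t undefined")
  }
  jzs_bf_from_t(t0, df = n - 2, n_eff = n, prior = prior)
}

#' Classify a covariate's influence on a target ROI
#'
#' Given the target's original one-sample result and its covariate-adjusted
#' intercept result:
#' * `mediated` — the covariate eliminates the effect: adjusted BF10 < 1/3
#'   *and* adjusted p > 0.05;
#' * `moderated` — the effect is reduced but not eliminated: 1/3 <=
#'   adjusted BF10 < 3 and adjusted BF10 < original BF10;
#' * `unchanged` — adjusted BF10 >= 3, or not reduced at all;
#' * `inconsistent` — the remaining cells (e.g. adjusted BF10 < 1/3 with
#'   adjusted p <= 0.05), flagged rather than silently binned, since the
#'   frequentist and Bayesian thresholds need not agree.
#'
#' @param original `bayes_result` for the target alone (should satisfy the
#'   active criterion).
#' @param adjusted `bayes_result` from [partial_intercept_test()].
#' @return one of `"mediated"`, `"moderated"`, `"unchanged"`,
#'   `"inconsistent"`.
#' @export
classify_relation <- function(original, adjusted) {
  stopifnot(inherits(original, "bayes_result"),
            inherits(adjusted, "bayes_result"))
  bf <- adjusted$bf10
  if (bf < 1 / 3 && adjusted$p > 0.05) "mediated"
  else if (bf >= 1 / 3 && bf < 3 && bf < original$bf10) "moderated"
  else if (bf >= 3 || bf >= original$bf10) "unchanged"
  else "inconsistent"
}

#' Full moderator/mediator matrix for one condition
#'
#' Runs [partial_intercept_test()] for every ordered pair of ROIs flagged
#' active under `condition` and classifies each relation. Directionality is
#' preserved: mediation of A by B is assessed independently of B by A.
#'
#' @param est a [compound_estimates()] table.
#' @param condition condition label.
#' @param prior a [jzs_prior()].
#' @param rois ROI subset passed to [activation_table()].
#' @return data frame of class `mediation_matrix` with one row per ordered
#'   (target, covariate) pair: original and adjusted t, df, p, bf10, and
#'   `relation`. With fewer than 2 active ROIs an empty table is returned
#'   with a message (attribute `notice`).
#' @export
mediation_matrix <- function(est, condition, prior = jzs_prior(),
                             rois = NULL) {
  act <- activation_table(est, condition, prior = prior, rois = rois)
  active <- sort(active_rois(act))
  empty <- data.frame(target = character(0), covariate = character(0),
                      condition = character(0),
                      orig_t = numeric(0), orig_df = numeric(0),
                      orig_p = numeric(0), orig_bf10 = numeric(0),
                      adj_t = numeric(0), adj_df = numeric(0),
                      adj_p = numeric(0), adj_bf10 = numeric(0),
                      relation = character(0), stringsAsFactors = FALSE)
  if (length(active) < 2L) {
    notice <- sprintf(
      "mediation analysis for '%s' skipped: %d active ROI(s), need >= 2",
      condition, length(active))
    message(notice)
    attr(empty, "notice") <- notice
    class(empty) <- c("mediation_matrix", "data.frame")
    return(empty)
  }
  m <- compound_matrix(est, condition, rois = active)
  originals <- lapply(active, function(roi) jzs_one_sample(m[, roi], prior))
  names(originals) <- active
  pairs <- expand.grid(covariate = active, target = active,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$target != pairs$covariate, c("target", "covariate")]
  pairs <- pairs[order(pairs$target, pairs$covariate), ]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    tgt <- pairs$target[i]; cov <- pairs$covariate[i]
    orig <- originals[[tgt]]
    adj <- partial_intercept_test(m[, tgt], m[, cov], prior = prior)
    data.frame(target = tgt, covariate = cov, condition = condition,
               orig_t = orig$t, orig_df = orig$df, orig_p = orig$p,
               orig_bf10 = orig$bf10,
               adj_t = adj$t, adj_df = adj$df, adj_p = adj$p,
               adj_bf10 = adj$bf10,
               relation = classify_relation(orig, adj),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mediation_matrix", "data.frame")
  out
}

#' Square grid of relation labels from a mediation matrix
#'
#' @param mat output of [mediation_matrix()].
#' @return character matrix, rows = targets, columns = covariates; the
#'   diagonal is `"-"`.
#' @export
relation_grid <- function(mat) {
  stopifnot(inherits(mat, "mediation_matrix"))
  rois <- sort(unique(c(mat$target, mat$covariate)))
  g <- matrix("-", length(rois), length(rois), dimnames = list(rois, rois))
  g[cbind(match(mat$target, rois), match(mat$covariate, rois))] <- mat$relation
  g
}
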