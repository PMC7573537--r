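## Synthetic data with known ground truth -----------------------------------
##
## The generator emulates the structure of the study the pipeline targets:
## 30 participants, 16 lateralised ROIs, 131 contrasts partitioned into
## execution / proactive-inhibition / reactive-inhibition sets. For each
## participant, ROI and condition a latent mean is drawn around the
## scenario's true mean with between-participant spread tau; every contrast
## observation adds independent within-participant noise sigma. Optional
## coupling directives replace a target ROI's latent mean with a linear
## function of a covariate ROI's latent mean, giving the mediation screen a
## recoverable ground truth.

#' Parameters for the synthetic %BOLD generator
#'
#' Defaults mirror the emulated study: 30 participants and 131 contrasts.
#' The published analysis does not state how the 131 contrasts split across
#' conditions, so near-equal thirds (44/44/43) are used. Default magnitudes
#' (effects of 0.3 %BOLD where a scenario is active, tau = 0.2 between
#' participants, sigma = 0.3 between contrasts) are plausible ROI-level
#' values; only their ratios matter for recovery behaviour.
#'
#' @param n_participants number of participants (>= 2).
#' @param contrast_counts named counts per condition; names must be the
#'   three base conditions.
#' @param roi_means numeric matrix of true mean %BOLD, rows = the 16 ROI
#'   ids, columns = the three base conditions. `NULL` means all zero.
#' @param between_participant_sd tau, SD of participant latent means
#'   (%BOLD).
#' @param within_participant_contrast_sd sigma, SD of per-contrast noise
#'   (%BOLD).
#' @param coupling `NULL`, or a data frame with columns `target`,
#'   `covariate` (ROI ids), `condition`, `intercept`, `slope`, `resid_sd`;
#'   the directed coupling graph must be acyclic within each condition.
#' @param seed integer RNG seed used by [generate_dataset()].
#' @return object of class `synthetic_params`.
#' @export
synthetic_params <- function(n_participants = 30,
                             contrast_counts = c(execution = 44,
                                                 inhibition_pro = 44,
                                                 inhibition_reac = 43),
                             roi_means = NULL,
                             between_participant_sd = 0.2,
                             within_participant_contrast_sd = 0.3,
                             coupling = NULL,
                             seed = 1L) {
  if (n_participants < 2) {
    pbf_stop("invalid_params", "n_participants must be >= 2")
  }
  if (!all(CONDITIONS %in% names(contrast_counts)) ||
      any(contrast_counts[CONDITIONS] < 1)) {
    pbf_stop("invalid_params",
             "contrast_counts must name all three conditions with counts >= 1")
  }
  contrast_counts <- contrast_counts[CONDITIONS]
  if (is.null(roi_means)) {
    roi_means <- matrix(0, nrow = 16, ncol = 3,
                        dimnames = list(roi_ids(), CONDITIONS))
  }
  stopifnot(is.matrix(roi_means),
            identical(rownames(roi_means), roi_ids()),
            identical(colnames(roi_means), CONDITIONS))
  if (between_participant_sd < 0 || within_participant_contrast_sd < 0) {
    pbf_stop("invalid_params", "standard deviations must be >= 0")
  }
  if (!is.null(coupling)) {
    needed <- c("target", "covariate", "condition", "intercept", "slope",
                "resid_sd")
    if (!all(needed %in% names(coupling))) {
      pbf_stop("invalid_params", sprintf(
        "coupling must have columns: %s", paste(needed, collapse = ", ")))
    }
    coupling$target <- parse_roi(coupling$target)
    coupling$covariate <- parse_roi(coupling$covariate)
    if (any(coupling$resid_sd < 0)) {
      pbf_stop("invalid_params", "coupling resid_sd must be >= 0")
    }
    for (cn in unique(coupling$condition)) {
      check_condition(cn, allow_all = FALSE)
      sub <- coupling[coupling$condition == cn, ]
      if (anyDuplicated(sub$target)) {
        pbf_stop("invalid_params",
                 "at most one coupling directive per target ROI per condition")
      }
      topological_order(sub) # errors on cycles
    }
  }
  structure(list(n_participants = as.integer(n_participants),
                 contrast_counts = contrast_counts,
                 roi_means = roi_means,
                 between_participant_sd = between_participant_sd,
                 within_participant_contrast_sd = within_participant_contrast_sd,
                 coupling = coupling,
                 seed = as.integer(seed),
                 scenario = NA_character_),
            class = "synthetic_params")
}

## Kahn's algorithm on the coupling edges (covariate -> target);
## errors with class cyclic_coupling if no full ordering exists
topological_order <- function(edges) {
  nodes <- unique(c(edges$target, edges$covariate))
  ordered <- character(0)
  while (length(ordered) < length(nodes)) {
    pending <- edges[!(edges$covariate %in% ordered), , drop = FALSE]
    free <- setdiff(nodes, c(ordered, pending$target))
    if (length(free) == 0L) {
      pbf_stop("cyclic_coupling", "coupling directives form a cycle")
    }
    ordered <- c(ordered, free)
  }
  ordered
}

#' Generate a synthetic %BOLD table with ground truth
#'
#' For participant i, ROI k, condition c the latent mean is
#' `m = mu[k, c] + b`, `b ~ Normal(0, tau^2)` (drawn independently per
#' participant, ROI and condition); a coupling directive targeting k
#' replaces this with `intercept + slope * m_covariate + Normal(0,
#' resid_sd^2)`. Each contrast assigned to c then yields an observation
#' `m + Normal(0, sigma^2)`. All draws use R's default Mersenne-Twister
#' stream seeded from `seed`, in a fixed order, so output is reproducible
#' bit-for-bit across platforms.
#'
#' @param params a [synthetic_params()].
#' @param seed RNG seed; defaults to `params$seed`.
#' @return list with elements
#'   * `table` — a [bold_table()];
#'   * `assignment` — the matching [contrast_assignment()];
#'   * `truth` — list with the realised latent participant means
#'     (`latent_means`, long data frame), the generating `params` and the
#'     `scenario` label if a preset was used.
#' @export
generate_dataset <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n <- params$n_participants
  rois <- roi_ids()
  participants <- sprintf("p%02d", seq_len(n))
  tau <- params$between_participant_sd
  sigma <- params$within_participant_contrast_sd

  contrast_ids <- lapply(CONDITIONS, function(cn) {
    sprintf("%s_%03d", cn, seq_len(params$contrast_counts[[cn]]))
  })
  names(contrast_ids) <- CONDITIONS

  latent <- list()
  obs <- list()
  for (cn in CONDITIONS) {
    m <- matrix(rnorm(n * length(rois), mean = 0, sd = tau),
                nrow = n, ncol = length(rois),
                dimnames = list(participants, rois))
    m <- sweep(m, 2, params$roi_means[, cn], `+`)
    cpl <- params$coupling
    if (!is.null(cpl)) {
      cpl <- cpl[cpl$condition == cn, , drop = FALSE]
      if (nrow(cpl)) {
        ord <- topological_order(cpl)
        for (roi in intersect(ord, cpl$target)) {
          d <- cpl[cpl$target == roi, ]
          m[, roi] <- d$intercept + d$slope * m[, d$covariate] +
            rnorm(n, 0, d$resid_sd)
        }
      }
    }
    latent[[cn]] <- data.frame(
      participant = rep(participants, times = length(rois)),
      roi = rep(rois, each = n),
      condition = cn,
      latent_mean = as.vector(m),
      stringsAsFactors = FALSE)
    for (cid in contrast_ids[[cn]]) {
      noise <- matrix(rnorm(n * length(rois), 0, sigma), nrow = n)
      vals <- m + noise
      obs[[cid]] <- data.frame(
        participant = rep(participants, times = length(rois)),
        contrast = cid,
        roi = rep(rois, each = n),
        value = as.vector(vals),
        stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, obs)
  rownames(table) <- NULL
  table <- validate_bold_table(table)
  assignment <- contrast_assignment(
    unlist(contrast_ids, use.names = FALSE),
    rep(CONDITIONS, times = vapply(contrast_ids, length, integer(1))))
  truth <- list(latent_means = do.call(rbind, latent),
                params = params, scenario = params$scenario)
  list(table = table, assignment = assignment, truth = truth)
}

#' Built-in simulation scenarios
#'
#' Named [synthetic_params()] presets with known ground truth:
#' * `null` — all true means zero;
#' * `direct_execution_left` — effect on left STR, GPi, SN, THAL under
#'   execution (the direct pathway engaged by right-hand responses);
#' * `indirect_inhibition_right` — effect on all six right subcortical
#'   structures under both inhibition conditions;
#' * `hyperdirect_inhibition_right` — effect on right GPi, STN, SN, THAL
#'   under both inhibition conditions;
#' * `full_mediation_pair` — active covariate (R_STN) whose latent mean
#'   fully determines the target (R_THAL: intercept 0, slope 1) under
#'   inhibition, so the intercept test should classify the pair as
#'   mediated;
#' * `independent_pair` — R_STN and R_THAL both active (mean 0.5,
#'   tau = 0.1) but generated independently, so mediation should *not* be
#'   declared.
#'
#' @param effect true mean %BOLD in active ROIs (default 0.3).
#' @param ... further arguments passed to [synthetic_params()] (e.g.
#'   `n_participants`, noise levels).
#' @return named list of `synthetic_params`.
#' @export
scenario_presets <- function(effect = 0.3, ...) {
  zeros <- function() matrix(0, 16, 3, dimnames = list(roi_ids(), CONDITIONS))
  with_means <- function(rois, conditions, value = effect, ...) {
    mu <- zeros()
    mu[rois, conditions] <- value
    synthetic_params(roi_means = mu, ...)
  }
  inhib <- c("inhibition_pro", "inhibition_reac")
  presets <- list(
    null = synthetic_params(roi_means = zeros(), ...),
    direct_execution_left =
      with_means(c("L_STR", "L_GPi", "L_SN", "L_THAL"), "execution", ...),
    indirect_inhibition_right =
      with_means(paste0("R_", ROI_SUBCORTICAL), inhib, ...),
    hyperdirect_inhibition_right =
      with_means(c("R_GPi", "R_STN", "R_SN", "R_THAL"), inhib, ...),
    full_mediation_pair = {
      mu <- zeros()
      mu["R_STN", inhib] <- 0.5
      synthetic_params(
        roi_means = mu,
        coupling = data.frame(target = "R_THAL", covariate = "R_STN",
                              condition = inhib, intercept = 0, slope = 1,
                              resid_sd = 0.05, stringsAsFactors = FALSE),
        ...)
    },
    independent_pair =
      with_means(c("R_STN", "R_THAL"), inhib, value = 0.5,
                 between_participant_sd = 0.1, ...)
  )
  for (nm in names(presets)) presets[[nm]]$scenario <- nm
  presets
}
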