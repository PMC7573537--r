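test_that("the intercept test matches an independent normal-equations fit", {
  set.seed(17)
  cov <- rnorm(30, 0.5, 0.2)
  tgt <- 0.5 + 0 * cov + rnorm(30, 0, 0.1)
  res <- partial_intercept_test(tgt, cov)
  expect_equal(res$df, 28)
  expect_equal(res$t, normal_equations_intercept_t(tgt, cov),
               tolerance = 1e-9)
  expect_equal(res$bf10,
               jzs_bf_from_t(res$t, df = 28, n_eff = 30)$bf10)
})

test_that("with a flat estimated slope the intercept t tracks the one-sample t", {
  # orthogonalise the covariate so beta1-hat is 0 exactly; then the
  # intercept estimate and residuals coincide with the one-sample ones and
  # only the df differ (N-2 vs N-1)
  set.seed(23)
  tgt <- rnorm(30, 0.5, 0.1)
  cov <- rnorm(30, 0, 1)
  cov <- resid(lm(cov ~ tgt))  # orthogonal to tgt and to the constant
  res <- partial_intercept_test(tgt, cov)
  t1 <- jzs_one_sample(tgt)$t
  # same estimate and residuals, df 28 instead of 29
  expect_equal(res$t, t1 * sqrt(28 / 29), tolerance = 1e-9)
})

test_that("perfect mediation and degenerate covariates hit their limits", {
  x <- c(0.4, 0.5, 0.6, 0.7, 0.3)
  res <- partial_intercept_test(x, x)   # target == covariate elementwise
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_lt(res$bf10, 1)

  expect_error(partial_intercept_test(x, rep(1, 5)),
               class = "pathwaybf_error_degenerate_covariate")
  expect_error(partial_intercept_test(x[1:3], x[1:3]),
               class = "pathwaybf_error_insufficient_data")
  expect_error(partial_intercept_test(x, x[1:3]),
               class = "pathwaybf_error_length_mismatch")
})

test_that("relation classification follows the threshold rules", {
  br <- function(bf, p = 0.5) {
    structure(list(t = 1, df = 29, n_eff = 30, p = p, bf10 = bf,
                   category = interpret_bf(bf)), class = "bayes_result")
  }
  orig <- br(20, p = 0.001)
  expect_equal(classify_relation(orig, br(0.2, p = 0.4)), "mediated")
  expect_equal(classify_relation(orig, br(1.5, p = 0.03)), "moderated")
  expect_equal(classify_relation(orig, br(25, p = 1e-4)), "unchanged")
  expect_equal(classify_relation(orig, br(5, p = 0.01)), "unchanged")
  # BF and p disagree: below 1/3 yet still significant -> flagged
  expect_equal(classify_relation(orig, br(0.2, p = 0.01)), "inconsistent")
  # not reduced at all counts as unchanged even when below 3
  expect_equal(classify_relation(br(1.5), br(2.0, p = 0.2)), "unchanged")
})

test_that("the mediation matrix is directional and ordered", {
  set.seed(41)
  n <- 30
  cov <- rnorm(n, 0.5, 0.2)
  est <- make_est(list(R_STN = cov,
                       R_THAL = cov + rnorm(n, 0, 0.05),
                       L_STR = rnorm(n, 0, 0.2)))
  mat <- mediation_matrix(est, "execution")
  expect_s3_class(mat, "mediation_matrix")
  expect_equal(nrow(mat), 2L)  # two active ROIs, both directions
  expect_equal(mat$target, sort(mat$target))
  expect_setequal(unique(c(mat$target, mat$covariate)),
                  c("R_STN", "R_THAL"))
  g <- relation_grid(mat)
  expect_equal(diag(g), c("-", "-"), ignore_attr = TRUE)
})

test_that("fewer than two active ROIs yields an informative empty result", {
  set.seed(4)
  est <- make_est(list(R_STN = rnorm(30, 0.8, 0.2),
                       L_STR = rnorm(30, 0, 0.2)))
  expect_message(mat <- mediation_matrix(est, "execution"), "1 active")
  expect_equal(nrow(mat), 0L)
  expect_match(attr(mat, "notice"), "need >= 2")
})

test_that("coupled and independent presets separate in the mediation screen", {
  # Under full mediation the adjusted intercept t is (nearly) central, so
  # the covariate always at least reduces the target's evidence; whether
  # the reduction crosses the BF < 1/3 line in a single replicate is
  # stochastic. Independent active ROIs must never be called mediated.
  presets <- scenario_presets()
  run_one <- function(preset, seed) {
    sim <- generate_dataset(preset, seed = seed)
    est <- compound_estimates(sim$table, sim$assignment)
    suppressMessages(mediation_matrix(est, "inhibition_all"))
  }
  seeds <- 1:12
  full <- vapply(seeds, function(s) {
    mat <- run_one(presets$full_mediation_pair, s)
    mat$relation[mat$target == "R_THAL" & mat$covariate == "R_STN"]
  }, character(1))
  expect_gte(mean(full %in% c("mediated", "moderated")), 0.75)
  expect_gt(mean(full == "mediated"), 0.25)

  indep <- unlist(lapply(seeds, function(s) {
    mat <- run_one(presets$independent_pair, s)
    pair <- mat[mat$target %in% c("R_STN", "R_THAL") &
                  mat$covariate %in% c("R_STN", "R_THAL"), ]
    pair$relation
  }))
  expect_false(any(indep == "mediated"))
})
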