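test_that("default membership maps encode the three pathways per hand", {
  m <- default_pathway_models("right")
  expect_setequal(m$hyperdirect$members, c("R_GPi", "R_STN", "R_SN", "R_THAL"))
  expect_setequal(m$direct$members, c("L_STR", "L_GPi", "L_SN", "L_THAL"))
  expect_setequal(m$indirect$members,
                  paste0("R_", c("STR", "GPe", "GPi", "SN", "STN", "THAL")))
  # non-members: remaining same-hemisphere plus all six contralateral
  expect_setequal(m$hyperdirect$non_members,
                  c("R_GPe", "R_STR", paste0("L_", c("STR", "GPe", "GPi",
                                                     "SN", "STN", "THAL"))))
  for (pw in m) {
    expect_setequal(c(pw$members, pw$non_members),
                    roi_ids(subcortical = TRUE))
  }
  # left hand mirrors every hemisphere
  ml <- default_pathway_models("left")
  expect_equal(sort(ml$hyperdirect$members),
               sort(sub("^R", "L", m$hyperdirect$members)))
  expect_equal(sort(ml$direct$members),
               sort(sub("^L", "R", m$direct$members)))

  expect_error(pathway_model("x", "R", c("GPi", "IFG")),
               class = "pathwaybf_error_invalid_pathway")
})

test_that("evidence products follow the member/inverse-non-member rule", {
  hyper <- default_pathway_models()$hyperdirect
  expect_equal(evidence_product(bf_map(1), hyper)$bf_product, 1)

  # one member at 4, two non-members at 0.5: 4 * 2 * 2 = 16
  toy <- bf_map(1, R_STN = 4, L_STR = 0.5, L_GPe = 0.5)
  sc <- evidence_product(toy, hyper)
  expect_equal(sc$bf_product, 16)
  expect_equal(nrow(sc$ledger), 12L)
  expect_equal(sum(sc$ledger$role == "member"), 4L)

  expect_error(evidence_product(toy[-1], hyper),
               class = "pathwaybf_error_missing_roi")
  bad <- bf_map(1); bad["R_STN"] <- -2
  expect_error(evidence_product(bad, hyper),
               class = "pathwaybf_error_nonpositive_bf")
})

test_that("log contributions add up and are permutation invariant", {
  set.seed(5)
  bfs <- bf_map(1)
  bfs[] <- exp(rnorm(12, 0, 2))
  hyper <- default_pathway_models()$hyperdirect
  sc <- evidence_product(bfs, hyper)
  expect_equal(sc$log10_bf_product, sum(sc$ledger$log10_contribution),
               tolerance = 1e-9)
  perm <- sample(names(bfs))
  expect_equal(evidence_product(bfs[perm], hyper)$log10_bf_product,
               sc$log10_bf_product)
})

test_that("swapping members and non-members inverts the product exactly", {
  set.seed(6)
  bfs <- bf_map(1)
  bfs[] <- exp(rnorm(12, 0, 1.5))
  hyper <- default_pathway_models()$hyperdirect
  swapped <- structure(list(name = "swapped", hemisphere = "R",
                            members = hyper$non_members,
                            non_members = hyper$members),
                       class = "pathway_model")
  expect_equal(evidence_product(bfs, hyper)$log10_bf_product,
               -evidence_product(bfs, swapped)$log10_bf_product,
               tolerance = 1e-12)
})

test_that("published per-ROI Bayes factors reproduce the published grid", {
  pub <- published_roi_bf()
  expect_equal(nrow(pub), 16L)
  tabs <- list(execution = setNames(pub$execution, pub$roi),
               inhibition_all = setNames(pub$inhibition, pub$roi))
  grid <- evidence_table(models = default_pathway_models("right"),
                         conditions = names(tabs), bf_tables = tabs)
  cell <- function(cond, pw) grid$bf_product[grid$condition == cond &
                                               grid$pathway == pw]
  # published products; inputs are 2-decimal rounded, hence 5% tolerance
  expect_equal(cell("execution", "direct"), 21.945, tolerance = 0.05)
  expect_equal(cell("execution", "indirect"), 0.002, tolerance = 0.05)
  expect_equal(cell("execution", "hyperdirect"), 0.056, tolerance = 0.05)
  expect_equal(cell("inhibition_all", "direct"), 1.917e-9, tolerance = 0.05)
  expect_equal(cell("inhibition_all", "indirect"), 3.216e11, tolerance = 0.05)
  expect_equal(cell("inhibition_all", "hyperdirect"), 558.224,
               tolerance = 0.05)
  expect_equal(grid$matched, c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("roi_bf_table computes all twelve subcortical Bayes factors", {
  p <- scenario_presets()$null
  p$contrast_counts <- c(execution = 6, inhibition_pro = 3,
                         inhibition_reac = 3)
  sim <- generate_dataset(p, seed = 19)
  est <- compound_estimates(sim$table, sim$assignment)
  bfs <- roi_bf_table(est, "execution")
  expect_setequal(names(bfs), roi_ids(subcortical = TRUE))
  expect_true(all(bfs > 0))
  expect_gt(mean(bfs < 3), 0.5)  # null scenario: mostly weak evidence

  # degenerate (zero-variance) cells surface the guard per ROI
  p0 <- scenario_presets()$null
  p0$between_participant_sd <- 0
  p0$within_participant_contrast_sd <- 0
  sim0 <- generate_dataset(p0, seed = 1)
  est0 <- compound_estimates(sim0$table, sim0$assignment)
  expect_error(roi_bf_table(est0, "execution"),
               class = "pathwaybf_error_degenerate_sample")
})

test_that("the evidence grid crosses every condition with every pathway", {
  p <- scenario_presets(n_participants = 12)$hyperdirect_inhibition_right
  p$contrast_counts <- c(execution = 4, inhibition_pro = 4,
                         inhibition_reac = 4)
  sim <- generate_dataset(p, seed = 2)
  est <- compound_estimates(sim$table, sim$assignment)
  grid <- evidence_table(est)
  expect_equal(nrow(grid), 12L)
  expect_setequal(unique(grid$condition),
                  c("execution", "inhibition_all", "inhibition_pro",
                    "inhibition_reac"))
  expect_equal(sum(grid$matched), 7L)
  # matched hyperdirect inhibition cells should beat the mismatched
  # execution/hyperdirect control cell
  hd <- grid[grid$pathway == "hyperdirect", ]
  expect_gt(hd$log10_bf_product[hd$condition == "inhibition_all"],
            hd$log10_bf_product[hd$condition == "execution"])
})
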