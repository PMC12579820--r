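test_that("power-law draws are seeded, supported above xmin, and estimator-consistent", {
  x1 <- rpowerlaw(500, 2.5, seed = 8)
  x2 <- rpowerlaw(500, 2.5, seed = 8)
  expect_identical(x1, x2)
  expect_true(all(x1 >= 1))
  x3 <- rpowerlaw(300, 3, xmin = 4, seed = 9)
  expect_true(all(x3 >= 4))
  expect_error(rpowerlaw(10, 1), "> 1")
  # generator and estimator agree at scale
  big <- rpowerlaw(50000, 2.5, seed = 10)
  expect_equal(fit_powerlaw(big, xmin = 1)$alpha, 2.5, tolerance = 0.05)
  # draw frequencies track the pmf at the head of the support
  f1 <- mean(big == 1)
  expect_equal(f1, 1 / hurwitz_zeta(2.5, 1), tolerance = 0.02)
})

test_that("deep-tail inversion matches the zeta tail exactly", {
  # quantile function: smallest x with P(X >= x + 1) <= v
  for (v in c(0.5, 1e-3, 1e-7, 1e-11)) {
    x <- ighclonal:::qpowerlaw_tail(v, 2.5, 1)
    expect_lte(powerlaw_tail(x + 1, 2.5, 1), v)
    if (x > 1) expect_gt(powerlaw_tail(x, 2.5, 1), v)
  }
})

test_that("repertoire generation respects the configured composition", {
  cfg <- sim_config(n_clones = 400, frac_incomplete = 0.25, seed = 13,
    disease_spec = list(list(type = "INCOMPLETE", target_e = 1e-6),
                        list(type = "COMPLETE", target_e = 1e-6)))
  g <- generate_repertoire(cfg)
  expect_equal(nrow(g$repertoire$clones), 402L)
  expect_equal(sum(g$truth$clones$is_disease), 2L)
  expect_equal(g$truth$clonotype, "IDC")
  frac_inc <- mean(g$repertoire$clones$rearrangement_type == "INCOMPLETE")
  expect_gt(frac_inc, 0.15); expect_lt(frac_inc, 0.35)
  # no disease spec: truth clonotype is UDC
  expect_equal(generate_repertoire(sim_config(n_clones = 50,
                                              seed = 2))$truth$clonotype,
               "UDC")
  # identical seeds give identical repertoires
  expect_identical(generate_repertoire(cfg), g)
})

test_that("disease placement by target e-value is computed from the true background", {
  cfg <- sim_config(n_clones = 300, alpha = 2.5, seed = 14,
    disease_spec = list(list(type = "COMPLETE", target_e = 1e-5)))
  g <- generate_repertoire(cfg)
  dis <- g$repertoire$clones[g$truth$clones$is_disease, ]
  n_tail <- 300  # all background counts are >= xmin = 1
  e_at <- n_tail * powerlaw_tail(dis$read_count, 2.5, 1)
  e_above <- n_tail * powerlaw_tail(dis$read_count - 1, 2.5, 1)
  expect_lte(e_at, 1e-5 * (1 + 1e-8))  # placed at the smallest such count:
  expect_gt(e_above, 1e-5)   # one read fewer would miss the target
  # an unreachable truth (target at or above the threshold) is rejected
  expect_error(sim_config(disease_spec = list(
    list(type = "COMPLETE", target_e = 0.5))), "not below")
})

test_that("planted disease clones are recovered across seeds", {
  hits <- vapply(1:60, function(s) {
    g <- generate_repertoire(sim_config(n_clones = 264, seed = 5000 + s,
      disease_spec = list(list(type = "COMPLETE", target_e = 1e-4))))
    calls <- call_disease_clones(g$repertoire)
    id <- g$truth$clones$clone_id[g$truth$clones$is_disease]
    identical(calls$calls$status[calls$calls$clone_id == id], "DISEASE")
  }, FALSE)
  expect_gte(mean(hits), 0.95)
})

test_that("paired generation realizes the planned patterns and overlap extremes", {
  p <- generate_paired(sim_config(n_clones = 200), sim_config(n_clones = 200),
                       pattern_plan = c("B", "C"), overlap = 0.5, seed = 33)
  pc <- summarize_patient(p$diagnosis, p$relapse)
  expect_setequal(pc$patterns_present, c("B", "C"))
  expect_true(pc$clonality_changed)
  expect_equal(sort(p$truth$patterns$pattern), c("B", "C"))
  # zero overlap with nothing planned: disjoint repertoires
  p0 <- generate_paired(sim_config(n_clones = 100), sim_config(n_clones = 100),
                        overlap = 0, seed = 34)
  expect_equal(morisita_horn(align_by_identity(p0$diagnosis, p0$relapse)), 0)
  # a persisting clone cannot exist without any sharing
  expect_error(generate_paired(pattern_plan = "A", overlap = 0),
               "overlap")
})

test_that("cohort generation follows the clonotype mix with seeded determinism", {
  co <- generate_cohort(40, seed = 15, repertoires = FALSE)
  expect_equal(nrow(co$metadata), 40L)
  expect_true(all(co$truth$clonotype %in% c("UDC", "IDC", "CDC")))
  co2 <- generate_cohort(40, seed = 15, repertoires = FALSE)
  expect_identical(co, co2)
  # degenerate mix forces the label
  co3 <- generate_cohort(10, clonotype_mix = c(UDC = 0, IDC = 1, CDC = 0),
                         seed = 16, repertoires = FALSE)
  expect_true(all(co3$truth$clonotype == "IDC"))
  expect_error(generate_cohort(10, clonotype_mix = c(UDC = 0.5, IDC = 0.2,
                                                     CDC = 0.2)),
               "sum to 1")
})

test_that("under the independent covariate model the age test is null-calibrated", {
  p_vals <- vapply(1:200, function(s) {
    co <- generate_cohort(10000, seed = 7000 + s, repertoires = FALSE)
    tab <- build_contingency(co$truth$clonotype, co$metadata$age_group)
    chi_square_independence(tab)$p_value
  }, numeric(1))
  frac <- mean(p_vals < 0.05)
  expect_gte(frac, 0.02); expect_lte(frac, 0.09)
})

test_that("the age-associated covariate model yields a detectable signal", {
  co <- generate_cohort(500, covariate_model = "age_assoc", seed = 18,
                        repertoires = FALSE)
  tab <- build_contingency(co$truth$clonotype, co$metadata$age_group)
  expect_lt(chi_square_independence(tab)$p_value, 0.01)
})
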