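test_that("half-lives at the three reference Cand1 doses match the model family", {
  expect_equal(fig3_run(0)$t_half_min[1], 48, tolerance = 0.05)
  expect_equal(fig3_run(100)$t_half_min[1], 28, tolerance = 0.05)
  expect_equal(fig3_run(1000)$t_half_min[1], 95, tolerance = 0.05)
  # flux bound: without Cand1 the pre-assembled pool 300*30/660 nM caps the
  # degradation flux, so t_half >= 150 / (kdeg * 13.64) s
  bound_min <- 150 / (0.004 * 300 * 30 / 660) / 60
  expect_gt(fig3_run(0)$t_half_min[1], bound_min)
})

test_that("total substrate decreases strictly and kdeg = 0 conserves it", {
  run <- fig3_run(100)
  ST <- run$substrate_total[, 1]
  meaningful <- ST > 1e-6 * 300          # above solver noise floor
  expect_true(all(diff(ST[meaningful]) < 0))
  tot <- pool_totals(300, 100, c(30, 630), 300)
  run0 <- run_degradation(tbl_params, tot,
                          substrate_params(1e8, 1, kdeg = 0),
                          t_max = 1e4, n_out = 120)
  expect_true(run0$censored[1])
  expect_true(is.na(run0$t_half_min[1]))
  expect_lt(diff(range(run0$substrate_total[, 1])) / 300, 1e-6)
})

test_that("t_half is insensitive to solver tolerance refinement", {
  run_a <- fig3_run(100)
  run_b <- run_degradation(tbl_params, deg_totals,
                           substrate_params(1e8, 1, 0.004),
                           cand1_total = 100, rtol = 1e-10, atol = 1e-13)
  expect_equal(run_a$t_half_min[1], run_b$t_half_min[1], tolerance = 1e-3)
})

test_that("dose response is non-monotone at diffusion-limited kon, monotone at low kon", {
  sub_hi <- substrate_params(1e8, 1, 0.004)
  dr_hi <- cand1_dose_response(tbl_params, deg_totals, sub_hi,
                               cand1_grid = c(0, 30, 60, 120, 300, 1000),
                               refine = TRUE, refine_tol = 10)
  expect_false(dr_hi$monotone)
  expect_lte(dr_hi$optimum_cand1_nM, 120)
  expect_gt(dr_hi$optimum_cand1_nM, 0)
  # weak-binding substrate: Cand1 only hurts
  sub_lo <- substrate_params(3e5, 1, 0.004)
  dr_lo <- cand1_dose_response(tbl_params, deg_totals, sub_lo,
                               cand1_grid = c(0, 30, 120, 300),
                               refine = FALSE, t_max = 1e6)
  expect_true(dr_lo$monotone)
  expect_true(all(diff(dr_lo$curve$t_half_min) > 0))
})

test_that("redistribution decomposition closes and identifies the reservoir", {
  rd <- redistribution_analysis(fig3_run(100))
  # conservation closure at every output time
  expect_lt(rd$closure_error, 1e-6)
  expect_equal(rd$dominant, "Cul1.SR2")
  expect_gt(rd$peak_fold, 2)
  # after degradation completes the pool returns to pre-stimulus level
  expect_lt(abs(rd$Delta[length(rd$Delta)]), 0.05)
  rd_hi <- redistribution_analysis(fig3_run(1000))
  expect_equal(rd_hi$dominant, "Cul1.Cand1")
  expect_lt(rd_hi$closure_error, 1e-6)
})

test_that("hierarchy variants order the half-lives as expected", {
  ref <- hierarchy_fix("reference")
  expect_equal(ref$t_half_min[1], ref$t_half_min[2], tolerance = 1e-6)
  ha <- hierarchy_fix("affinity_substrate")   # S1 binds its SR 5x weaker
  expect_lt(ha$t_half_min[2], ha$t_half_min[1])
  hb <- hierarchy_fix("affinity_receptor")    # SR1 binds Cul1 5x weaker
  expect_lt(hb$t_half_min[2], hb$t_half_min[1])
  hc <- hierarchy_fix("abundance")            # SR1 pool 90 vs 30 nM
  expect_lt(hc$t_half_min[1], hc$t_half_min[2])
  # unused receptor pool dips and recovers while engaged fractions rise
  for (h in list(ha, hb, hc)) {
    occ3 <- h$occupancy_fraction$sr3
    expect_lt(min(occ3), occ3[1] - 0.001)
    expect_gt(occ3[length(occ3)], min(occ3))
    expect_gt(max(h$occupancy_fraction$sr1), h$occupancy_fraction$sr1[1])
  }
})

test_that("hierarchy asymmetry is mirror-symmetric between the branches", {
  # swapping which substrate carries the 5x kon penalty mirrors the order
  tot <- pool_totals(300, 400, c(60, 60, 540), c(300, 300))
  subs_1weak <- list(substrate_params(2e7, 1, 0.004, receptor = 1L),
                     substrate_params(1e8, 1, 0.004, receptor = 2L))
  subs_2weak <- list(substrate_params(1e8, 1, 0.004, receptor = 1L),
                     substrate_params(2e7, 1, 0.004, receptor = 2L))
  r1 <- run_degradation(tbl_params, tot, subs_1weak, n_out = 250)
  r2 <- run_degradation(tbl_params, tot, subs_2weak, n_out = 250)
  expect_equal(r1$t_half_min[1], r2$t_half_min[2], tolerance = 1e-6)
  expect_equal(r1$t_half_min[2], r2$t_half_min[1], tolerance = 1e-6)
})
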