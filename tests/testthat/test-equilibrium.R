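test_that("equilibrium solver reproduces known occupancies", {
  ss <- table1_steady()
  eq <- ss$equilibrium
  # printed working point of the occupancy/exchange trade-off
  expect_equal(eq$complexes$cul1_sr[1], 6.4, tolerance = 0.01)
  # total SCF pool from the independent three-conservation oracle below
  expect_equal(sum(eq$complexes$cul1_sr), 42.48, tolerance = 0.005)
  # steady state in the strict sense
  expect_lt(ss$rhs_norm, 1e-10)
  # equilibrium relations hold for all four reactions simultaneously
  with(eq, {
    expect_equal(complexes$cul1_sr,
                 free$cul1 * free$sr / tbl_params$Ksr, tolerance = 1e-9)
    expect_equal(complexes$cul1_cand1,
                 free$cul1 * free$cand1 / tbl_params$Kca, tolerance = 1e-9)
    expect_equal(complexes$ternary,
                 complexes$cul1_cand1 * free$sr / tbl_params$Ksr_prime,
                 tolerance = 1e-9)
    expect_equal(complexes$ternary,
                 complexes$cul1_sr * free$cand1 / tbl_params$Kca_prime,
                 tolerance = 1e-9)
  })
})

test_that("equal receptor pools give equal occupancies; no Cand1 gives competitive split", {
  eq <- solve_equilibrium(tbl_params, pool_totals(300, 390, c(330, 330)))
  expect_equal(eq$complexes$cul1_sr[1], eq$complexes$cul1_sr[2],
               tolerance = 1e-10)
  # Cand1-free, quasi-irreversible binding: Cul1 partitions as SRi_T/SR_T
  eq0 <- solve_equilibrium(tbl_params, pool_totals(300, 0, c(100, 560)))
  expect_equal(eq0$complexes$cul1_sr[1], 300 * 100 / 660, tolerance = 1e-3)
  expect_equal(eq0$complexes$cul1_cand1, 0)
})

test_that("algebraic and relaxation routes agree", {
  eq <- solve_equilibrium(tbl_params, pool_totals(300, 390, c(100, 560)),
                          cross_check = TRUE)
  expect_lt(eq$cross_check_dev, 1e-6)
  eq2 <- solve_equilibrium(tbl_params, pool_totals(300, 50, c(30, 630)),
                           cross_check = TRUE)
  expect_lt(eq2$cross_check_dev, 1e-6)
})

test_that("slope f matches its closed form and stays inside (0, 1)", {
  tot <- pool_totals(300, 390, c(100, 560))
  f <- slope_f(tbl_params, tot)
  expect_equal(f, 0.9439, tolerance = 1e-3)
  # direct evaluation of the occupancy approximation at Cand1_T = 50
  expect_equal(occupancy_low_cand1(tbl_params,
                                   pool_totals(300, 50, c(100, 560))),
               (100 / 660) * (300 - f * 50), tolerance = 1e-12)
  # f -> 0 when eta*Ksr' >> Cul1_T
  p_big <- with_eta(tbl_params, 1e4)
  expect_lt(slope_f(p_big, tot), 0.01)
  expect_error(slope_f(tbl_params, pool_totals(700, 390, c(100, 560))),
               "saturated")
  # property: 0 < f < 1 over randomized valid parameter sets
  set.seed(42)
  for (i in 1:50) {
    p <- kinetic_params(Ksr = 10^runif(1, -5, 0), ksr = 10^runif(1, -7, -3),
                        Ksr_prime = 10^runif(1, 1, 4),
                        ksr_prime = 10^runif(1, -2, 1),
                        Kca_prime = 10^runif(1, 0, 3),
                        kca_prime = 10^runif(1, -3, 0),
                        kca = 10^runif(1, -6, -3))
    cul1 <- runif(1, 50, 500)
    tt <- pool_totals(cul1, 0, cul1 + c(runif(1, 10, 500), runif(1, 10, 500)))
    f_i <- slope_f(p, tt)
    expect_gt(f_i, 0); expect_lt(f_i, 1)
  }
})

test_that("high-Cand1 occupancy follows the 1/Cand1 law and matches numerics", {
  tot3k <- pool_totals(300, 3000, c(100, 560))
  v <- occupancy_high_cand1(tbl_params, tot3k)
  # direct formula: eta*Ksr' * (Cul1_T/Cand1_T) * SR1_T / (Ksr'+SR_T+Cul1_T)
  expect_equal(v, (50 / 650) * 650 * 0.1 * 100 / 1610, tolerance = 1e-12)
  tot6k <- pool_totals(300, 6000, c(100, 560))
  expect_equal(occupancy_high_cand1(tbl_params, tot6k), v / 2,
               tolerance = 1e-12)
  # the power law approaches the numeric equilibrium from below, with a
  # slowly vanishing correction: ~17% high at 10x Cul1_T, ~9% at 100x
  dev <- vapply(c(3e3, 1e4, 3e4), function(ca) {
    tt <- pool_totals(300, ca, c(100, 560))
    num <- solve_equilibrium(tbl_params, tt)$complexes$cul1_sr[1]
    abs(occupancy_high_cand1(tbl_params, tt) - num) / num
  }, numeric(1))
  expect_lt(dev[1], 0.2)
  expect_true(all(diff(dev) < 0))
})

test_that("exchange-rate limits bracket the numeric eigenvalue", {
  tot <- pool_totals(300, 390, c(100, 560))
  lims <- exchange_rate_limits(tbl_params, tot, cand1_total = 1e-9)
  expect_equal(unname(lims["low"]), tbl_params$ksr, tolerance = 1e-3)
  expect_equal(unname(lims["high"]),
               1.3 * (1 + (300 / 650) * 950 / 1610), tolerance = 1e-12)
  # numeric leading eigenvalue approaches the high-Cand1 plateau
  ss_hi <- steady_state(tbl_params, pool_totals(300, 1e4, c(100, 560)))
  expect_equal(ss_hi$exchange_rate, unname(lims["high"]), tolerance = 0.1)
  # low-Cand1 closed form tracks the numeric rate (systematic offset ~25%)
  ss_lo <- steady_state(tbl_params, pool_totals(300, 10, c(100, 560)))
  lo <- unname(exchange_rate_limits(tbl_params, tot, 10)["low"])
  expect_equal(lo, ss_lo$exchange_rate, tolerance = 0.3)
})

test_that("steady-state spectrum is stable and tau_s is the inverse rate", {
  ss <- table1_steady()
  expect_true(all(Re(ss$spectrum) < 0))
  expect_equal(ss$tau_s * ss$exchange_rate, 1)
  expect_equal(ss$exchange_rate, 0.11, tolerance = 0.02)
})

test_that("trade-off scan is monotone and curves overlap across eta", {
  grid <- 10^seq(0, 4, length.out = 25)
  sc <- tradeoff_scan(tbl_params, pool_totals(300, 390, c(100, 560)),
                      cand1_grid = grid, eta_values = c(0.077, 1))
  for (e in unique(sc$eta)) {
    s <- sc[sc$eta == e, ]
    expect_true(all(diff(s$occupancy_nM) < 0))
    expect_true(all(diff(s$exchange_rate_per_s) > -1e-12))
  }
  # occupancy brackets: linear approximation above, power law below the
  # numeric curve on their respective sides of Cand1_T = Cul1_T
  s <- sc[sc$eta == 0.077, ]
  lowc <- s$cand1_total_nM < 100
  for (i in which(lowc)) {
    app <- occupancy_low_cand1(
      tbl_params, pool_totals(300, s$cand1_total_nM[i], c(100, 560)))
    expect_equal(app, s$occupancy_nM[i], tolerance = 0.05)
  }
})

test_that("receptor-addition transient relaxes on the eigen timescale", {
  tr <- sr_addition_transient(tbl_params, pool_totals(300, 390, c(100, 560)),
                              added_sr1 = 100)
  expect_lt(abs(log(tr$t_relax / tr$tau_s)), log(2))  # within a factor of 2
  expect_lt(tr$tau_s, 60)                             # seconds at high Cand1
  # final occupancy equals the pooled equilibrium
  tc <- tr$timecourse
  expect_equal(tc$Cul1.SR1[nrow(tc)], tr$final_occupancy,
               tolerance = 1e-6)
  # low Cand1: minutes
  tr_lo <- sr_addition_transient(tbl_params, pool_totals(300, 10, c(100, 560)),
                                 added_sr1 = 100)
  expect_gt(tr_lo$t_relax, 300)
  # adding nothing changes nothing
  tr0 <- sr_addition_transient(tbl_params, pool_totals(300, 390, c(100, 560)),
                               added_sr1 = 0)
  expect_lt(diff(range(tr0$timecourse$Cul1.SR2)), 1e-6)
})
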