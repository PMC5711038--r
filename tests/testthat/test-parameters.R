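test_that("detailed balance residual behaves as direct arithmetic", {
  # published table values with Kca rounded to 1.73e-5 nM
  p_rounded <- kinetic_params(Ksr = 2.25e-4, ksr = 9e-7,
                              Ksr_prime = 650, ksr_prime = 1.3,
                              Kca_prime = 50, kca_prime = 0.04,
                              kca = 1e-5, Kca = 1.73e-5)
  # |1.73e-5*650 - 50*2.25e-4| / (50*2.25e-4)
  expect_equal(check_detailed_balance(p_rounded), 4.444444e-4,
               tolerance = 1e-5)
  # derived Kca balances the cycle exactly
  expect_equal(check_detailed_balance(default_params()), 0)
  # doubling Kca drives the residual to ~1
  p2 <- default_params()
  p2$Kca <- 2 * p2$Kca
  expect_equal(check_detailed_balance(p2), 1, tolerance = 1e-12)
  # a supplied Kca far off balance is rejected
  expect_error(
    kinetic_params(Ksr = 2.25e-4, ksr = 9e-7, Ksr_prime = 650,
                   ksr_prime = 1.3, Kca_prime = 50, kca_prime = 0.04,
                   kca = 1e-5, Kca = 1e-4),
    "detailed balance")
})

test_that("derived scale factors match their definitions", {
  p <- default_params()
  expect_equal(p$eta, 50 / 650)
  expect_equal(p$eta, p$Kca / p$Ksr)
  expect_equal(p$alpha, 1e-5 / 9e-7)
  expect_equal(p$beta, 0.04 / 1.3)
  expect_equal(p$Kca, 1.730769e-5, tolerance = 1e-6)
})

test_that("gamma scales the binary affinities but not eta or the ternary", {
  g <- 10
  p <- default_params(gamma = g)
  net <- build_network(p, pool_totals(300, 390, c(100, 560)))
  base <- build_network(default_params(), pool_totals(300, 390, c(100, 560)))
  koff <- function(n, lab) {
    i <- which(vapply(n$reactions, function(r) r$label == lab, TRUE))
    n$reactions[[i]]$koff
  }
  # Cul1+SR and Cul1+Cand1 off-rates scale by gamma ...
  expect_equal(koff(net, "Cul1 + SR1 <-> Cul1.SR1"),
               g * koff(base, "Cul1 + SR1 <-> Cul1.SR1"))
  expect_equal(koff(net, "Cul1 + Cand1 <-> Cul1.Cand1"),
               g * koff(base, "Cul1 + Cand1 <-> Cul1.Cand1"))
  # ... ternary off-rates do not
  expect_equal(koff(net, "Cul1.Cand1 + SR1 <-> Cul1.Cand1.SR1"),
               koff(base, "Cul1.Cand1 + SR1 <-> Cul1.Cand1.SR1"))
  # eta and detailed balance are gamma-invariant
  expect_equal(p$eta, default_params()$eta)
  expect_equal(check_detailed_balance(p), 0)
  expect_error(default_params(gamma = 0.5), "gamma")
})

test_that("with_eta retargets the Cand1 preference consistently", {
  for (eta in c(0.01, 0.077, 1, 10)) {
    p <- with_eta(default_params(), eta)
    expect_equal(p$eta, eta, tolerance = 1e-12)
    expect_equal(p$Kca_prime / p$Ksr_prime, eta, tolerance = 1e-12)
    expect_equal(check_detailed_balance(p), 0, tolerance = 1e-14)
  }
})

test_that("constructors validate their inputs", {
  expect_error(pool_totals(300, -1, c(100, 560)), "non-negative")
  expect_error(pool_totals(300, 390, numeric(0)), "at least one")
  expect_error(substrate_params(-1, 1, 0.004), "positive")
  expect_error(substrate_params(1e8, 1, 0.004,
                                binding_mode = "random",
                                ternary_binding = FALSE),
               "random")
  expect_error(
    kinetic_params(Ksr = 0, ksr = 9e-7, Ksr_prime = 650, ksr_prime = 1.3,
                   Kca_prime = 50, kca_prime = 0.04, kca = 1e-5),
    "positive")
  # substrate kon is converted from 1/M/s to 1/nM/s
  s <- substrate_params(1e8, 1, 0.004)
  expect_equal(s$kon_nM, 0.1)
  expect_equal(s$KD, 10)
})
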