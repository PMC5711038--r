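test_that("rhs vanishes at the binding equilibrium and drives assembly from empty", {
  tot <- pool_totals(300, 390, c(100, 560))
  net <- build_network(tbl_params, tot)
  y_eq <- initial_state(net)
  expect_lt(max(abs(network_rhs(net, y_eq)[[1]])), 1e-9)
  # from the empty state only association terms survive:
  # d[Cul1.SR1]/dt = ksr * Cul1_T * SR1_T / Ksr
  y0 <- stats::setNames(numeric(5), state_names(net))
  d <- network_rhs(net, y0)[[1]]
  expect_equal(d[1], tbl_params$ksr * 300 * 100 / tbl_params$Ksr,
               tolerance = 1e-12)
  expect_equal(d[2], tbl_params$ksr * 300 * 560 / tbl_params$Ksr,
               tolerance = 1e-12)
  expect_equal(d[4], 0)                 # no ternary flux without complexes
})

test_that("conservation holds identically and along trajectories", {
  tot <- pool_totals(300, 390, c(100, 560), 300)
  sub <- substrate_params(1e8, 1, kdeg = 0)   # no degradation: S conserved
  net <- build_network(tbl_params, tot, sub)
  # algebraic identity: conserved-total derivatives are zero for any state
  set.seed(11)
  for (i in 1:10) {
    y <- stats::setNames(runif(length(state_names(net)), 0, 5),
                         state_names(net))
    dy <- network_rhs(net, y)[[1]]
    n_cplx <- length(net$complexes)
    # d(bound)/dt + d(free)/dt = 0 by construction; substrate total:
    dS <- dy[n_cplx + 1] +
      sum(dy[seq_len(n_cplx)] * net$comp[, net$n_cons + 1])
    expect_lt(abs(dS), 1e-10)
  }
  tc <- simulate_network(net, c(0, 10^seq(-2, 4, length.out = 60)))
  res <- conservation_residuals(tc)
  expect_lt(max(abs(res)), 1e-6)
})

test_that("relabelling SR1 and SR2 mirrors the trajectories exactly", {
  tot_a <- pool_totals(300, 390, c(100, 560))
  tot_b <- pool_totals(300, 390, c(560, 100))
  times <- c(0, 10^seq(-2, 3, length.out = 40))
  tc_a <- simulate_network(build_network(tbl_params, tot_a), times)
  tc_b <- simulate_network(build_network(tbl_params, tot_b), times)
  expect_equal(tc_a$Cul1.SR1, tc_b$Cul1.SR2, tolerance = 1e-10)
  expect_equal(tc_a$Cul1.Cand1.SR1, tc_b$Cul1.Cand1.SR2, tolerance = 1e-10)
  expect_equal(tc_a$Cul1.Cand1, tc_b$Cul1.Cand1, tolerance = 1e-10)
})

test_that("the five-complex rhs reproduces the explicit two-receptor equations", {
  # the generic network rhs must agree term-for-term with the hand-written
  # five-ODE system for the base cycle
  tot <- pool_totals(300, 390, c(100, 560))
  net <- build_network(tbl_params, tot)
  p <- tbl_params
  rhs5 <- function(y) {
    cul1 <- 300 - sum(y)
    sr1 <- 100 - (y[1] + y[4]); sr2 <- 560 - (y[2] + y[5])
    cand1 <- 390 - (y[3] + y[4] + y[5])
    c(p$ksr * (cul1 * sr1 / p$Ksr - y[1]) -
        p$kca_prime * (y[1] * cand1 / p$Kca_prime - y[4]),
      p$ksr * (cul1 * sr2 / p$Ksr - y[2]) -
        p$kca_prime * (y[2] * cand1 / p$Kca_prime - y[5]),
      p$kca * (cul1 * cand1 / p$Kca - y[3]) -
        p$ksr_prime * (y[3] * (sr1 + sr2) / p$Ksr_prime - (y[4] + y[5])),
      p$kca_prime * (y[1] * cand1 / p$Kca_prime - y[4]) +
        p$ksr_prime * (y[3] * sr1 / p$Ksr_prime - y[4]),
      p$kca_prime * (y[2] * cand1 / p$Kca_prime - y[5]) +
        p$ksr_prime * (y[3] * sr2 / p$Ksr_prime - y[5]))
  }
  set.seed(4)
  for (i in 1:5) {
    y <- runif(5, 0, 30)
    expect_equal(unname(network_rhs(net, y)[[1]]), rhs5(y),
                 tolerance = 1e-12)
  }
})

test_that("jacobian matches a hand-rolled finite difference", {
  tot <- pool_totals(300, 390, c(100, 560))
  net <- build_network(tbl_params, tot)
  y <- initial_state(net)
  J <- network_jacobian(net, y)
  expect_equal(dim(J), c(5, 5))
  f <- function(z) network_rhs(net, z)[[1]]
  h <- 1e-5
  yp <- y; yp[3] <- y[3] + h
  col3 <- (f(yp) - f(y)) / h
  expect_equal(unname(J[, 3]), unname(col3), tolerance = 1e-3)
})
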