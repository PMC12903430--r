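test_that("transmission is the filtrate-to-retentate ratio", {
  expect_equal(transmission(0, 5), 0)
  expect_equal(transmission(3.2, 3.2), 1)
  expect_equal(transmission(0.85, 5.0), 0.17)
  expect_error(transmission(1, 0), "c_r")
  expect_error(transmission(-1, 5), "c_f")
  expect_warning(transmission(6, 5), "suspect")
})

test_that("per-cycle retention f^r matches the integrated mass balance", {
  skip_if_not_installed("deSolve")
  # oracle: numerically integrate dm/dV = r m / V from V0 down to f V0
  oracle <- function(r, f, v0 = 10) {
    grid <- seq(v0, f * v0, length.out = 1e4 + 1)
    out <- deSolve::ode(c(m = 1), grid,
                        function(v, y, p) list(p$r * y[1] / v),
                        list(r = r), rtol = 1e-12, atol = 1e-14)
    unname(out[nrow(out), "m"])
  }
  for (r in c(0.05, 0.17, 0.5, 1)) {
    for (f in c(0.1, 0.5)) {
      expect_equal(batch_cycle_retention(r, f), oracle(r, f),
                   tolerance = 1e-6)
    }
  }
  expect_equal(batch_cycle_retention(0, 0.1), 1)
  expect_equal(batch_cycle_retention(1, 0.1), 0.1)
  expect_equal(batch_cycle_retention(0.17, 0.1), 0.1^0.17)
  expect_error(batch_cycle_retention(0.2, 1), "0, 1")
})

test_that("retention is monotone in r and f and bounded", {
  r <- seq(0, 1, by = 0.1)
  k <- batch_cycle_retention(r, 0.1)
  expect_true(all(diff(k) < 0))
  f <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(batch_cycle_retention(0.3, f)) > 0))
  expect_true(all(k[r > 0] < 1 & k[r > 0] >= 0.1))
})

test_that("batch simulation washes impurities while conserving mass", {
  st <- diafiltration_state(c("product", "impurity"), c(100, 25),
                            c(0, 0.17), volume = 10)
  traj <- simulate_batch(st, 12, f = 0.1)
  expect_equal(length(unique(traj$cycle)), 13)

  prod <- traj[traj$label == "product", ]
  imp <- traj[traj$label == "impurity", ]
  # rejected product never leaves
  expect_true(all(prod$mass == 100))
  # impurity follows the closed form; ~0.9% after 12 cycles
  expect_equal(imp$mass, 25 * (0.1^0.17)^(0:12))
  expect_equal(imp$retained_fraction[13], 0.00912, tolerance = 1e-3)
  # mass conservation per species to 1e-9 relative
  expect_lt(max(abs(imp$mass + imp$permeate_mass - 25) / 25), 1e-9)
  expect_lt(max(abs(prod$mass + prod$permeate_mass - 100) / 100), 1e-9)

  # species are independent: joint and separate runs agree exactly
  solo <- simulate_batch(diafiltration_state("impurity", 25, 0.17, 10),
                         12, f = 0.1)
  expect_equal(imp$mass, solo$mass)
})

test_that("cycle planning inverts the closed form", {
  expect_equal(cycles_to_purity(0.17, 0.1, 0.01), 12L)
  expect_equal(cycles_to_purity(1, 0.1, 0.001), 3L)
  expect_equal(cycles_to_purity(0.5, 0.1, 1 - 1e-12), 1L)
  # planned cycle count actually reaches the target, one less does not
  for (r in c(0.08, 0.17, 0.4)) {
    n <- cycles_to_purity(r, 0.1, 0.01)
    expect_lte(batch_cycle_retention(r, 0.1)^n, 0.01 * (1 + 1e-9))
    expect_gt(batch_cycle_retention(r, 0.1)^(n - 1), 0.01)
  }
  expect_error(cycles_to_purity(0, 0.1, 0.01), "cannot be washed out")
})

test_that("continuous diafiltration follows the exponential decay", {
  expect_equal(simulate_continuous(5, 0.17, 2, 0), 5)
  vf <- 2 * log(100) / 0.17
  expect_equal(simulate_continuous(1, 0.17, 2, vf), 0.01)
  # continuous mode is run at the minimal retentate volume (the cell
  # concentrated once to f V0), which is what makes it cheaper in
  # solvent than batch cycling from the full volume for equal purity
  n <- cycles_to_purity(0.17, 0.1, 0.01)
  batch_solvent <- n * (1 - 0.1) * 10
  cont_solvent <- (0.1 * 10) * log(1 / 0.01) / 0.17
  expect_lt(cont_solvent, batch_solvent)
})

test_that("batch and continuous models agree in the fine-cycle limit", {
  r <- 0.17
  f <- 0.99
  n <- 200
  st <- diafiltration_state("imp", 1, r, volume = 10)
  traj <- simulate_batch(st, n, f = f)
  batch_final <- traj$mass[traj$cycle == n]
  vf <- n * (1 - f) * 10
  cont_final <- simulate_continuous(1, r, 10, vf)
  expect_lt(abs(batch_final - cont_final) / cont_final, 0.01)
})

test_that("transmission estimation inverts the batch model", {
  m <- gen_filtration_series(0.17, f = 0.1, cycles = 8, sigma = 0)
  est <- estimate_transmission(m, f = 0.1)
  expect_equal(est$per_cycle, rep(0.17, 8))
  expect_equal(est$mean, 0.17)
  expect_equal(est$mass_weighted_mean, 0.17)

  # constant series: nothing leaves, r = 0
  expect_equal(estimate_transmission(rep(2, 5), f = 0.1)$mean, 0)

  # seeded 5% multiplicative noise, 10 cycles: recovery within 0.02
  m_noisy <- gen_filtration_series(0.12, f = 0.1, cycles = 10,
                                   sigma = 0.05, seed = 42)
  expect_lt(abs(estimate_transmission(m_noisy, f = 0.1)$mean - 0.12), 0.02)

  expect_error(estimate_transmission(c(1, 0), 0.1), "> 0")
  expect_error(estimate_transmission(1, 0.1), "at least two")
})

test_that("the stirred-cell transmission test is self-consistent", {
  # rejected solute: empty filtrate, retentate concentrated by the
  # volume ratio
  t0 <- simulate_transmission_test(0)
  expect_equal(t0$c_f, 0)
  expect_equal(t0$c_r, 5 * 9 / 6.3)
  # freely passing solute: filtrate equals retentate
  t1 <- simulate_transmission_test(1)
  expect_equal(t1$c_f, t1$c_r)
  # the sampled ratio returns the stage transmission
  t01 <- simulate_transmission_test(0.10)
  expect_equal(t01$r_hat, 0.10, tolerance = 1e-12)
  # multi-stage protocol with per-stage transmissions
  ts <- simulate_transmission_test(c(0.07, 0.17, 0.30))
  expect_equal(ts$r_hat, c(0.07, 0.17, 0.30), tolerance = 1e-12)
  expect_true(all(diff(ts$mass_start) < 0))  # mass leaves at every stage

  expect_error(simulate_transmission_test(0.1, collected = 9), "smaller")
})
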