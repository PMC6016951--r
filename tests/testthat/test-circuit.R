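test_that("steady-state voltage solves the equivalent circuit", {
  p <- circuit_params(E_exc = 50, E_inh = -20)
  expect_equal(steady_state_voltage(0, 0, p), 0)
  expect_equal(steady_state_voltage(1, 1, p), 10)
  # one dominant battery pulls the membrane to its reversal
  expect_equal(steady_state_voltage(1e9, 0, p), 50, tolerance = 1e-6)
  expect_equal(steady_state_voltage(0, 1e9, p), -20, tolerance = 1e-6)
  expect_error(steady_state_voltage(-0.1, 0, p), "non-negative")
  expect_error(circuit_params(g_leak = 0), "g_leak")

  # bounds and monotonicity over random draws
  set.seed(42)
  for (i in 1:200) {
    pp <- random_circuit_params()
    ge <- stats::runif(1, 0, 5); gi <- stats::runif(1, 0, 5)
    v <- steady_state_voltage(ge, gi, pp)
    expect_gte(v, min(pp$E_inh, 0))
    expect_lte(v, max(pp$E_exc, 0))
    expect_gte(steady_state_voltage(ge + 0.1, gi, pp), v)
    expect_lte(steady_state_voltage(ge, gi + 0.1, pp), v)
  }
})

test_that("closed-form nonlinear responses match brute-force composition", {
  # oracle: compose the responses directly from the membrane equation
  oracle_exc_exc <- function(x, p) {
    R1 <- steady_state_voltage(x, 0, p)
    R12 <- steady_state_voltage(2 * x, 0, p)
    list(R1 = R1, R12 = R12, R_nonlin = R12 - 2 * R1)
  }
  oracle_exc_inh <- function(x, p) {
    rest <- steady_state_voltage(0, 1, p)   # tonic inhibition = leak
    R1 <- steady_state_voltage(x, 1, p) - rest
    R2 <- steady_state_voltage(0, 1 - x, p) - rest
    R12 <- steady_state_voltage(x, 1 - x, p) - rest
    list(R1 = R1, R2 = R2, R12 = R12, rest = rest,
         R_nonlin = R12 - (R1 + R2))
  }

  # frozen spot checks (exact rational values)
  p50 <- circuit_params(E_exc = 50, E_inh = -10)
  ee <- response_exc_exc(1, p50)
  expect_equal(ee$R_nonlin, -50 / 3)
  expect_equal(ee$R12, 100 / 3)
  ei <- response_exc_inh(1, p50)
  expect_equal(ei$V_rest, -5)
  expect_equal(ei$R12, 30)
  expect_equal(ei$R_nonlin, 20 / 3)

  set.seed(7)
  for (i in 1:1000) {
    p <- random_circuit_params()
    x <- stats::runif(1, 0, 1)
    ee <- response_exc_exc(x, p)
    oe <- oracle_exc_exc(x, p)
    expect_equal(ee$R1, oe$R1, tolerance = 1e-12)
    expect_equal(ee$R12, oe$R12, tolerance = 1e-12)
    expect_equal(ee$R_nonlin, oe$R_nonlin, tolerance = 1e-12)
    ei <- response_exc_inh(x, p)
    oi <- oracle_exc_inh(x, p)
    expect_equal(ei$V_rest, oi$rest, tolerance = 1e-12)
    expect_equal(ei$R1, oi$R1, tolerance = 1e-12)
    expect_equal(ei$R2, oi$R2, tolerance = 1e-12)
    expect_equal(ei$R12, oi$R12, tolerance = 1e-12)
    # R_nonlin is a difference of near-equal responses, so the oracle's
    # own round-off is amplified at small x; compare on the response
    # scale rather than relative to the (possibly tiny) difference
    expect_lt(abs(ei$R_nonlin - oi$R_nonlin),
              1e-12 * max(1, abs(oi$R12), abs(oi$R1 + oi$R2)))
  }
  # the exc-exc drive is not limited to the unit interval
  x <- 3.7; p <- circuit_params(E_exc = 65, E_inh = -15)
  expect_equal(response_exc_exc(x, p)$R_nonlin,
               oracle_exc_exc(x, p)$R_nonlin, tolerance = 1e-12)
})

test_that("two excitatory inputs sum sublinearly, exc + disinhibition supralinearly", {
  x <- seq(0, 1, by = 0.001)
  p <- circuit_params(E_exc = 50, E_inh = -10)
  ee <- nonlinearity_sweep(x, p, "exc_exc")
  expect_true(all(ee$R_nonlin <= 0))
  expect_true(all(diff(ee$R_nonlin) < 0))          # strictly decreasing
  expect_identical(ee$R_nonlin[1], 0)
  ei <- nonlinearity_sweep(x, p, "exc_inh")
  expect_true(all(ei$R_nonlin >= 0))
  expect_true(all(ei$R_nonlin[-1] > 0))            # zero only at x = 0
  # supralinearity holds for any |E_exc| > |E_inh|
  set.seed(11)
  for (i in 1:50) {
    E <- stats::runif(1, 10, 100)
    p2 <- circuit_params(E_exc = E, E_inh = -stats::runif(1, 0.1, E * 0.99))
    expect_true(all(response_exc_inh(x[-1], p2)$R_nonlin > 0))
  }
})

test_that("sweep tables validate their domain", {
  expect_error(response_exc_exc(-0.5), "non-negative")
  expect_error(response_exc_inh(1.2), "\\[0, 1\\]")
  tab <- nonlinearity_sweep(c(0, 0.5, 1), mode = "exc_inh")
  expect_named(tab, c("x", "R1", "R2", "R12", "linear_expectation",
                      "R_nonlin", "V_rest"))
  expect_equal(unlist(tab[1, 2:6]), c(R1 = 0, R2 = 0, R12 = 0,
                                      linear_expectation = 0, R_nonlin = 0))
  expect_equal(tab$R_nonlin, tab$R12 - tab$linear_expectation,
               tolerance = 1e-12)
})
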