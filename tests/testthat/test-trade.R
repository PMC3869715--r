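test_that("owner utility is the discounted value of holdings", {
  ls0 <- tibble::tibble(x = 1, y = 1, z = 1)
  p <- land_params(a = 1, b = 2, c = 3)
  expect_equal(owner_utility(ls0, p), 6)
  expect_equal(owner_utility(ls0, p, infected = TRUE, h = 0), 0)
  expect_equal(owner_utility(ls0, p, infected = TRUE, h = 0.01), 0.06)
  expect_equal(owner_utility(ls0, p, infected = FALSE, h = 0.01), 6)
})

test_that("purchasing power normalises, is scale-free and handles zero wealth", {
  expect_equal(purchasing_power(c(3, 1)), c(0.75, 0.25))
  expect_equal(purchasing_power(rep(7, 5)), rep(0.2, 5))
  set.seed(3)
  for (i in 1:25) {
    U <- runif(sample(2:50, 1), 0, 100)
    P <- purchasing_power(U)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_true(all(P >= 0))
    expect_equal(purchasing_power(13.7 * U), P, tolerance = 1e-12)
  }
  # two owners: complementary powers
  P2 <- purchasing_power(c(5.3, 2.2))
  expect_equal(P2[1] + P2[2], 1)
  # all land worthless: uniform fallback
  expect_equal(purchasing_power(c(0, 0, 0, 0)), rep(0.25, 4))
})

test_that("sale pressure follows the configured rule", {
  expect_equal(sale_pressure(c(3, 1)), c(0.25, 0.75))
  expect_equal(sale_pressure(c(1, 1, 1, 1), rule = "mean"), rep(0, 4))
  expect_equal(sale_pressure(c(1, 2, 3, 4), rule = "median"), c(1, 1, 0, 0))
  expect_equal(sale_pressure(c(1, 2, 6), rule = "mean"), c(1, 1, 0))
  expect_error(land_params(sale_rule = "barter"))
})

test_that("pooled trade redistributes empty land and conserves it", {
  ls0 <- tibble::tibble(x = c(0, 0), y = c(0, 0), z = c(10, 10))
  ts <- tibble::tibble(power = c(0.75, 0.25), pressure = c(0.25, 0.75))
  out <- trade_step(ls0, ts)
  expect_equal(out$z, c(15, 5))

  # no sale pressure, no movement
  ts0 <- tibble::tibble(power = c(0.5, 0.5), pressure = c(0, 0))
  expect_equal(trade_step(ls0, ts0)$z, ls0$z)

  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:30, 1)
    ls <- init_landscape(n, 17)
    ts <- trade_state(ls, land_params())
    out <- trade_step(ls, ts)
    expect_equal(sum(out$z), sum(ls$z), tolerance = 1e-9)
    expect_equal(out$x, ls$x)
    expect_equal(out$y, ls$y)
    expect_true(all(out$z >= 0))
  }
})

test_that("under the complement rule wealthier owners gain more of the pool", {
  # among owners holding equal empty land, expected net gain of E land
  # is strictly increasing in utility
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:20, 1)
    U <- runif(n, 0.1, 10)
    P <- purchasing_power(U)
    V <- sale_pressure(U, P, "complement")
    z <- rep(5, n)
    gain <- P * sum(V * z) - V * z
    expect_true(all(diff(gain[order(U)]) > 0))
  }
})

test_that("trade state ties utilities, power and pressure together", {
  set.seed(5)
  ls <- init_landscape(6, 12)
  ts <- trade_state(ls, land_params())
  expect_equal(ts$power, purchasing_power(ts$utility))
  expect_equal(ts$pressure, 1 - ts$power)
  expect_equal(attr(ts, "pool"), sum(ts$pressure * ls$z))
})
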