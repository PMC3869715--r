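test_that("force of infection is frequency dependent and capped", {
  expect_equal(force_of_infection(0, 64, 2), 0)
  expect_equal(force_of_infection(32, 64, 2), 1)
  expect_equal(force_of_infection(64, 64, 2), 1)
  expect_equal(force_of_infection(8, 64, 2), 0.25)
  expect_equal(force_of_infection(8, 64, 1), 0.125)
})

test_that("infection draws respect protection, recovery and the rate", {
  set.seed(1)
  expect_false(any(sample_infections(0, 50)))
  all_in <- sample_infections(1, 50, protected = c(3, 7))
  expect_false(any(all_in[c(3, 7)]))
  expect_true(all(all_in[-c(3, 7)]))

  # owners infected last year recover this year even at full force
  prev <- rep(c(TRUE, FALSE), 25)
  nxt <- sample_infections(1, 50, recovering = prev)
  expect_false(any(nxt[prev]))
  expect_true(all(nxt[!prev]))

  # binomial sampling at lambda = 0.5
  set.seed(99)
  draws <- sample_infections(0.5, 1e4)
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
})

test_that("SIS prevalence settles at the deterministic fixed point", {
  # kappa' ~ Binomial(n - kappa, min(1, R0 kappa / n)); for R0 = 1.5 the
  # fixed point solves kappa = (n - kappa) 1.5 kappa / n, i.e. kappa = n/3
  set.seed(7)
  n <- 600
  r0 <- 1.5
  inf <- rep(FALSE, n)
  inf[1:200] <- TRUE
  kap <- numeric(400)
  for (t in seq_along(kap)) {
    lam <- force_of_infection(sum(inf), n, r0)
    inf <- sample_infections(lam, n, recovering = inf)
    kap[t] <- sum(inf)
  }
  prev <- mean(kap[101:400]) / n
  expect_lt(abs(prev - 1 / 3), 0.02)
})

test_that("protected owners are never infected over a whole run", {
  cfg <- sim_config(
    n = 24, m = 16, seed = 5, record_every = 1, max_steps = 400,
    disease = disease_params(r0 = 2, h = 0.5, protected_frac = 0.25)
  )
  res <- run_simulation(cfg)
  traj <- tidy(res)
  hit <- dplyr::filter(traj, .data$owner %in% res$protected, .data$infected)
  expect_identical(nrow(hit), 0L)
  expect_gt(sum(traj$infected), 0) # the epidemic did happen
})

test_that("an economically neutral disease (h = 1) leaves trajectories unchanged", {
  base <- sim_config(n = 16, m = 16, seed = 11, record_every = 5,
                     max_steps = 600)
  with_dis <- sim_config(n = 16, m = 16, seed = 11, record_every = 5,
                         max_steps = 600,
                         disease = disease_params(r0 = 2, h = 1))
  a <- run_simulation(base)
  b <- run_simulation(with_dis)
  expect_equal(b$final[, c("x", "y", "z")], a$final[, c("x", "y", "z")])
  expect_identical(b$steps, a$steps)
  expect_identical(b$outcome, a$outcome)
})

test_that("disease seeding defaults to the endemic level", {
  set.seed(1)
  inf <- replicate(20, sum(latifundia:::seed_infections(64, disease_params(r0 = 2))))
  expect_true(all(inf == 32))
  inf1 <- sum(latifundia:::seed_infections(64, disease_params(r0 = 1)))
  expect_identical(inf1, 1L)
  inf0 <- sum(latifundia:::seed_infections(64, disease_params(r0 = 2, kappa0 = 5)))
  expect_identical(inf0, 5L)
})
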