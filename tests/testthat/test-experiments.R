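test_that("sweeps are row-complete with probabilities in range", {
  sw <- sweep_size_utilities(k_n = 2, k_m = 2:3, reps = 3, seed = 1,
                             max_steps = 1500)
  expect_identical(nrow(sw), 6L * 2L)            # 6 orderings x 2 sizes
  expect_identical(anyDuplicated(sw[, c("ordering", "k_n", "k_m")]), 0L)
  expect_true(all(sw$p_equity >= 0 & sw$p_equity <= 1))
  expect_true(all(sw$reps == 3))
  reps <- tidy(sw)
  expect_identical(nrow(reps), nrow(sw) * 3L)

  rt <- sweep_transition_rates(rates = c(0.3, 0.7), n = 4, m = 4, reps = 2,
                               seed = 1, max_steps = 1500)
  expect_identical(nrow(rt), 8L)
  expect_true(all(rt$p_equity >= 0 & rt$p_equity <= 1))
})

test_that("replicates are seed-paired: extending reps keeps earlier runs", {
  short <- run_replicates(sim_config(n = 6, m = 6, seed = 4, reps = 5))
  long <- run_replicates(sim_config(n = 6, m = 6, seed = 4, reps = 10))
  expect_equal(long[1:5, ], short)
})

test_that("the empty-land-first utility ordering is the most equitable", {
  sw <- sweep_size_utilities(k_n = 2:3, k_m = 2:3, reps = 10, seed = 2,
                             max_steps = 2000)
  by_ord <- dplyr::summarise(dplyr::group_by(sw, .data$ordering),
                             p = mean(.data$p_equity))
  best <- by_ord$p[by_ord$ordering == "c>b>a"]
  expect_true(all(best >= by_ord$p))
})

test_that("fast uniform land turnover is at least as equitable as slow", {
  fast <- run_replicates(sim_config(
    n = 64, m = 64, seed = 6, reps = 20,
    params = land_params(r = 0.9, eta = 0.9, mu = 0.9), max_steps = 4000))
  slow <- run_replicates(sim_config(
    n = 64, m = 64, seed = 6, reps = 20,
    params = land_params(r = 0.1, eta = 0.1, mu = 0.1), max_steps = 4000))
  expect_gte(mean(fast$outcome == "equity"), mean(slow$outcome == "equity"))
})

test_that("the disease experiment reproduces its controls", {
  de <- disease_experiment(r0_values = 2, h_values = c(1, 0),
                           protected_fractions = 0,
                           n = 16, m = 16, reps = 3, seed = 3,
                           max_steps = 3000)
  nd <- dplyr::filter(de, .data$scenario == "ND")
  expect_equal(nd$owner_ratio, 1)
  expect_equal(nd$p_equity, 1)
  # no discount: disease is economically invisible, equity persists
  h1 <- dplyr::filter(de, .data$h == 1)
  expect_equal(h1$owner_ratio, 1)
  # every requested cell is present exactly once
  expect_identical(nrow(de), 3L)
})
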