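test_that("eclosion generator is seeded, truncated and recovers its moments", {
  m <- eclosion_model("PNW", mean_days = 30.68, n_flies = 289, se_days = 0.41)
  expect_equal(m$sd_days, 0.41 * sqrt(289))

  tab1 <- gen_eclosion(m, seed = 1)
  tab2 <- gen_eclosion(m, seed = 1)
  expect_identical(tab1, tab2)
  expect_equal(nrow(tab1), 289L)
  expect_true(all(tab1$days_to_eclosion >= 0))
  # sample mean within 3 SE of the model mean
  expect_lt(abs(mean(tab1$days_to_eclosion) - 30.68), 3 * 0.41)

  # moment recovery at large n: mean and SD within 1% of the model
  big <- eclosion_model("X", mean_days = 50, n_flies = 1e5, sd_days = 6)
  days <- gen_eclosion(big, seed = 2)$days_to_eclosion
  expect_lt(abs(mean(days) - 50) / 50, 0.01)
  expect_lt(abs(sd(days) - 6) / 6, 0.01)

  # degenerate spread collapses onto the rounded mean
  tiny <- eclosion_model("X", mean_days = 30.68, n_flies = 5, sd_days = 1e-6)
  expect_true(all(gen_eclosion(tiny, seed = 3)$days_to_eclosion == 31L))

  expect_error(eclosion_model("X", 30, 10, sd_days = 0), class = "ciflow_invalid_parameter")
  expect_error(eclosion_model("X", 30, 0, sd_days = 1), class = "ciflow_invalid_parameter")
})

test_that("mating-trial generator allocates matings binomially and is invertible", {
  # no hybrid matings possible
  tal0 <- gen_mating_trials(c("A", "B"), p_hybrid = 0, total_matings = 50,
                            hours_observed = 10, seed = 1)
  expect_equal(tal0$H, 0)
  expect_equal(tal0$C, 50)

  # published inversion: p_hybrid 0.295 corresponds to SI 0.41, recovered to
  # within the 3-sigma binomial error bound 3 * 2 * sqrt(p(1-p)/n)
  tal <- gen_mating_trials(c("SW", "PNW"), p_hybrid = 0.295,
                           total_matings = 2000, hours_observed = 100, seed = 7)
  expect_equal(tal$H + tal$C, 2000)
  expect_lt(abs(sexual_isolation(tal) - 0.41),
            3 * 2 * sqrt(0.295 * 0.705 / 2000))

  # random mating recovers SI near 0 (same bound: 0.03 at n = 10000)
  rnd <- gen_mating_trials(c("A", "B"), p_hybrid = 0.5, total_matings = 10000,
                           hours_observed = 10, seed = 7)
  expect_lt(abs(sexual_isolation(rnd)), 0.03)

  # the per-direction table pools back to the tally
  expect_equal(sum(tal$table$n_matings[tal$table$cross_class == "hybrid"]), tal$H)
  expect_equal(sum(tal$table$n_matings), 2000)

  expect_identical(gen_mating_trials(c("A", "B"), 0.3, 100, 10, seed = 5),
                   gen_mating_trials(c("A", "B"), 0.3, 100, 10, seed = 5))
  expect_error(gen_mating_trials(c("A", "B"), 0.3, 100, 0, seed = 5),
               class = "ciflow_invalid_parameter")
})

test_that("cross generator obeys the egg-target stopping rule", {
  # high laying rate: cages stop as soon as they pass 100 eggs
  fast <- cross_design("A", "A", n_cages = 25, eggs_per_female_day = 60)
  tab <- gen_crosses(fast, seed = 4)
  expect_true(all(tab$days_observed <= 28))
  expect_true(all(tab$eggs_laid[tab$days_observed < 28] > 100))
  # a cage over target stopped laying the same day it crossed it, so it can
  # exceed 100 by at most one day's output
  expect_true(all(tab$eggs_laid <= 100 + max(tab$eggs_laid / tab$days_observed) * 3))

  # laying too slow to reach the target: every cage runs the full period
  slow <- cross_design("A", "A", n_cages = 20, eggs_per_female_day = 1, max_days = 5)
  expect_true(all(gen_crosses(slow, seed = 4)$days_observed == 5))

  expect_identical(gen_crosses(fast, seed = 9), gen_crosses(fast, seed = 9))
})

test_that("cross generator reproduces hatch structure and rejects impossible designs", {
  # without CI, hybrid and parental arms hatch alike
  arms <- paired_cross_arms(ci_true = 0, seed = 21)
  hp <- hatch_proportions(arms)
  expect_lt(abs(diff(hp$mean_hatch)), 0.05)
  expect_true(all(arms$eggs_hatched <= arms$eggs_laid))

  # an unfertilized-egg background depresses both arms equally
  d <- cross_design("A", "A", n_cages = 30, parental_hatch = 0.8,
                    unfertilized_rate = 0.5)
  tab <- gen_crosses(d, seed = 6)
  expect_lt(abs(mean(tab$eggs_hatched / tab$eggs_laid) - 0.4), 0.05)

  # implied hybrid hatch above 1 is rejected
  expect_error(cross_design("A", "B", n_cages = 5, parental_hatch = 0.6,
                            ci_strength_true = -0.8),
               class = "ciflow_invalid_parameter")
  expect_error(cross_design("A", "B", n_cages = 5, cage_females = 4),
               class = "ciflow_invalid_parameter")
})

test_that("infection survey draws match the requested strain frequencies", {
  all_double <- list(P1 = c(wCin2 = 0, wCin3 = 0, double = 1),
                     P2 = c(wCin2 = 0, wCin3 = 0, double = 1))
  sv <- gen_infection_survey(all_double, n_per_pop = 10, seed = 2)
  expect_true(all(sv$wCin2 == 1) && all(sv$wCin3 == 1))

  # a fully wCin3-only site has no wCin2 carriers
  only3 <- list(site17 = c(wCin2 = 0, wCin3 = 1, double = 0))
  sv3 <- gen_infection_survey(only3, n_per_pop = 6, seed = 2)
  expect_true(all(sv3$wCin2 == 0) && all(sv3$wCin3 == 1))

  expect_identical(gen_infection_survey(all_double, 10, seed = 5),
                   gen_infection_survey(all_double, 10, seed = 5))
  expect_error(
    gen_infection_survey(list(P = c(wCin2 = 0.5, wCin3 = 0.4, double = 0.2)),
                         n_per_pop = 5, seed = 1),
    class = "ciflow_invalid_parameter")
})
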