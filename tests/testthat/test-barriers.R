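test_that("activity profiles enumerate active days correctly", {
  # one fly: active on all nine days of the 7-15 window
  p1 <- activity_profile(ecl_table(0), window = c(7, 15))
  expect_equal(p1$day_index, 7:15)
  expect_equal(p1$active_proportion, rep(1, 9))

  # two staggered flies: disjoint windows, each day carried by one fly
  p2 <- activity_profile(ecl_table(c(0, 10)), window = c(7, 15))
  expect_equal(range(p2$day_index), c(7, 25))
  active <- p2$active_proportion[p2$active_proportion > 0]
  expect_true(all(active == 0.5))
  expect_equal(p2$active_proportion[p2$day_index == 16], 0) # the gap day

  # the profile mass of a large sample centers near mean + window midpoint
  pnw <- gen_eclosion(published_models()$PNW, seed = 1)
  pr <- activity_profile(pnw, window = c(7, 30))
  centroid <- sum(pr$day_index * pr$active_proportion) / sum(pr$active_proportion)
  expect_lt(abs(centroid - (30.68 + 18.5)), 1)

  expect_error(activity_profile(ecl_table(numeric(0))), class = "ciflow_empty_input")
  expect_error(activity_profile(ecl_table(1), window = c(15, 7)),
               class = "ciflow_invalid_parameter")
})

test_that("allochronic isolation matches hand-computed cosine values", {
  # identical profiles are fully overlapping
  p <- activity_profile(ecl_table(c(0, 3, 5)), window = c(7, 15))
  expect_equal(allochronic_isolation(p, p), 0)

  # disjoint supports are complete isolation
  a <- activity_profile(ecl_table(0), window = c(7, 15))
  b <- activity_profile(ecl_table(40), window = c(7, 15))
  expect_equal(allochronic_isolation(a, b), 100)

  # x = (0.5, 0.5), y = (0, 1): AI = 100 (1 - 0.5 / sqrt(0.5)) = 29.2893
  x <- activity_profile(ecl_table(c(1, 2)), window = c(0, 0))
  y <- activity_profile(ecl_table(2), window = c(0, 0))
  expect_equal(allochronic_isolation(x, y), 100 * (1 - 0.5 / sqrt(0.5)),
               tolerance = 1e-12)
})

test_that("allochronic isolation is symmetric and scale invariant", {
  for (seed in 1:5) {
    ta <- withr::with_seed(seed, ecl_table(sample(0:40, 30, replace = TRUE)))
    tb <- withr::with_seed(seed + 50, ecl_table(sample(10:60, 25, replace = TRUE)))
    pa <- activity_profile(ta, c(7, 30))
    pb <- activity_profile(tb, c(7, 30))
    ai <- allochronic_isolation(pa, pb)
    expect_equal(allochronic_isolation(pb, pa), ai)
    pa_scaled <- pa
    pa_scaled$active_proportion <- pa$active_proportion * 7.3
    expect_equal(allochronic_isolation(pa_scaled, pb), ai, tolerance = 1e-12)
    expect_true(ai >= 0 && ai <= 100)
  }
})

test_that("a shorter adult lifespan never weakens reconstructed allochrony", {
  mods <- published_models()
  ecl <- lapply(seq_along(mods), function(i) gen_eclosion(mods[[i]], seed = i))
  names(ecl) <- names(mods)
  p30 <- lapply(ecl, activity_profile, window = c(7, 30))
  p15 <- lapply(ecl, activity_profile, window = c(7, 15))
  for (pair in list(c("PNW", "SW"), c("ENA", "SW"), c("ENA", "PNW"))) {
    ai30 <- allochronic_isolation(p30[[pair[1]]], p30[[pair[2]]])
    ai15 <- allochronic_isolation(p15[[pair[1]]], p15[[pair[2]]])
    expect_gte(ai15, ai30)
  }
})

test_that("sexual isolation and the hybrid mating probability invert each other", {
  expect_equal(sexual_isolation(mating_tally(c("A", "B"), H = 0, C = 10)), 1)
  expect_equal(sexual_isolation(mating_tally(c("A", "B"), H = 5, C = 5)), 0)
  expect_equal(sexual_isolation(mating_tally(c("A", "B"), H = 2, C = 8)), 0.6)
  expect_error(mating_tally(c("A", "B"), H = 0, C = 0),
               class = "ciflow_invalid_parameter")

  expect_equal(hybrid_mating_probability(1), 0)
  expect_equal(hybrid_mating_probability(-1), 1)
  expect_equal(hybrid_mating_probability(0.41), 0.295)
  expect_error(hybrid_mating_probability(1.2), class = "ciflow_invalid_parameter")

  si <- seq(-1, 1, by = 0.125)
  expect_equal(1 - 2 * hybrid_mating_probability(si), si, tolerance = 1e-12)

  # per-hour rates agree with counts for a single pooled tally
  tal <- mating_tally(c("A", "B"), H = 3, C = 7, hours_observed = 20)
  expect_equal(sexual_isolation(tal, use_rates = TRUE), sexual_isolation(tal))
})

test_that("hatch proportions apply the minimum-egg filter per direction", {
  hp <- hatch_proportions(hand_crosses())
  aa <- hp[hp$maternal_pop == "A" & hp$paternal_pop == "A", ]
  ab <- hp[hp$maternal_pop == "A" & hp$paternal_pop == "B", ]
  bb <- hp[hp$maternal_pop == "B" & hp$paternal_pop == "B", ]
  # the 9-egg cage is excluded; the 30/30 cage carries the A x A mean
  expect_equal(aa$mean_hatch, 1)
  expect_equal(aa$n_cages, 1L)
  expect_equal(aa$n_excluded, 1L)
  # A x B: cages 10/5 and 50/25, unweighted mean of 0.5 and 0.5
  expect_equal(ab$mean_hatch, 0.5)
  expect_equal(ab$n_cages, 2L)
  # the zero-egg B x B cage is excluded from hatch (but not from fecundity)
  expect_equal(bb$n_cages, 1L)
  expect_equal(bb$mean_hatch, 0.9)

  # raising the filter empties a direction, which must be reported by name
  expect_error(hatch_proportions(hand_crosses(), min_eggs = 35),
               "A female x A male", class = "ciflow_undefined_statistic")
})

test_that("CI strength is the relative hatch reduction, unclamped", {
  expect_equal(ci_strength(0.5, 0.5), 0)
  expect_equal(ci_strength(0, 0.4), 1)
  expect_equal(ci_strength(0.15, 0.75), 0.8)
  expect_warning(cc <- ci_strength(0.8, 0.5), "negative")
  expect_equal(cc, -0.6)
  expect_error(ci_strength(0.1, 0), class = "ciflow_undefined_statistic")
})

test_that("synthetic crosses recover their design CI strength within 0.05", {
  for (spec in list(list(c = 0.2, seed = 101), list(c = 0.5, seed = 202),
                    list(c = 0.8, seed = 11))) {
    chat <- estimate_ci(paired_cross_arms(spec$c, n_cages = 40, seed = spec$seed))
    expect_lt(abs(chat - spec$c), 0.05)
  }
  # the designed hybrid hatch is about (1 - c) of the parental hatch
  arms <- paired_cross_arms(0.8, seed = 11)
  hp <- hatch_proportions(arms)
  hyb <- hp$mean_hatch[hp$paternal_pop == "SW"]
  par <- hp$mean_hatch[hp$paternal_pop == "PNW"]
  expect_lt(abs(hyb / par - 0.2), 0.05)
})

test_that("fecundity summaries use only single-pair cages", {
  fec <- fecundity_summary(hand_crosses())
  aa <- fec[fec$maternal_pop == "A" & fec$paternal_pop == "A", ]
  # cages: 30 eggs / 10 days and 9 eggs / 5 days -> mean of 3.0 and 1.8
  expect_equal(aa$mean_eggs_female_day, mean(c(3, 1.8)))
  expect_equal(aa$n_cages, 2L)
  # the 2x2 cage is dropped, leaving one A x B cage
  ab <- fec[fec$maternal_pop == "A" & fec$paternal_pop == "B", ]
  expect_equal(ab$n_cages, 1L)
  expect_equal(ab$mean_eggs_female_day, 10 / 8)
  # zero-egg cages count as zeros
  bb <- fec[fec$maternal_pop == "B" & fec$paternal_pop == "B", ]
  expect_equal(bb$mean_eggs_female_day, mean(c(4, 0)))

  only_big <- hand_crosses()[4, ]
  expect_error(fecundity_summary(only_big), class = "ciflow_undefined_statistic")
})
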