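#' Eclosion model for one population
#'
#' Describes the adult-eclosion phenology of one population as a normal
#' distribution truncated at zero, parameterized from a published summary
#' (mean, standard error, sample size). The generator rounds draws to whole
#' days, matching a daily eclosion census.
#'
#' @param population Population label, e.g. `"PNW"`.
#' @param mean_days Mean days to eclosion.
#' @param n_flies Number of flies to emulate (positive integer).
#' @param se_days Standard error of the mean, in days. Converted once to a
#'   standard deviation as `sd = se * sqrt(n)`. Supply either `se_days` or
#'   `sd_days`.
#' @param sd_days Standard deviation in days (alternative to `se_days`).
#'
#' @return An object of class `eclosion_model`.
#' @seealso [gen_eclosion()], [cherry_fly_eclosion_models()]
#' @export
#' @examples
#' m <- eclosion_model("PNW", mean_days = 30.68, n_flies = 289, se_days = 0.41)
#' m$sd_days # 0.41 * sqrt(289) = 6.97
eclosion_model <- function(population, mean_days, n_flies,
                           se_days = NULL, sd_days = NULL) {
  if (!is.character(population) || length(population) != 1L) {
    stop_invalid_parameter("`population` must be a single label")
  }
  if (!is.numeric(mean_days) || length(mean_days) != 1L || !is.finite(mean_days)) {
    stop_invalid_parameter("`mean_days` must be a finite number")
  }
  if (!is_count(n_flies)) {
    stop_invalid_parameter("`n_flies` must be a positive integer")
  }
  if (is.null(sd_days)) {
    if (is.null(se_days)) {
      stop_invalid_parameter("supply one of `se_days` or `sd_days`")
    }
    sd_days <- se_days * sqrt(n_flies)
  }
  if (!is.numeric(sd_days) || length(sd_days) != 1L || !is.finite(sd_days) ||
      sd_days <= 0) {
    stop_invalid_parameter("`sd_days` must be a positive number")
  }
  structure(
    list(population = population, mean_days = mean_days,
         sd_days = sd_days, n_flies = as.integer(n_flies)),
    class = "eclosion_model"
  )
}

#' @export
print.eclosion_model <- function(x, ...) {
  cat(sprintf("<eclosion_model> %s: mean %.2f d, sd %.2f d, n = %d\n",
              x$population, x$mean_days, x$sd_days, x$n_flies))
  invisible(x)
}

#' Published eclosion summaries for the three cherry fly study populations
#'
#' Eclosion models built from the published 2017 rearing summaries for
#' *Rhagoletis indifferens* in the Pacific Northwest (PNW) and *R. cingulata*
#' in the eastern (ENA) and southwestern (SW) USA: PNW 30.68 +- 0.41 days
#' (SE, n = 289), ENA 40.82 +- 0.51 days (n = 71), SW 64.55 +- 0.23 days
#' (n = 579).
#'
#' @return Named list of three [eclosion_model()] objects (`PNW`, `ENA`, `SW`).
#' @export
#' @examples
#' cherry_fly_eclosion_models()$SW
cherry_fly_eclosion_models <- function() {
  list(
    PNW = eclosion_model("PNW", mean_days = 30.68, n_flies = 289, se_days = 0.41),
    ENA = eclosion_model("ENA", mean_days = 40.82, n_flies = 71,  se_days = 0.51),
    SW  = eclosion_model("SW",  mean_days = 64.55, n_flies = 579, se_days = 0.23)
  )
}

#' Generate a per-fly eclosion table
#'
#' Draws days-to-eclosion for `model$n_flies` flies from a normal distribution
#' truncated at zero (via inverse-CDF sampling) and rounds to whole days.
#'
#' @param model An [eclosion_model()].
#' @param seed Integer seed; the same model and seed reproduce the same table.
#'
#' @return A data.frame with columns `fly_id`, `population`,
#'   `days_to_eclosion`.
#' @export
#' @examples
#' ecl <- gen_eclosion(eclosion_model("PNW", 30.68, 289, se_days = 0.41), seed = 1)
#' mean(ecl$days_to_eclosion)
gen_eclosion <- function(model, seed) {
  if (!inherits(model, "eclosion_model")) {
    stop_invalid_parameter("`model` must be an eclosion_model")
  }
  n <- model$n_flies
  days <- with_seed(seed, {
    lo <- pnorm(0, model$mean_days, model$sd_days)
    u <- runif(n, min = lo, max = 1)
    round(qnorm(u, model$mean_days, model$sd_days))
  })
  data.frame(
    fly_id = sprintf("%s_%04d", model$population, seq_len(n)),
    population = model$population,
    days_to_eclosion = as.integer(days),
    stringsAsFactors = FALSE
  )
}

#' Generate a no-choice mating trial tally
#'
#' Allocates a fixed number of observed copulations between hybrid and
#' parental classes by a binomial draw, emulating pooled no-choice trials for
#' one population pair. Reciprocal hybrid directions are split evenly at
#' random, as are the two parental types.
#'
#' @param pair Character vector of the two population labels.
#' @param p_hybrid Probability that a given copulation is heterotypic
#'   (hybrid); `(1 - SI) / 2` for a target sexual-isolation index SI.
#' @param total_matings Total copulations observed (positive integer).
#' @param hours_observed Total observation hours (positive).
#' @param seed Integer seed.
#'
#' @return A `mating_tally` object with counts `H` (hybrid) and `C`
#'   (parental), per-hour rates, and a 4-row `table` in the on-disk matings
#'   schema (see [read_matings()]).
#' @export
#' @examples
#' tal <- gen_mating_trials(c("SW", "PNW"), p_hybrid = 0.295,
#'                          total_matings = 200, hours_observed = 100, seed = 1)
#' sexual_isolation(tal)
gen_mating_trials <- function(pair, p_hybrid, total_matings, hours_observed, seed) {
  if (!is.character(pair) || length(pair) != 2L || pair[1] == pair[2]) {
    stop_invalid_parameter("`pair` must be two distinct population labels")
  }
  if (!is_proportion(p_hybrid)) {
    stop_invalid_parameter("`p_hybrid` must be a proportion in [0, 1]")
  }
  if (!is_count(total_matings)) {
    stop_invalid_parameter("`total_matings` must be a positive integer")
  }
  if (!is.numeric(hours_observed) || length(hours_observed) != 1L ||
      !is.finite(hours_observed) || hours_observed <= 0) {
    stop_invalid_parameter("`hours_observed` must be a positive number")
  }
  counts <- with_seed(seed, {
    H <- rbinom(1L, size = total_matings, prob = p_hybrid)
    C <- total_matings - H
    # split each class between its two directions/types
    h1 <- rbinom(1L, size = H, prob = 0.5)
    c1 <- rbinom(1L, size = C, prob = 0.5)
    c(H = H, C = C, h1 = h1, c1 = c1)
  })
  tab <- data.frame(
    pair_female = c(pair[1], pair[2], pair[1], pair[2]),
    pair_male = c(pair[2], pair[1], pair[1], pair[2]),
    n_matings = c(counts[["h1"]], counts[["H"]] - counts[["h1"]],
                  counts[["c1"]], counts[["C"]] - counts[["c1"]]),
    hours_observed = rep(hours_observed / 4, 4L),
    cross_class = c("hybrid", "hybrid", "parental", "parental"),
    stringsAsFactors = FALSE
  )
  mating_tally(pair = pair, H = counts[["H"]], C = counts[["C"]],
               hours_observed = hours_observed, table = tab)
}

#' Mating tally for one population pair
#'
#' Pooled counts of hybrid (`H`, heterotypic) and parental (`C`, homotypic)
#' copulations for a pair of populations, with the total observation time.
#'
#' @param pair Character vector of the two population labels.
#' @param H,C Non-negative counts (or summed per-hour rates) of hybrid and
#'   parental matings; `H + C` must be positive.
#' @param hours_observed Total observation hours.
#' @param table Optional per-direction table in the matings schema.
#'
#' @return A `mating_tally` object.
#' @export
mating_tally <- function(pair, H, C, hours_observed = NA_real_, table = NULL) {
  if (!is.numeric(H) || !is.numeric(C) || length(H) != 1L || length(C) != 1L ||
      is.na(H) || is.na(C) || H < 0 || C < 0) {
    stop_invalid_parameter("`H` and `C` must be single non-negative numbers")
  }
  if (H + C <= 0) {
    stop_invalid_parameter("`H + C` must be positive")
  }
  structure(
    list(pair = pair, H = H, C = C, hours_observed = hours_observed,
         rate_H = H / hours_observed, rate_C = C / hours_observed,
         table = table),
    class = "mating_tally"
  )
}

#' @export
print.mating_tally <- function(x, ...) {
  cat(sprintf("<mating_tally> %s-%s: H = %g, C = %g (%.4g h observed)\n",
              x$pair[1], x$pair[2], x$H, x$C, x$hours_observed))
  invisible(x)
}

#' Design of an egg-hatch cross experiment
#'
#' Parameters for generating one arm (one maternal x paternal direction) of a
#' cage-based egg-hatch experiment. Cages hold 1-3 mating pairs; eggs
#' accumulate daily until more than `egg_target` eggs are collected or
#' `max_days` elapse, whichever comes first. Hybrid-cross eggs hatch at
#' `parental_hatch * (1 - ci_strength_true)`, the CI-reduced rate.
#'
#' @param maternal_pop,paternal_pop Population labels; the cross is hybrid
#'   when they differ.
#' @param n_cages Number of replicate cages (positive integer).
#' @param cage_females,cage_males Pairs per cage, integers in 1-3.
#' @param parental_hatch Baseline hatch proportion in (0, 1].
#' @param ci_strength_true True relative hatch reduction c (<= 1) applied when
#'   the cross is hybrid; the implied hybrid hatch
#'   `parental_hatch * (1 - ci_strength_true)` must lie in \[0, 1\].
#' @param eggs_per_female_day Poisson mean egg output per female per day.
#' @param max_days Observation cap in days (the 4-week rule is 28).
#' @param unfertilized_rate Background fraction of eggs that are unfertilized
#'   and can never hatch, in \[0, 1).
#' @param egg_target Stop collecting once the cage exceeds this many eggs.
#'
#' @return An object of class `cross_design`.
#' @seealso [gen_crosses()]
#' @export
cross_design <- function(maternal_pop, paternal_pop, n_cages,
                         cage_females = 1L, cage_males = 1L,
                         parental_hatch = 0.75, ci_strength_true = 0,
                         eggs_per_female_day = 2.5, max_days = 28L,
                         unfertilized_rate = 0, egg_target = 100L) {
  if (!is_count(n_cages)) stop_invalid_parameter("`n_cages` must be a positive integer")
  if (!is_count(cage_females) || cage_females > 3 ||
      !is_count(cage_males) || cage_males > 3) {
    stop_invalid_parameter("cage sizes must be integers in 1..3")
  }
  if (!is.numeric(parental_hatch) || length(parental_hatch) != 1L ||
      is.na(parental_hatch) || parental_hatch <= 0 || parental_hatch > 1) {
    stop_invalid_parameter("`parental_hatch` must lie in (0, 1]")
  }
  if (!is.numeric(ci_strength_true) || length(ci_strength_true) != 1L ||
      is.na(ci_strength_true) || ci_strength_true > 1) {
    stop_invalid_parameter("`ci_strength_true` must be a number <= 1")
  }
  hybrid_hatch <- parental_hatch * (1 - ci_strength_true)
  if (hybrid_hatch < 0 || hybrid_hatch > 1) {
    stop_invalid_parameter(sprintf(
      "implied hybrid hatch %.3f = parental_hatch * (1 - ci_strength_true) is outside [0, 1]",
      hybrid_hatch))
  }
  if (!is.numeric(eggs_per_female_day) || eggs_per_female_day <= 0) {
    stop_invalid_parameter("`eggs_per_female_day` must be positive")
  }
  if (!is_count(max_days)) stop_invalid_parameter("`max_days` must be a positive integer")
  if (!is.numeric(unfertilized_rate) || unfertilized_rate < 0 || unfertilized_rate >= 1) {
    stop_invalid_parameter("`unfertilized_rate` must lie in [0, 1)")
  }
  structure(
    list(maternal_pop = maternal_pop, paternal_pop = paternal_pop,
         n_cages = as.integer(n_cages),
         cage_females = as.integer(cage_females),
         cage_males = as.integer(cage_males),
         parental_hatch = parental_hatch,
         ci_strength_true = ci_strength_true,
         hybrid_hatch = hybrid_hatch,
         eggs_per_female_day = eggs_per_female_day,
         max_days = as.integer(max_days),
         unfertilized_rate = unfertilized_rate,
         egg_target = as.integer(egg_target)),
    class = "cross_design"
  )
}

#' Generate a cage-level cross table
#'
#' Simulates each cage of a [cross_design()]: daily egg output is Poisson with
#' mean `cage_females * eggs_per_female_day`, accumulated until the cage
#' exceeds `egg_target` eggs or `max_days` elapse. Each egg is unfertilized
#' with probability `unfertilized_rate` (never hatches); otherwise it hatches
#' with probability `parental_hatch`, reduced by the factor
#' `1 - ci_strength_true` when the cross is hybrid (maternal and paternal
#' populations differ).
#'
#' @param design A [cross_design()].
#' @param seed Integer seed.
#'
#' @return A data.frame in the crosses schema: `cage_id`, `maternal_pop`,
#'   `paternal_pop`, `cage_females`, `cage_males`, `days_observed`,
#'   `eggs_laid`, `eggs_hatched`.
#' @export
#' @examples
#' d <- cross_design("PNW", "SW", n_cages = 5, parental_hatch = 0.75,
#'                   ci_strength_true = 0.8)
#' gen_crosses(d, seed = 11)
gen_crosses <- function(design, seed) {
  if (!inherits(design, "cross_design")) {
    stop_invalid_parameter("`design` must be a cross_design")
  }
  is_hybrid <- design$maternal_pop != design$paternal_pop
  p_hatch <- if (is_hybrid) design$hybrid_hatch else design$parental_hatch
  p_hatch <- p_hatch * (1 - design$unfertilized_rate)
  lambda <- design$cage_females * design$eggs_per_female_day
  with_seed(seed, {
    rows <- lapply(seq_len(design$n_cages), function(i) {
      eggs <- 0L
      day <- 0L
      while (day < design$max_days && eggs <= design$egg_target) {
        day <- day + 1L
        eggs <- eggs + rpois(1L, lambda)
      }
      hatched <- rbinom(1L, size = eggs, prob = p_hatch)
      data.frame(
        cage_id = sprintf("%sx%s_%03d", design$maternal_pop, design$paternal_pop, i),
        maternal_pop = design$maternal_pop,
        paternal_pop = design$paternal_pop,
        cage_females = design$cage_females,
        cage_males = design$cage_males,
        days_observed = day,
        eggs_laid = eggs,
        eggs_hatched = hatched,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Generate an endosymbiont infection survey
#'
#' Draws per-fly infection status for two strains from per-population
#' multinomial frequencies over the three compatible states: singly infected
#' by either strain, or doubly infected.
#'
#' @param strain_freqs Named list (one element per population) of numeric
#'   vectors with entries `wCin2`, `wCin3` and `double`, each the proportion
#'   of flies in that state; every vector must sum to 1 (tolerance 1e-9).
#' @param n_per_pop Flies sampled per population (positive integer).
#' @param seed Integer seed.
#'
#' @return A data.frame with columns `fly_id`, `population`, `wCin2`, `wCin3`
#'   (presence coded 1/0).
#' @export
#' @examples
#' freqs <- list(SW = c(wCin2 = 0, wCin3 = 0.125, double = 0.875))
#' gen_infection_survey(freqs, n_per_pop = 8, seed = 3)
gen_infection_survey <- function(strain_freqs, n_per_pop, seed) {
  if (!is.list(strain_freqs) || is.null(names(strain_freqs)) ||
      any(!nzchar(names(strain_freqs)))) {
    stop_invalid_parameter("`strain_freqs` must be a named list of per-population frequencies")
  }
  if (!is_count(n_per_pop)) {
    stop_invalid_parameter("`n_per_pop` must be a positive integer")
  }
  states <- c("wCin2", "wCin3", "double")
  for (pop in names(strain_freqs)) {
    f <- strain_freqs[[pop]]
    if (!is.numeric(f) || !all(states %in% names(f))) {
      stop_invalid_parameter(sprintf(
        "frequencies for population '%s' must be named over {%s}",
        pop, paste(states, collapse = ", ")))
    }
    if (any(f < 0) || abs(sum(f[states]) - 1) > 1e-9) {
      stop_invalid_parameter(sprintf(
        "frequencies for population '%s' must be non-negative and sum to 1", pop))
    }
  }
  with_seed(seed, {
    rows <- lapply(names(strain_freqs), function(pop) {
      f <- strain_freqs[[pop]][states]
      counts <- as.vector(rmultinom(1L, size = n_per_pop, prob = f))
      state <- rep(states, counts)
      data.frame(
        fly_id = sprintf("%s_%03d", pop, seq_len(n_per_pop)),
        population = pop,
        wCin2 = as.integer(state %in% c("wCin2", "double")),
        wCin3 = as.integer(state %in% c("wCin3", "double")),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
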