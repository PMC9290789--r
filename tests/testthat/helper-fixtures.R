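# Shared fixtures: tiny deterministic tables used across test files.

published_models <- function() cherry_fly_eclosion_models()

# Eclosion table with explicit days, for hand-enumerable activity profiles.
ecl_table <- function(days, population = "X") {
  data.frame(population = rep(population, length(days)),
             days_to_eclosion = days, stringsAsFactors = FALSE)
}

# A cross table written out by hand for filter-enumeration tests.
hand_crosses <- function() {
  data.frame(
    cage_id = sprintf("c%02d", 1:6),
    maternal_pop = c("A", "A", "A", "A", "B", "B"),
    paternal_pop = c("A", "A", "B", "B", "B", "B"),
    cage_females = c(1L, 1L, 1L, 2L, 1L, 1L),
    cage_males = c(1L, 1L, 1L, 2L, 1L, 1L),
    days_observed = c(10L, 5L, 8L, 8L, 10L, 10L),
    eggs_laid = c(30L, 9L, 10L, 50L, 40L, 0L),
    eggs_hatched = c(30L, 9L, 5L, 25L, 36L, 0L),
    stringsAsFactors = FALSE
  )
}

# Both arms (parental sink x sink, hybrid sink female x source male) of a
# cross experiment at a known CI strength.
paired_cross_arms <- function(ci_true, n_cages = 40L, seed = 11L,
                              parental_hatch = 0.75) {
  parental <- cross_design("PNW", "PNW", n_cages = n_cages,
                           parental_hatch = parental_hatch)
  hybrid <- cross_design("PNW", "SW", n_cages = n_cages,
                         parental_hatch = parental_hatch,
                         ci_strength_true = ci_true)
  rbind(gen_crosses(parental, seed = seed),
        gen_crosses(hybrid, seed = seed + 1L))
}

estimate_ci <- function(crosses, sink = "PNW", source = "SW") {
  hp <- hatch_proportions(crosses)
  par_h <- hp$mean_hatch[hp$maternal_pop == sink & hp$paternal_pop == sink]
  hyb_h <- hp$mean_hatch[hp$maternal_pop == sink & hp$paternal_pop == source]
  ci_strength(hyb_h, par_h)
}
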