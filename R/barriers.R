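#' Daily sexual-activity profile of a population
#'
#' Converts a per-fly eclosion table into the proportion of flies that are
#' sexually active on each calendar day. A fly eclosing on day `e` is active
#' on the inclusive integer day range `e + window[1]` to `e + window[2]`;
#' cherry flies need about 7 days posteclosion to reach sexual maturity and
#' survive 15-30 days, so the two windows of interest are `c(7, 15)` and
#' `c(7, 30)`.
#'
#' @param eclosion Data.frame with columns `population` and
#'   `days_to_eclosion` (non-negative; rounded to whole days).
#' @param window Integer vector `c(start_offset, end_offset)`, both in days
#'   posteclosion, `0 <= start <= end`.
#'
#' @return An `activity_profile`: list with `population`, integer `day_index`,
#'   and `active_proportion` (fraction of the cohort active on each day),
#'   trimmed to the nonzero support.
#' @export
#' @examples
#' ecl <- data.frame(population = "X", days_to_eclosion = c(0, 10))
#' activity_profile(ecl, window = c(7, 15))
activity_profile <- function(eclosion, window = c(7L, 30L)) {
  if (!is.data.frame(eclosion) || nrow(eclosion) == 0L) {
    stop_empty_input("`eclosion` must be a non-empty data.frame")
  }
  if (!all(c("population", "days_to_eclosion") %in% names(eclosion))) {
    stop_schema("`eclosion` needs columns 'population' and 'days_to_eclosion'")
  }
  if (!is.numeric(window) || length(window) != 2L || any(is.na(window)) ||
      window[1] < 0 || window[1] > window[2] ||
      any(window != floor(window))) {
    stop_invalid_parameter("`window` must be integer offsets c(start, end) with 0 <= start <= end")
  }
  days <- round(eclosion$days_to_eclosion)
  if (any(is.na(days)) || any(days < 0)) {
    stop_validation("`days_to_eclosion` must be non-negative and non-missing")
  }
  n <- length(days)
  start <- days + window[1]
  end <- days + window[2]
  grid <- seq.int(min(start), max(end))
  counts <- numeric(length(grid))
  for (i in seq_len(n)) {
    idx <- (start[i] - grid[1] + 1L):(end[i] - grid[1] + 1L)
    counts[idx] <- counts[idx] + 1
  }
  keep <- range(which(counts > 0))
  structure(
    list(population = unique(eclosion$population)[1],
         day_index = as.integer(grid[keep[1]:keep[2]]),
         active_proportion = counts[keep[1]:keep[2]] / n,
         window = as.integer(window),
         n_flies = n),
    class = "activity_profile"
  )
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile> %s: days %d-%d, window (%d, %d), n = %d\n",
              x$population, min(x$day_index), max(x$day_index),
              x$window[1], x$window[2], x$n_flies))
  invisible(x)
}

# Align two profiles on the union of their day grids, zero-padded.
align_profiles <- function(x, y) {
  lo <- min(x$day_index[1], y$day_index[1])
  hi <- max(x$day_index[length(x$day_index)], y$day_index[length(y$day_index)])
  xv <- yv <- numeric(hi - lo + 1L)
  xv[x$day_index - lo + 1L] <- x$active_proportion
  yv[y$day_index - lo + 1L] <- y$active_proportion
  list(x = xv, y = yv)
}

#' Allochronic (temporal premating) isolation between two populations
#'
#' The cosine-dissimilarity of two daily activity profiles, scaled to percent:
#' \deqn{AI = \left[1 - \frac{\sum_i x_i y_i}{\sqrt{\sum_i x_i^2 \sum_i y_i^2}}\right] \times 100}
#' where \eqn{x_i} and \eqn{y_i} are the proportions of sexually active flies
#' on day *i*. AI is 0 for identical phenologies, 100 for fully disjoint ones,
#' symmetric in its arguments, and invariant to rescaling either profile.
#'
#' @param profile_x,profile_y [activity_profile()] objects (aligned internally
#'   on the union of their day grids).
#'
#' @return AI in percent, a number in \[0, 100\].
#' @export
#' @examples
#' ecl1 <- data.frame(population = "A", days_to_eclosion = 0)
#' ecl2 <- data.frame(population = "B", days_to_eclosion = 40)
#' allochronic_isolation(activity_profile(ecl1), activity_profile(ecl2)) # 100
allochronic_isolation <- function(profile_x, profile_y) {
  if (!inherits(profile_x, "activity_profile") ||
      !inherits(profile_y, "activity_profile")) {
    stop_invalid_parameter("both arguments must be activity_profile objects")
  }
  al <- align_profiles(profile_x, profile_y)
  sx2 <- sum(al$x^2)
  sy2 <- sum(al$y^2)
  if (sx2 == 0 || sy2 == 0) {
    stop_undefined_statistic("allochronic isolation undefined: a profile is all zero")
  }
  (1 - sum(al$x * al$y) / sqrt(sx2 * sy2)) * 100
}

#' Sexual isolation index from a mating tally
#'
#' The joint-count isolation index \eqn{SI = 1 - 2H/(H + C)}, where `H` counts
#' hybrid (heterotypic) and `C` parental (homotypic) copulations. SI is 1 for
#' complete isolation, 0 for random mating, and -1 when all matings are
#' heterotypic. When assays differ in observation time, per-hour standardized
#' rates can be used in place of raw counts.
#'
#' @param tally A [mating_tally()], or a list/data.frame with elements `H` and
#'   `C`.
#' @param use_rates If `TRUE`, use the per-hour rates stored in the tally
#'   rather than raw counts (identical result for a single pooled tally).
#'
#' @return SI in \[-1, 1\].
#' @export
#' @examples
#' sexual_isolation(mating_tally(c("A", "B"), H = 2, C = 8)) # 0.6
sexual_isolation <- function(tally, use_rates = FALSE) {
  H <- if (use_rates) tally$rate_H else tally$H
  C <- if (use_rates) tally$rate_C else tally$C
  if (is.null(H) || is.null(C) || is.na(H) || is.na(C)) {
    stop_invalid_parameter("`tally` must carry H and C (or rates when use_rates = TRUE)")
  }
  if (H + C <= 0) {
    stop_undefined_statistic("sexual isolation undefined: H + C = 0")
  }
  1 - 2 * H / (H + C)
}

#' Hybrid mating probability implied by a sexual-isolation index
#'
#' Inverts the isolation index: the probability that a copulation is
#' heterotypic is \eqn{H/(H+C) = (1 - SI)/2}, the premating contribution to
#' the probability of gene flow.
#'
#' @param si Sexual isolation index in \[-1, 1\].
#' @return A proportion in \[0, 1\].
#' @export
#' @examples
#' hybrid_mating_probability(0.41) # 0.295
hybrid_mating_probability <- function(si) {
  if (!is.numeric(si) || any(is.na(si)) || any(si < -1) || any(si > 1)) {
    stop_invalid_parameter("`si` must lie in [-1, 1]")
  }
  (1 - si) / 2
}

#' Mean hatch proportion per cross direction
#'
#' Computes, for each (maternal, paternal) direction in a cross table, the
#' unweighted mean across cages of the per-cage hatch proportion
#' `eggs_hatched / eggs_laid`, after excluding cages that produced fewer than
#' `min_eggs` eggs. The egg threshold controls for the small numbers of
#' unfertilized eggs that unmated females can lay.
#'
#' @param crosses Cross table (see [gen_crosses()] / [read_crosses()]).
#' @param min_eggs Minimum eggs laid for a cage to enter the mean (default 10).
#'
#' @return Data.frame with one row per direction: `maternal_pop`,
#'   `paternal_pop`, `n_cages`, `n_excluded`, `mean_hatch`, `se_hatch`.
#' @export
hatch_proportions <- function(crosses, min_eggs = 10L) {
  validate_crosses(crosses)
  key <- interaction(crosses$maternal_pop, crosses$paternal_pop, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    sub <- crosses[key == k, , drop = FALSE]
    pass <- sub$eggs_laid >= min_eggs
    if (!any(pass)) {
      stop_undefined_statistic(sprintf(
        "no cage with >= %d eggs in direction %s female x %s male",
        min_eggs, sub$maternal_pop[1], sub$paternal_pop[1]))
    }
    props <- sub$eggs_hatched[pass] / sub$eggs_laid[pass]
    data.frame(
      maternal_pop = sub$maternal_pop[1],
      paternal_pop = sub$paternal_pop[1],
      n_cages = sum(pass),
      n_excluded = sum(!pass),
      mean_hatch = mean(props),
      se_hatch = if (sum(pass) > 1) sd(props) / sqrt(sum(pass)) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' CI strength from hybrid and parental hatch rates
#'
#' The relative reduction in egg hatch attributable to cytoplasmic
#' incompatibility: \eqn{c = 1 - \mathrm{hybrid}/\mathrm{parental}}; 1 means
#' no hybrid eggs hatch, 0 means hybrid and parental crosses hatch equally.
#' Sampling noise can push the estimate below zero; negative values are
#' reported with a warning rather than truncated.
#'
#' @param hybrid_hatch,parental_hatch Mean hatch proportions; `parental_hatch`
#'   must be positive.
#'
#' @return The CI strength estimate (a number <= 1).
#' @export
#' @examples
#' ci_strength(0.15, 0.75) # 0.8
ci_strength <- function(hybrid_hatch, parental_hatch) {
  if (!is.numeric(hybrid_hatch) || !is.numeric(parental_hatch) ||
      length(hybrid_hatch) != 1L || length(parental_hatch) != 1L ||
      is.na(hybrid_hatch) || is.na(parental_hatch)) {
    stop_invalid_parameter("hatch rates must be single numbers")
  }
  if (parental_hatch <= 0) {
    stop_undefined_statistic("CI strength undefined: parental hatch rate is zero")
  }
  cc <- 1 - hybrid_hatch / parental_hatch
  if (cc < 0) {
    warning("estimated CI strength is negative (hybrid hatch exceeds parental); ",
            "reported unclamped", call. = FALSE)
  }
  cc
}

#' Fecundity summary (eggs per female per day) per cross direction
#'
#' Restricted to single-pair (1 female x 1 male) cages, computes per cage
#' `eggs_laid / days_observed` and summarizes each (maternal, paternal)
#' direction with its unweighted mean and standard error. Zero-egg cages
#' contribute zeros; they are not excluded.
#'
#' @param crosses Cross table (see [gen_crosses()] / [read_crosses()]).
#'
#' @return Data.frame with columns `maternal_pop`, `paternal_pop`, `n_cages`,
#'   `mean_eggs_female_day`, `se_eggs_female_day`.
#' @export
fecundity_summary <- function(crosses) {
  validate_crosses(crosses)
  sub <- crosses[crosses$cage_females == 1L & crosses$cage_males == 1L, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop_undefined_statistic("no 1 female x 1 male cages in the cross table")
  }
  rate <- sub$eggs_laid / sub$days_observed
  key <- interaction(sub$maternal_pop, sub$paternal_pop, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    r <- rate[key == k]
    data.frame(
      maternal_pop = sub$maternal_pop[key == k][1],
      paternal_pop = sub$paternal_pop[key == k][1],
      n_cages = length(r),
      mean_eggs_female_day = mean(r),
      se_eggs_female_day = if (length(r) > 1) sd(r) / sqrt(length(r)) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
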