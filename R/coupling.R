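#' Probability of gene flow after compounding isolating barriers
#'
#' Composes allochronic and sexual isolation into the probability of gene
#' flow between two populations in hypothetical sympatry,
#' \deqn{p(GH) = \left[m_0 (1 - AI/100)\right] \cdot \frac{1 - SI}{2},}
#' where the baseline migration rate \eqn{m_0 = 0.5} reflects panmixia. The
#' first bracket is the temporal co-occurrence factor, the second the
#' probability that a copulation is heterotypic. The composition follows the
#' published worked products exactly; note that with both barriers absent it
#' evaluates to \eqn{m_0/2 = 0.25}, not \eqn{m_0} (see the methods vignette).
#'
#' @param ai_percent Allochronic isolation in percent, \[0, 100\].
#' @param si Sexual isolation index in \[-1, 1\].
#' @param baseline_m Baseline migration proportion (default 0.5).
#'
#' @return p(GH), a probability (vectorized over the inputs).
#' @export
#' @examples
#' gene_flow_probability(96.5, 0.41)  # 0.0175 * 0.295 = 5.163e-3
#' gene_flow_probability(99.57, 0.41) # 0.00215 * 0.295 = 6.342e-4
gene_flow_probability <- function(ai_percent, si, baseline_m = 0.5) {
  if (!is.numeric(ai_percent) || any(is.na(ai_percent)) ||
      any(ai_percent < 0) || any(ai_percent > 100)) {
    stop_invalid_parameter("`ai_percent` must lie in [0, 100]")
  }
  if (!is.numeric(si) || any(is.na(si)) || any(si < -1) || any(si > 1)) {
    stop_invalid_parameter("`si` must lie in [-1, 1]")
  }
  if (!is.numeric(baseline_m) || any(is.na(baseline_m)) ||
      any(baseline_m < 0) || any(baseline_m > 1)) {
    stop_invalid_parameter("`baseline_m` must lie in [0, 1]")
  }
  baseline_m * (1 - ai_percent / 100) * hybrid_mating_probability(si)
}

#' Critical migration rate for unidirectional CI (symmetric migration)
#'
#' Closed-form invasion threshold for a CI-inducing endosymbiont spreading
#' from an infected into an uninfected population, as a function of CI
#' strength `c` and maternal transmission `t`:
#' \deqn{m_k = \min\left\{\frac{c - 4t(1-t)}{4t^2},\;
#'   \frac{4ct\,(1-\sqrt{t})^2}{\left(c + \sqrt{c^2 - 4ct(1-t)}\right)^2}\right\}.}
#' The first branch is the rate above which the infected population is so
#' diluted by uninfected immigrants that its high-infection equilibrium
#' vanishes; the second is the rate above which infected immigrants push the
#' uninfected population past its unstable invasion threshold. Both are exact
#' saddle-node conditions of the single-population recursion
#' \eqn{p' = pt/(1 - cp(1 - tp))} with the partner population pinned at its
#' equilibrium, and hence lower bounds for the fully coupled two-population
#' system (see [find_critical_migration()]).
#'
#' Bistability requires \eqn{c \ge 4t(1-t)}; outside that region no invasion
#' threshold exists and an error is raised.
#'
#' @param c CI strength (relative hatch reduction) in \[0, 1\].
#' @param t Maternal transmission rate in (0, 1\].
#' @param branches If `TRUE`, return both branch values alongside the minimum.
#'
#' @return The critical migration rate (or, with `branches = TRUE`, a named
#'   list with `m_k`, `retention` and `invasion` branch values).
#' @export
#' @examples
#' unidirectional_mk(0.8, 0.99)   # ~3.2e-5
#' unidirectional_mk(0.738, 0.875) # ~7.4e-3
unidirectional_mk <- function(c, t, branches = FALSE) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0 || c > 1) {
    stop_invalid_parameter("`c` must lie in [0, 1]")
  }
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0 || t > 1) {
    stop_invalid_parameter("`t` must lie in (0, 1]")
  }
  disc <- c^2 - 4 * c * t * (1 - t)
  if (disc < 0 || c == 0) {
    stop_no_threshold(sprintf(
      "no bistability at c = %g, t = %g (requires c >= 4t(1-t) = %g): a rare infection cannot persist",
      c, t, 4 * t * (1 - t)))
  }
  retention <- (c - 4 * t * (1 - t)) / (4 * t^2)
  invasion <- 4 * c * t * (1 - sqrt(t))^2 / (c + sqrt(disc))^2
  if (branches) {
    list(m_k = min(retention, invasion), retention = retention, invasion = invasion)
  } else {
    min(retention, invasion)
  }
}

#' Critical migration rate for bidirectional CI (lower bound)
#'
#' Closed-form lower-bound invasion threshold when two populations are fixed
#' for different CI-inducing strains with perfect maternal transmission:
#' \deqn{m_k = \frac{2(a+b) - ab - 2\sqrt{(a+b)^2 - a^2 b - a b^2}}{a^2},}
#' where `a` is the CI level of the strain with the larger effect and `b` the
#' lesser. It is the exact saddle-node threshold for a population resisting
#' immigrants from a source fixed for the stronger strain (mainland-island
#' configuration), and therefore bounds the symmetric two-population
#' threshold from below.
#'
#' @param a CI level of the stronger strain, in (0, 1\].
#' @param b CI level of the weaker strain, in \[0, a\].
#'
#' @return The critical migration rate.
#' @export
#' @examples
#' bidirectional_mk(1, 1)   # 6 - 4*sqrt(2) ~ 0.1716
#' bidirectional_mk(1, 0.5) # ~0.0505
bidirectional_mk <- function(a, b) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) ||
      !is.numeric(b) || length(b) != 1L || is.na(b)) {
    stop_invalid_parameter("`a` and `b` must be single numbers")
  }
  if (a <= 0) {
    stop_no_threshold("bidirectional m_k undefined for a = 0 (formula divides by a^2)")
  }
  if (a > 1 || b < 0 || b > a) {
    stop_invalid_parameter("require 1 >= a >= b >= 0")
  }
  (2 * (a + b) - a * b - 2 * sqrt((a + b)^2 - a^2 * b - a * b^2)) / a^2
}

#' Introgression verdict for one barrier/threshold comparison
#'
#' Applies the decision rule: the endosymbiont strain is expected to
#' *introgress* when the probability of gene flow exceeds the critical
#' migration rate, to be *retained* (strain difference preserved) when it is
#' below, and *indeterminate* within an absolute tolerance band of equality.
#'
#' @param p_gh Probability of gene flow (non-negative; vectorized).
#' @param m_k Critical migration rate (non-negative; vectorized).
#' @param tol Absolute half-width of the indeterminate band (default 1e-12;
#'   the compared quantities span roughly 1e-5 to 1e-2).
#'
#' @return Character vector over `{"introgress", "retained", "indeterminate"}`.
#' @export
#' @examples
#' introgression_verdict(6.342e-4, 3e-5) # "introgress"
introgression_verdict <- function(p_gh, m_k, tol = 1e-12) {
  if (!is.numeric(p_gh) || !is.numeric(m_k) || any(is.na(p_gh)) ||
      any(is.na(m_k)) || any(p_gh < 0) || any(m_k < 0)) {
    stop_invalid_parameter("`p_gh` and `m_k` must be non-negative numbers")
  }
  ifelse(abs(p_gh - m_k) <= tol, "indeterminate",
         ifelse(p_gh > m_k, "introgress", "retained"))
}

#' Verdict table over lifespan and transmission scenarios
#'
#' Builds the full scenario grid for a set of population pairs: for every
#' pair, lifespan scenario and transmission rate, computes p(GH) from the
#' pair's barrier estimates, the critical migration rate from its CI
#' parameters, and the introgression verdict.
#'
#' @param barriers Data.frame with one row per pair and lifespan scenario:
#'   columns `pair` (label such as `"SW-PNW"`), `lifespan` (scenario label,
#'   e.g. `"30-day"`), `ai_percent`, `si`. Duplicated (pair, lifespan) rows
#'   are deduplicated.
#' @param ci_params Data.frame with one row per pair: columns `pair`, `mode`
#'   (`"unidirectional"` or `"bidirectional"`), and `c` (unidirectional) or
#'   `a`, `b` (bidirectional).
#' @param transmission Numeric vector of maternal transmission rates in
#'   (0, 1\] (applied to unidirectional pairs; the bidirectional bound assumes
#'   perfect transmission and is constant across the grid).
#' @param baseline_m Baseline migration proportion for p(GH).
#' @param tol Equality tolerance for the verdict.
#'
#' @return Data.frame ordered by (pair, lifespan, transmission) with columns
#'   `pair`, `lifespan`, `transmission`, `ai_percent`, `si`, `p_gh`, `m_k`,
#'   `verdict`. Empty inputs give an empty table.
#' @export
scenario_table <- function(barriers, ci_params,
                           transmission = c(0.875, 0.99),
                           baseline_m = 0.5, tol = 1e-12) {
  empty <- data.frame(
    pair = character(), lifespan = character(), transmission = numeric(),
    ai_percent = numeric(), si = numeric(), p_gh = numeric(),
    m_k = numeric(), verdict = character(), stringsAsFactors = FALSE
  )
  if (is.null(barriers) || nrow(barriers) == 0L ||
      is.null(ci_params) || nrow(ci_params) == 0L ||
      length(transmission) == 0L) {
    return(empty)
  }
  need_b <- c("pair", "lifespan", "ai_percent", "si")
  if (!all(need_b %in% names(barriers))) {
    stop_schema(sprintf("`barriers` needs columns: %s",
                        paste(setdiff(need_b, names(barriers)), collapse = ", ")))
  }
  if (!all(c("pair", "mode") %in% names(ci_params))) {
    stop_schema("`ci_params` needs columns 'pair' and 'mode'")
  }
  if (any(transmission <= 0 | transmission > 1)) {
    stop_invalid_parameter("transmission rates must lie in (0, 1]")
  }
  barriers <- barriers[!duplicated(barriers[c("pair", "lifespan")]), , drop = FALSE]
  ci_params <- ci_params[!duplicated(ci_params$pair), , drop = FALSE]

  rows <- list()
  for (pr in unique(ci_params$pair)) {
    ci <- ci_params[ci_params$pair == pr, , drop = FALSE]
    br <- barriers[barriers$pair == pr, , drop = FALSE]
    if (nrow(br) == 0L) {
      stop_missing_input(sprintf("no barrier estimates for pair '%s'", pr))
    }
    for (ls in unique(br$lifespan)) {
      bl <- br[br$lifespan == ls, , drop = FALSE]
      p <- gene_flow_probability(bl$ai_percent, bl$si, baseline_m)
      for (tt in sort(transmission)) {
        mk <- switch(ci$mode,
          unidirectional = unidirectional_mk(ci$c, tt),
          bidirectional = bidirectional_mk(ci$a, ci$b),
          stop_invalid_parameter(sprintf("unknown CI mode '%s'", ci$mode))
        )
        rows[[length(rows) + 1L]] <- data.frame(
          pair = pr, lifespan = ls, transmission = tt,
          ai_percent = bl$ai_percent, si = bl$si, p_gh = p, m_k = mk,
          verdict = introgression_verdict(p, mk, tol),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$pair, out$lifespan, out$transmission), , drop = FALSE]
}
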