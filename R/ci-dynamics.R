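#' One generation of the single-population CI recursion
#'
#' Deterministic infinite-population recursion for the frequency `p` of an
#' endosymbiont that causes cytoplasmic incompatibility of strength `c` with
#' maternal transmission `t` (no fitness cost, no drift):
#' \deqn{p' = \frac{pt}{1 - cp(1 - tp)}.}
#' Infected mothers transmit to a fraction `t` of eggs; uninfected eggs sired
#' by infected males (frequency `p`) die with probability `c`. Besides
#' extinction at 0, the interior fixed points are the roots of
#' \eqn{ctp^2 - cp + (1 - t) = 0} (see [stable_unstable_equilibria()]).
#'
#' @param p Infection frequency in \[0, 1\] (vectorized).
#' @param c CI strength in \[0, 1\].
#' @param t Maternal transmission rate in (0, 1\].
#'
#' @return Next-generation frequency, in \[0, 1\].
#' @export
#' @examples
#' step_single(0.5, c = 0.8, t = 0.9)
step_single <- function(p, c, t) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_invalid_parameter("`p` must lie in [0, 1]")
  }
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0 || c > 1) {
    stop_invalid_parameter("`c` must lie in [0, 1]")
  }
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0 || t > 1) {
    stop_invalid_parameter("`t` must lie in (0, 1]")
  }
  p * t / (1 - c * p * (1 - t * p))
}

#' Stable and unstable equilibria of the CI recursion
#'
#' The two positive fixed points of [step_single()], i.e. the roots of
#' \eqn{ctp^2 - cp + (1-t) = 0}: the larger is the stable high-infection
#' equilibrium, the smaller the unstable invasion threshold below which a
#' rare infection is lost. Bistability requires the discriminant
#' \eqn{c^2 - 4ct(1-t) \ge 0}.
#'
#' @inheritParams step_single
#' @return Named numeric vector `c(stable = , unstable = )`, both in (0, 1\]
#'   (with perfect transmission the pair is `(1, 0)`).
#' @export
#' @examples
#' stable_unstable_equilibria(0.8, 0.99)
stable_unstable_equilibria <- function(c, t) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 0 || c > 1) {
    stop_invalid_parameter("`c` must lie in (0, 1]")
  }
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0 || t > 1) {
    stop_invalid_parameter("`t` must lie in (0, 1]")
  }
  if (t == 1) {
    return(c(stable = 1, unstable = 0))
  }
  disc <- c^2 - 4 * c * t * (1 - t)
  if (disc < 0) {
    stop_no_threshold(sprintf(
      "no bistability at c = %g, t = %g: discriminant c^2 - 4ct(1-t) = %g < 0",
      c, t, disc))
  }
  r <- sqrt(disc)
  c(stable = (c + r) / (2 * c * t), unstable = (c - r) / (2 * c * t))
}

#' Dynamics parameters for the two-population CI simulator
#'
#' @param mode `"unidirectional"` (one strain, infected vs uninfected
#'   populations) or `"bidirectional"` (two mutually incompatible strains).
#' @param c CI strength (unidirectional mode).
#' @param t Maternal transmission rate in (0, 1\]; the bidirectional closed
#'   form assumes perfect transmission, so `t` defaults to 1 in that mode but
#'   the recursion itself accepts any `t`.
#' @param m Symmetric per-generation migration proportion in \[0, 0.5\].
#' @param a,b CI levels of the stronger and weaker strain (bidirectional
#'   mode), with `1 >= a >= b >= 0`.
#'
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(mode = c("unidirectional", "bidirectional"),
                            c = NULL, t = NULL, m = 0,
                            a = NULL, b = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m > 0.5) {
    stop_invalid_parameter("`m` must lie in [0, 0.5]")
  }
  if (mode == "unidirectional") {
    if (is.null(c) || is.null(t)) {
      stop_invalid_parameter("unidirectional mode requires `c` and `t`")
    }
    if (c < 0 || c > 1) stop_invalid_parameter("`c` must lie in [0, 1]")
    if (t <= 0 || t > 1) stop_invalid_parameter("`t` must lie in (0, 1]")
  } else {
    if (is.null(a) || is.null(b)) {
      stop_invalid_parameter("bidirectional mode requires `a` and `b`")
    }
    if (a < b || a > 1 || b < 0) stop_invalid_parameter("require 1 >= a >= b >= 0")
    if (is.null(t)) t <- 1
    if (t <= 0 || t > 1) stop_invalid_parameter("`t` must lie in (0, 1]")
  }
  structure(list(mode = mode, c = c, t = t, m = m, a = a, b = b),
            class = "dynamics_params")
}

#' Simulation state for one or two populations
#'
#' @param freq Numeric matrix of infection frequencies, one row per
#'   population, one column per strain (a single column for unidirectional
#'   dynamics; columns `A`, `B` for bidirectional).
#' @param generation Generation counter (starts at 0).
#'
#' @return An object of class `sim_state`.
#' @export
sim_state <- function(freq, generation = 0L) {
  freq <- as.matrix(freq)
  if (any(is.na(freq)) || any(freq < -1e-9) || any(freq > 1 + 1e-9)) {
    stop_numerical("infection frequencies must lie in [0, 1]")
  }
  if (any(rowSums(freq) > 1 + 1e-9)) {
    stop_numerical("per-population strain frequencies must sum to at most 1")
  }
  freq[] <- pmin(pmax(freq, 0), 1)
  structure(list(freq = freq, generation = as.integer(generation)),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> generation %d\n", x$generation))
  print(x$freq)
  invisible(x)
}

# Bidirectional within-population recursion (two strains, no double
# infection): mothers of strain i transmit to fraction t of eggs; an egg not
# carrying the sire's strain dies with probability equal to that strain's CI
# level (a for strain A sires, b for strain B sires).
bidi_repro <- function(x, y, a, b, t) {
  u <- 1 - x - y
  survA <- 1 - b * y           # A eggs: killed only by B sires
  survB <- 1 - a * x           # B eggs: killed only by A sires
  survU <- 1 - a * x - b * y   # uninfected eggs: killed by either
  wx <- t * x * survA
  wy <- t * y * survB
  W <- wx + wy + ((1 - t) * (x + y) + u) * survU
  c(wx / W, wy / W)
}

#' One generation of the two-population CI recursion
#'
#' Advances a two-population [sim_state()] by one generation: symmetric
#' migration first (each population receives a proportion `m` of the other's
#' composition), then local reproduction via the unidirectional recursion
#' ([step_single()]) or the two-strain bidirectional recursion.
#'
#' @param state A [sim_state()] with two rows.
#' @param params A [dynamics_params()].
#'
#' @return The next [sim_state()] (generation incremented).
#' @export
#' @examples
#' st <- sim_state(matrix(c(0.99, 0), ncol = 1))
#' pp <- dynamics_params("unidirectional", c = 0.8, t = 0.99, m = 0.01)
#' step_two_pop(st, pp)
step_two_pop <- function(state, params) {
  if (!inherits(state, "sim_state")) stop_invalid_parameter("`state` must be a sim_state")
  if (!inherits(params, "dynamics_params")) {
    stop_invalid_parameter("`params` must be dynamics_params")
  }
  freq <- state$freq
  if (nrow(freq) != 2L) stop_invalid_parameter("`state` must hold exactly two populations")
  m <- params$m
  mig <- (1 - m) * freq + m * freq[2:1, , drop = FALSE]
  if (params$mode == "unidirectional") {
    if (ncol(mig) != 1L) stop_invalid_parameter("unidirectional state needs one strain column")
    new <- matrix(step_single(mig[, 1], params$c, params$t), ncol = 1)
  } else {
    if (ncol(mig) != 2L) stop_invalid_parameter("bidirectional state needs two strain columns")
    new <- rbind(
      bidi_repro(mig[1, 1], mig[1, 2], params$a, params$b, params$t),
      bidi_repro(mig[2, 1], mig[2, 2], params$a, params$b, params$t)
    )
  }
  if (any(new < -1e-9) || any(new > 1 + 1e-9)) {
    stop_numerical("frequencies left [0, 1] beyond numerical tolerance")
  }
  dimnames(new) <- dimnames(freq)
  sim_state(new, state$generation + 1L)
}

# Iterate population 2 against a source population. scheme = "mainland_island"
# pins population 1 at `source` (the model under which the closed-form
# thresholds are exact); "symmetric" lets both populations evolve under
# two-way migration. Returns population 2's final frequency (first strain).
run_two_pop <- function(mode, c = NULL, t = NULL, a = NULL, b = NULL,
                        m, source, horizon, scheme) {
  pinned <- scheme == "mainland_island"
  if (mode == "unidirectional") {
    p1 <- source
    p2 <- 0
    for (g in seq_len(horizon)) {
      q1 <- if (pinned) source else (1 - m) * p1 + m * p2
      q2 <- (1 - m) * p2 + m * p1
      n1 <- if (pinned) source else q1 * t / (1 - c * q1 * (1 - t * q1))
      n2 <- q2 * t / (1 - c * q2 * (1 - t * q2))
      if (abs(n1 - p1) < 1e-13 && abs(n2 - p2) < 1e-13) {
        return(n2)
      }
      p1 <- n1
      p2 <- n2
    }
    p2
  } else {
    # strain A resident in population 1 at `source`, strain B in population 2
    x1 <- source; y1 <- 0
    x2 <- 0; y2 <- source
    for (g in seq_len(horizon)) {
      qx1 <- (1 - m) * x1 + m * x2; qy1 <- (1 - m) * y1 + m * y2
      qx2 <- (1 - m) * x2 + m * x1; qy2 <- (1 - m) * y2 + m * y1
      if (pinned) { qx1 <- source; qy1 <- 0 }
      n1 <- if (pinned) c(source, 0) else bidi_repro(qx1, qy1, a, b, t)
      n2 <- bidi_repro(qx2, qy2, a, b, t)
      if (max(abs(n1[1] - x1), abs(n1[2] - y1),
              abs(n2[1] - x2), abs(n2[2] - y2)) < 1e-13) {
        return(n2[1])
      }
      x1 <- n1[1]; y1 <- n1[2]
      x2 <- n2[1]; y2 <- n2[2]
    }
    x2
  }
}

#' Locate the critical migration rate by bisection
#'
#' Finds the invasion threshold of the two-population CI recursion: the
#' migration rate above which the focal strain crosses population 2's
#' unstable equilibrium and spreads. Unidirectional runs start from
#' (stable equilibrium, uninfected); bidirectional runs start with strain A
#' resident in population 1 and strain B in population 2, and track strain
#' A's frequency in population 2 against its within-population unstable point
#' `b / (a + b)`.
#'
#' Two migration schemes are available. `"mainland_island"` (default) pins
#' population 1 at its resident equilibrium — the configuration under which
#' the closed forms [unidirectional_mk()] and [bidirectional_mk()] are exact
#' saddle-node thresholds, making it the validation oracle for them.
#' `"symmetric"` lets both populations evolve under two-way migration; its
#' thresholds are never below the mainland-island values (the closed forms
#' are lower bounds) and exceed them appreciably only near the bistability
#' boundary and for near-symmetric bidirectional CI.
#'
#' @inheritParams dynamics_params
#' @param m_range Bisection bracket for the migration rate.
#' @param tol Bisection tolerance on `m`.
#' @param horizon Maximum generations per trajectory (an early exit triggers
#'   when per-generation change falls below 1e-13).
#' @param scheme `"mainland_island"` or `"symmetric"` (see Details).
#'
#' @return The critical migration rate (bracket midpoint at tolerance).
#' @export
#' @examples
#' find_critical_migration("unidirectional", c = 0.8, t = 0.99)
#' unidirectional_mk(0.8, 0.99)
find_critical_migration <- function(mode = c("unidirectional", "bidirectional"),
                                    c = NULL, t = NULL, a = NULL, b = NULL,
                                    m_range = c(0, 0.5), tol = 1e-6,
                                    horizon = 10000L,
                                    scheme = c("mainland_island", "symmetric")) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  if (!is.numeric(m_range) || length(m_range) != 2L || m_range[1] < 0 ||
      m_range[2] > 0.5 || m_range[1] >= m_range[2]) {
    stop_invalid_parameter("`m_range` must be an increasing bracket within [0, 0.5]")
  }
  params <- dynamics_params(mode, c = c, t = t, m = 0, a = a, b = b)
  if (mode == "unidirectional") {
    eq <- stable_unstable_equilibria(params$c, params$t) # errors if no bistability
    source <- eq[["stable"]]
    threshold <- eq[["unstable"]]
  } else {
    if (!is.null(t) && t != 1) {
      stop_invalid_parameter(
        "bidirectional threshold search assumes perfect transmission (t = 1)")
    }
    if (params$a + params$b == 0) stop_no_threshold("both CI levels are zero")
    source <- 1
    threshold <- params$b / (params$a + params$b)
  }
  # Shave the classifier inward by a hair: near-critical trajectories approach
  # the threshold asymptotically from below. A zero threshold (perfect
  # transmission) needs a strict comparison instead.
  eps <- min(1e-9, threshold / 2)
  classify <- function(m) {
    run_two_pop(mode, c = params$c, t = params$t, a = params$a, b = params$b,
                m = m, source = source, horizon = horizon, scheme = scheme) >
      threshold - eps
  }
  lo <- m_range[1]
  hi <- m_range[2]
  if (classify(lo) || !classify(hi)) {
    stop_no_threshold(sprintf(
      "no invasion threshold inside [%g, %g]: trajectory class is the same at both brackets",
      lo, hi))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (classify(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Scan closed-form critical migration rates against the simulation oracle
#'
#' Evaluates [unidirectional_mk()] on a (c, t) grid and compares each value
#' with the bifurcation point located by [find_critical_migration()].
#'
#' @param c_values,t_values Numeric grids of CI strengths and transmission
#'   rates.
#' @inheritParams find_critical_migration
#'
#' @return Data.frame with columns `c`, `t`, `closed_form`, `m_crit`
#'   (simulated), `rel_error`.
#' @export
mk_oracle_scan <- function(c_values, t_values, tol = 1e-6, horizon = 10000L,
                           scheme = c("mainland_island", "symmetric")) {
  scheme <- match.arg(scheme)
  grid <- expand.grid(c = c_values, t = t_values, KEEP.OUT.ATTRS = FALSE)
  grid$closed_form <- mapply(unidirectional_mk, grid$c, grid$t)
  grid$m_crit <- mapply(function(cc, tt) {
    find_critical_migration("unidirectional", c = cc, t = tt, tol = tol,
                            horizon = horizon, scheme = scheme)
  }, grid$c, grid$t)
  grid$rel_error <- abs(grid$closed_form - grid$m_crit) / grid$m_crit
  grid
}
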