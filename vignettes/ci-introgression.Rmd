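---
title: "Coupling cytoplasmic incompatibility with host reproductive isolation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling cytoplasmic incompatibility with host reproductive isolation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciflow)
```

## The question

Maternally inherited endosymbionts such as *Wolbachia* cause cytoplasmic
incompatibility (CI): crosses between an infected male and a female lacking
his strain produce inviable embryos. After secondary contact between host
populations fixed for different infection states, CI alone rarely preserves
the difference — above a critical migration rate $m_k$ the strain simply
introgresses. Whether it does depends on how strongly CI is *coupled* with
the host's own isolating barriers: phenological (allochronic) isolation,
mate choice, and postmating incompatibilities, which jointly depress the
effective gene flow $p(GH)$ between the populations.

`ciflow` implements this comparison for the North American cherry fly system
(*Rhagoletis cingulata* / *R. indifferens*), where southwestern (SW)
populations carry a second *Wolbachia* strain (wCin3) absent from Pacific
Northwest (PNW) and eastern (ENA) populations, and SW males sire hybrid
crosses with strongly reduced egg hatch. The package estimates each barrier
from assay tables, composes them into $p(GH)$, evaluates $m_k$ in closed
form, and verifies those closed forms with an explicit two-population
simulator.

## Barrier estimates

**Allochronic isolation.** Each fly eclosing on day $e$ is taken to be
sexually active on days $e + 7$ through $e + w$ inclusive, with $w = 15$ or
$30$: flies need about a week posteclosion to mature, and adult survival
spans roughly 15-30 days depending on temperature. With $x_i$, $y_i$ the
proportions of each population's flies active on day $i$,

$$AI = \left(1 - \frac{\sum_i x_i y_i}{\sqrt{\sum_i x_i^2 \sum_i y_i^2}}\right) \times 100,$$

a cosine dissimilarity in percent: 0 for identical phenologies, 100 for
disjoint ones, symmetric, and invariant to rescaling either profile (so no
normalization is enforced beyond zero-padded alignment on the union day
grid). Day grids are integer-valued and window endpoints inclusive (7-15
means nine active days), the plain reading of the experimental protocol.
Note the index is *not* monotone in window width in general; for these
populations the shorter lifespan does give uniformly higher AI, which the
test suite asserts on the reconstructions.

**Sexual isolation.** From pooled no-choice trials, $SI = 1 - 2H/(H+C)$ with
$H$ hybrid and $C$ parental copulations: 1 is complete isolation, 0 random
mating, $-1$ uniform heterotypic preference. Reciprocal hybrid directions are
pooled into $H$ and both parental types into $C$, giving one index per pair;
per-hour rates are available when assays differ in observation time
(`use_rates = TRUE`), raw counts are the default. The premating contribution
to gene flow is the inverse map $(1 - SI)/2$.

**CI strength.** From cage-level egg-hatch data, each (maternal, paternal)
direction gets the unweighted mean across cages of the per-cage hatch
proportion — the experiment's unit of replication is the cage, not the egg —
after excluding cages with fewer than 10 eggs (unmated females lay small
numbers of unfertilized eggs; the threshold controls for them). CI strength
is the relative reduction $c = 1 - \text{hybrid}/\text{parental}$. Sampling
noise can make $c$ negative; it is reported with a warning, never clamped,
so that downstream users see the data as they are. Fecundity (eggs per
female per day, single-pair cages only) is summarized for completeness but
enters no downstream calculation.

## Coupling and the verdict

Barriers compound multiplicatively against a panmictic baseline
$m_0 = 0.5$:

$$p(GH) = \big[m_0\,(1 - AI/100)\big] \cdot \frac{1 - SI}{2}.$$

This is the composition used in the source analysis, reproduced here exactly
as printed (it recovers the published products $0.00215 \times 0.295 =
6.342\times10^{-4}$ and $0.0175 \times 0.295 = 5.163\times10^{-3}$ for
SW-PNW). A caveat worth knowing: with both barriers absent the expression
evaluates to $m_0/2 = 0.25$ rather than the stated baseline $0.5$, because
$(1-SI)/2$ equals $1/2$ at random mating. We deliberately implement the
printed form rather than "correcting" it — the verdicts compare $p(GH)$
spanning $10^{-4}$-$10^{-2}$ against thresholds spanning
$10^{-5}$-$10^{-3}$, so a factor of two does not change any qualitative
conclusion, and fidelity to the published worked examples is the more
valuable property.

The verdict is the threshold comparison: introgress if $p(GH) > m_k$,
retained if smaller, indeterminate within an absolute tolerance of
$10^{-12}$ (far below the scale of either quantity; equality essentially
never arises except in constructed examples).

## CI frequency dynamics and the closed-form thresholds

The single-population recursion for infection frequency $p$ with CI strength
$c$ and maternal transmission $t$ (no fitness costs, deterministic,
infinite population) is

$$p' = \frac{pt}{1 - c\,p\,(1 - t\,p)}:$$

infected mothers transmit to a fraction $t$ of eggs, and uninfected eggs
die with probability $c$ when sired by an infected male (frequency $p$).
Interior fixed points solve $ctp^2 - cp + (1-t) = 0$; when
$c \ge 4t(1-t)$ the larger root is the stable high-infection state and the
smaller the unstable invasion threshold (bistability). With $t = 1$ the
pair degenerates to $(1, 0)$ and any introduction spreads.

For two populations exchanging migrants at rate $m$ per generation
(migration first, then reproduction — the census order matters slightly for
threshold values and is fixed and documented), the infection polymorphism
survives only below a critical rate. Two mechanisms destroy it, and each
yields an exact saddle-node condition when the partner population is held
at its resident equilibrium:

* **Retention failure** — uninfected immigrants dilute the infected
  population until its high equilibrium vanishes:
  $m = \dfrac{c - 4t(1-t)}{4t^2}$.
* **Invasion** — infected immigrants push the uninfected population past
  its unstable threshold:
  $m = \dfrac{4ct\,(1-\sqrt{t})^2}{\big(c + \sqrt{c^2 - 4ct(1-t)}\big)^2}$.

`unidirectional_mk()` returns the minimum of the two. The invasion branch
comes from a pleasant algebraic fact: the island's fixed-point equation with
immigration from a source at equilibrium is a cubic that always has the
source equilibrium as a root, so the remaining quadratic's discriminant
gives the fold in closed form.

For bidirectional CI (each population fixed for a different strain, CI
levels $a \ge b$, perfect transmission) the same construction for a
population resisting immigrants carrying the stronger strain gives

$$m_k = \frac{2(a+b) - ab - 2\sqrt{(a+b)^2 - a^2b - ab^2}}{a^2},$$

implemented in `bidirectional_mk()`. The two-strain recursion assumes no
double infections; an egg not carrying the sire's strain dies with
probability equal to that strain's CI level, and uninfected eggs are
vulnerable to both.

### Oracle validation and the migration scheme

Because typeset radicals are fragile, both closed forms are validated
against an independent numerical oracle: bisection (tolerance $10^{-6}$ on
$m$, horizon $10^4$ generations, early exit when per-generation change drops
below $10^{-13}$) on the classifier "population 2 ends above its unstable
equilibrium", starting from (resident equilibrium, uninfected) or (strain A
resident, strain B resident). The classifier is shaved inward by $10^{-9}$
because near-critical trajectories approach the threshold from below; with
perfect transmission the unstable point is 0 and the comparison is strict.

`find_critical_migration()` offers two migration schemes, and the
distinction is a genuine modeling point rather than a numerical detail:

* `"mainland_island"` (default) pins population 1 at its resident state.
  This is the configuration under which the closed forms are *exact*: the
  oracle reproduces them to bisection tolerance across the full
  $(c, t)$ grid and at bidirectional $(1, 1)$ and $(1, 0.5)$. It is also the
  natural reading of the thresholds as conservative *lower bounds* — a
  mainland that never degrades exerts maximal immigrant pressure.
* `"symmetric"` lets both populations evolve under two-way migration. Its
  thresholds are never below the mainland-island values. The bound is tight
  (within a few percent) away from degenerate regions, but loosens near the
  bistability fold $c \approx 4t(1-t)$ (about 13% at $c = 0.5$,
  $t = 0.875$) and qualitatively changes character for near-symmetric
  bidirectional CI: at $a = b$ the symmetric system loses its asymmetric
  equilibria through a pitchfork at a distinctly higher rate (0.25 at
  $a = b = 1$ versus the bound's $3 - 2\sqrt{2} \approx 0.172$).

The test suite validates the closed forms against the mainland-island
oracle and separately asserts the lower-bound relation to the symmetric
recursion on both sides of the tight/loose divide.

```{r mk, eval = FALSE}
unidirectional_mk(0.8, 0.99)                      # 3.19e-05 (closed form)
find_critical_migration("unidirectional",
                        c = 0.8, t = 0.99)        # same, by bisection
find_critical_migration("unidirectional", c = 0.8,
                        t = 0.99, scheme = "symmetric") # slightly above
```

## What the synthetic generators emulate — and what they do not

No raw assay tables ship with the package; seeded generators reproduce the
*statistical structure* the estimators assume, at the published study
conditions, so that every stage is testable end to end.

* **Eclosion** (`gen_eclosion()`): normal truncated at zero, rounded to
  whole days, parameterized by published means, standard errors and sample
  sizes (SD recovered once as $SE\sqrt{n}$ at model construction: PNW
  $30.68 \pm 0.41$, $n = 289$; ENA $40.82 \pm 0.51$, $n = 71$; SW
  $64.55 \pm 0.23$, $n = 579$). Real eclosion curves are typically
  right-skewed; normality is a declared stand-in, not an inference, since
  only first and second moments are published. Consequently reconstructed
  AI values carry a systematic offset of a couple of percentage points for
  the intermediate pairs (ENA-SW reconstructs near 84 against a published
  86.5; ENA-PNW near 26 against 28.5) while the near-saturated pairs match
  closely (PNW-SW: 96.5 at the 30-day window, 99.8 vs 99.6 at 15 days).
  Passing tests therefore certify the estimators and the pipeline, not the
  shape of real phenologies.
* **Mating trials** (`gen_mating_trials()`): the hybrid share of a fixed
  number of copulations is binomial with probability $(1-SI)/2$ at the
  published indices (0.41 SW-PNW, 0.39 SW-ENA); 200 matings over 100 h is a
  realistic no-choice assay scale (the source observed a minimum of 21.5 h
  per assay; counts are not published).
* **Crosses** (`gen_crosses()`): per cage, daily egg output is Poisson
  (2.5 eggs per female per day, matching observed fecundities of 1-3),
  accumulated until the cage exceeds 100 eggs or 28 days elapse — the
  experiment's stopping rule. Hatch is binomial at the parental rate
  (0.75, consistent with the published worked CI strengths) times $(1-c)$
  for hybrid crosses, with $c = 0.800$ (PNW female x SW male) and $0.738$
  (ENA female x SW male). An unfertilized-egg background is exposed as a
  parameter but defaults to 0 (unquantified in the source). Hatch
  probability is cage-size independent (the source pools cage sizes).
  With 40 cages per arm the design CI strength is recovered within 0.05.
* **Infection surveys** (`gen_infection_survey()`): multinomial over
  {wCin2-only, wCin3-only, doubly infected} per population. Survey tables
  are round-tripped through the I/O layer but do not feed the verdict;
  strain-frequency-to-transmission mapping is deliberately not formalized
  ($t$ stays a free input, scanned over 0.875 and 0.99 — the low value
  motivated by observed single-fly strain losses in survey data, the high
  one by typical insect vertical transmission).

All generators restore the caller's RNG state and are byte-reproducible for
a fixed seed.

## Numerical and reporting choices

* Bisection bracket $[0, 0.5]$, absolute tolerance $10^{-6}$: at thresholds
  near $3\times10^{-5}$ this is ~2-3% relative resolution, within the 5%
  validation margin; horizon doubling shifts results by less than the
  tolerance (asserted), guarding against slow-transient misclassification.
* The pipeline (`run_pipeline()`) writes TSV (no quoting ambiguity; `#`
  comment headers carry the configuration MD5 hash) plus a JSON mirror of
  the verdict table; identical configurations give byte-identical bundles,
  and failed stages remove partial outputs.
* `scripts/acceptance.R` reports each pair's reconstructed AI as the mean
  over 25 independent seeded reconstructions at the published sample sizes.
  A single reconstruction has sampling SD up to ~2.7 AI points (driven by
  ENA's $n = 71$); the replicate mean reports the method's central estimate
  (SE ~0.5 point) rather than one noisy draw. Problem sizes: 25 replicates
  of 360-868 flies per pair, seconds of runtime.

## Limitations

* The verdict framework assumes either a pinned mainland or two symmetric
  demes; no spatially explicit or clinal hybrid-zone structure is modeled,
  so thresholds should be read as order-of-magnitude guides (the source
  makes the same caveat about its mainland-island assumption).
* Dynamics are deterministic and infinite-population: no drift, no host
  population dynamics, no fitness effects of infection.
* Statistical hypothesis testing on the assay tables (ANOVA,
  Kruskal-Wallis and post hoc procedures in the original analysis) is out
  of scope: it requires the raw data, and standard tools already exist.
* The bidirectional threshold search requires perfect transmission
  ($t = 1$), matching the closed form it validates; the two-strain
  recursion itself accepts $t < 1$.
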