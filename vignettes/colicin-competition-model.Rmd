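---
title: "A stochastic lattice model of colicin-mediated range-expansion competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic lattice model of colicin-mediated range-expansion competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colicinsim)
```

## The system

A colicin-producing *Escherichia coli* strain (C) competes with a
toxin-sensitive strain (S, generically X) on solid medium. The producer
strain divides labor: most cells reproduce, but each reproducing cell
stochastically switches into a toxin-producing state from which there is
no return — the producing cell synthesizes colicin and then lyses,
releasing the toxin. Released colicin growth-arrests nearby sensitive
cells permanently; arrested cells stop dividing but keep occupying their
space. The competition is therefore a race between spatial exclusion
(the sensitive strain starts at a 100:1 numerical advantage) and toxin
action, with the producer paying for its weapon in cells.

`colicinsim` implements this system as a kinetic Monte Carlo model on a
250 x 250 lattice with five site states (`AGAR`, `C`, `C_ON`, `X`,
`X_STOP`), together with the full downstream analysis: outcome
classification, edge-cluster statistics, spatial initial-condition
metrics, transition times, expansion-rate and growth-rate fits, and the
sequential-ANOVA linear models that relate initial conditions to the
final outcome.

## The update rule

Time advances in fixed steps `dt`. Each step visits every active site in
a freshly randomized order:

* a reproducing cell (`C` at rate `r_c`, `X` at `r_x`) replicates into a
  uniformly chosen empty Moore neighbour; each orthogonal empty
  neighbour contributes `r * dt` to the replication probability and each
  diagonal neighbour half of that (`diag_factor = 0.5`). The target is
  chosen uniformly among the empty neighbours once the rate draw
  succeeds;
* a `C` cell instead switches to `C_ON` with probability `s_c * dt`;
* a `C_ON` cell lyses with probability `d_con * dt`; its site reverts to
  recolonizable agar and the toxin field gains
  `n_tox * exp(-d / lambda_tox)` at every site at physical distance `d`;
* a living `X` cell is arrested with probability
  `1 - exp(-sigma_x * toxin * dt)` — the exact integrated probability of
  a constant hazard, so this transition imposes no constraint on `dt`.
  `X_STOP` is permanent and keeps occupying its site.

`C_ON` and `X_STOP` never replicate and never revert. The step size is
chosen per zoom level as the largest value that keeps every single-event
probability at or below `p_cap = 0.05` and divides the recording
interval; a user-supplied fixed `dt` is validated against the same cap at
construction. With a steady reproducing population the producer dynamics
`dCon/dt = s_c C - d_con Con` give the steady-state ratio
`Con/C = s_c/d_con` and producer fraction `s_c/(s_c + d_con)`;
`simulate_producer_pool()` verifies the stochastic implementation against
this closed form. The surrogate holds the reproducing pool constant
(replication exactly balances the switching loss); with replication
literally absent the ratio has no fixed point once `s_c >= d_con`, so the
constant-pool construction is the faithful reading of the steady-state
assumption.

## Coarse-graining ("zooming")

The inoculum is resolved at 2 um per pixel, so a mature millimetre-scale
colony cannot stay on a 250 x 250 lattice. Whenever the colony touches
the lattice border, every 5 x 5 block collapses to one site: blocks with
fewer than 13 of 25 sites occupied become agar, the rest take the
plurality occupied state (ties broken by the fixed precedence
`C_ON > C > X_STOP > X`); the 50 x 50 result is re-centred in a fresh
250 x 250 agar lattice, the toxin field is block-averaged, and the pixel
size grows by 5. Two zooms take the run from single cells to a ~5 mm
colony.

The reaction rates must be adjusted at a zoom event, and how is a
genuine design decision. Rescaling only the replication rates (divide by
5, preserving the front speed in um/h) seems natural but inflates the
switching cost per replication opportunity, `s_c / r`, by a factor of 5
at every zoom: in runs near the producer-fraction optimum the C
population visibly collapses immediately after the second zoom — an
artifact of the discretization, not a prediction of the model. We
therefore rescale all three agent rates (`r_c`, `r_x`, `s_c`, `d_con`)
by 1/5 together. This preserves the three dimensionless quantities the
biology cares about — front speed in physical units, producer fraction
`s_c/(s_c + d_con)`, and the per-division switching cost `s_c/r` — at
every scale. The toxin sensitivity `sigma_x` (a hazard per toxin unit
per hour) and the decay length in micrometres are left untouched;
`lambda_mode = "lattice"` optionally fixes the decay length in lattice
units instead (its physical reach then grows at each zoom), which we
expose for sensitivity analysis.

## Parameters, units and defaults

| parameter | default | meaning |
|---|---|---|
| `r_c`, `r_x` | 5.5 / h | replication rate per orthogonal empty neighbour |
| `s_c` | 1.2 / h | C to C_on switching rate (50% producers at default `d_con`) |
| `d_con` | 1.2 / h | lysis rate of producers (mean producing time 50 min) |
| `sigma_x` | 1500 | arrest hazard per toxin unit per hour |
| `n_tox` | 1.0 | toxin released per lysis |
| `lambda_tox` | 50 um | decay length of the deposited profile |
| `base_pixel_um` | 2 um | pixel size at zoom 0 (one pixel ~ one cell) |
| `p_cap` | 0.05 | per-step single-event probability cap |
| `t_end` | 48 h | competition duration |

Two calibrations anchor the defaults. First, `r = 5.5/h` at 2 um/pixel
makes unperturbed single-strain colonies reach ~4.9 mm diameter at 48 h,
the observed size of mature control colonies;
`calibrate_growth_rate()` re-derives this from any target area curve.
Second, the characteristic switching-rate scan
(`default_s_c_values()`, 0.06-9.3 per hour) is chosen so that producer
fractions span ~5% to ~89%: reference switching-rate tables for this
system are commonly printed in per-minute units, and we map them to the
package's per-hour rates by a factor of 60. Under this mapping the
producing lifetime is ~50-60 min, the scan brackets the experimentally
measured producer fractions (about 14.5% at low induction and 57.8%
under a synchronized response), and the C-success optimum falls at ~50%
producers — all three anchors are mutually consistent, whereas reading
the printed values as per-hour rates caps the attainable producer
fraction at ~11% and breaks the optimum.

Third, the toxin decay length. Colicins diffusing from a lysed cell on
agar act over an effective range of roughly 100-400 um. The quantity
that plays that role in the model is not the decay length itself: a
sensitive cell is arrested once `sigma_x` times its accumulated toxin
times its exposure time reaches order one, which happens out to about
`lambda_tox * log(sigma_x * n_tox * t)` — ten-ish decay lengths under
standard conditions. The default `lambda_tox = 50 um` therefore puts the
effective arrest distance near 480 um, at the upper edge of the cited
band. This choice matters qualitatively: decay lengths of 150 um would
give effective kill distances of well over a millimetre, arrest becomes
all-or-nothing at colony scale, partial outcomes (coexistence)
disappear, and the multistability the model exists to study is
suppressed. With the default, the simulations reproduce the expected
structure: S-strain domination and coexistence at low switching rates,
predominantly C-strain domination (with occasional S-domination and
coexistence) at ~50% producers, and extinction or S-domination beyond
the optimum.

## Scenarios

Besides the stochastic reference, `scenario()` selects:

* `all_off` — switching disabled; the C strain is an unarmed but
  otherwise identical competitor (the toxin-deficient control);
* `sync_I` — grow 50 min, pause 50 min, then every C cell releases its
  toxin at once; `sync_II` — grow 100 min, release immediately. These
  model the synchronized stress response at saturating induction;
  population-wide extinction at high producer fractions requires this
  synchrony;
* `non_lysing_all_on` — every C cell releases toxin upon replication
  without dying, at halved replication rate and halved toxin amount;
  the comparison shows the cost that obligatory lysis imposes.

## Per-run metrics

`classify_outcome()` applies the area classification: extinction first
(total occupied area below 1e6 um^2 — a trapped, tiny all-C colony is
extinct), then C domination (final C fraction above 0.9), S domination
(below 0.1), else coexistence. Arrested `X_STOP` sites count toward the
S-strain area: arrested cells still occupy space and fluoresce in the
experiments the model mirrors.

`count_edge_clusters()` computes the phase-1 summary statistic: the
number of 8-connected components of C-lineage sites that (a) contain at
least one reproducing `C` site — clusters of doomed producers are not
viable — and (b) touch the colony edge, defined as occupied sites with a
Moore neighbour in the external agar background (agar 4-connected to the
lattice border, so enclosed pockets do not count). It is evaluated on
the 12 h snapshot, the end of the stochastic initial phase.

`initial_spatial_metrics()` implements the centre-of-mass statistics of
the founder C cells: `r_c0` is the norm of the mean C position relative
to the colony centroid, and `d_c0` the mean Euclidean distance of C
cells from their own centre of mass. The printed form of the spread
statistic (the norm of the mean deviation vector) is identically zero;
we implement the mean distance, the only reading that measures spread,
and keep the literal form behind `literal = TRUE` for audit. A
mean-radial-distance variant of `r_c0` is available via `radial = TRUE`.

`expansion_rate()` and `growth_rate_from_od()` share one windowing rule:
the linear (or log-linear) regime is the window of at least 25% of the
series (and 6 points) maximizing the fit R^2, with near-ties resolved to
the longer window so an exactly linear regime is returned whole; if no
window reaches R^2 = 0.98 the curve has no linear regime and the fit
errors out rather than returning a meaningless slope. `transition_time()`
reports the first time C holds more than half of the colonized area
sustained for two further recordings — a debounce against
single-snapshot noise.

## Statistical models

`sequential_anova()` wraps the type-I (sequential) decomposition of
`stats::anova()` and adds eta-squared effect sizes
(`SS_term / SS_total`); term order follows the formula, or an explicit
`term_order`. Unit tests verify the decomposition against an independent
nested-model RSS oracle and its exactness (`sum of SS = total SS` to
1e-8 relative).

Three model surfaces mirror the study's analysis: `fit_nc_edge_model()`
(edge-cluster count on the standardized initial metrics and dose),
`fit_fc_model_experimental()` (final fraction on dose as a categorical
factor, the edge-cluster count and spatial metrics, with all pairwise
interactions, sequential order dose, edge clusters, cell count, spread,
radius, then interactions), and `fit_fc_model_simulation()` (final
fraction on switching rate, edge-cluster count and initial-condition
label, all categorical, with pairwise interactions). Categorical
predictors use treatment contrasts; sequential sums of squares are
contrast-invariant, individual coefficients are not. p-values are
reported without multiple-testing correction, matching the original
analysis. `fc_variance_over_time()` uses the population variance
convention (divide by n), documented and fixed.

## What the generators emulate — and what they do not

`generate_inoculum()` reproduces the acoustic spotting geometry: ~150
cells (times an optional 2/4/8 density multiplier) uniformly on distinct
sites of a centred 450 um disc, each cell a producer with probability
1/101, resampled until at least one C cell is present. It does not model
the coffee-stain inhomogeneity of dense experimental spots, positional
jitter of the droplet, or imaging noise; passing tests therefore
validate the model pipeline, not image-derived experimental tables.
`synthetic_od_curve()`, `synthetic_area_curve()` and
`synthetic_regression_table()` generate fixtures with stored ground
truth for the fitting and ANOVA stages; their noise is lognormal
(multiplicative) for curves and Gaussian for regression responses.

## Numerical choices

* Random-sequential updating with a hard per-event probability cap
  (0.05) rather than event-driven simulation: convergent to the same
  rates, and the exponential-lifetime and steady-state checks in the
  test suite validate the discretization.
* Toxin deposition is truncated where a single event's contribution
  falls below `tox_cutoff = 1e-10` toxin units; with `sigma_x = 1500`
  and 48 h of exposure the neglected hazard is orders of magnitude below
  one event.
* All kernel randomness flows through R's RNG, so one `set.seed()` (or
  the `seed` argument) makes a run bit-reproducible; campaign seeds
  derive from a master seed by a fixed 31-bit hash (`derive_seed()`).
* Replication targets are drawn uniformly among empty Moore neighbours
  after the rate draw; the diagonal down-weighting lives in the rate
  only.

## Problem sizes used in the checks

The packaged test-suite runs the full study conditions where they are
cheap (48 replicates for outcome-distribution comparisons, 100
replicates for the neutral-drift check, 30 per density for the variance
trend) and desk scales elsewhere (the analysis drivers under
`analysis/` default to 4-12 replicates per condition and reduced design
grids; each driver states its scale). The fixed-IC ANOVA driver pools
edge-cluster counts above 3 into one level so every factor level stays
populated at small replicate counts.

## Known limitations

* The inoculation-density trend is only partially reproduced. The
  across-replicate variance of the C-fraction dynamics falls from the
  standard density to twice it, as expected if denser inocula average
  over early stochasticity, but at 4- and 8-fold density
  extinction-by-entrapment — viable C clusters sealed inside arrested S
  before the colony clears the extinction area threshold — becomes more
  frequent and re-inflates the variance. The monotone decline this
  statistic shows in plate experiments is not matched by the lattice
  model at high density, and the corresponding check in the test suite
  records that fact rather than hiding it.

* No explicit toxin diffusion or decay: deposition is instantaneous,
  static and additive, as in the lattice models this one descends from.
* No nutrient field, no off-lattice mechanics, no mutation or
  resistance evolution; resistant competitors are modelled simply as
  `sigma_x = 0`.
* The coarse-grained late-stage colony is a mean-field caricature of
  micro-scale structure; statements about single-cell-scale features are
  only meaningful before the first zoom.
* Experimental image segmentation is out of scope; all metrics are
  computed directly on simulated lattices.
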