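---
title: "A stochastic fire–beetle model of age-structured pine stands"
author: "firebeetle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic fire–beetle model of age-structured pine stands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system being modelled

Lodgepole and ponderosa pine stands in western North America are shaped by
two interacting disturbances: mountain pine beetle (MPB, *Dendroctonus
ponderosae*) outbreaks, which kill mature trees, and wildfire, which kills
trees of every age. Because beetles cannot effectively infest small-diameter
stems, the stand's *age structure* mediates the interaction: fire removes
mature trees and opens space for even-aged juvenile cohorts, and those
cohorts, when they mature decades later in near synchrony, fuel the next
beetle outbreak. `firebeetle` implements a discrete-time (annual),
well-mixed, single-stand model of this loop, together with two management
protocols that deliberately roughen the age structure.

## State variables and the annual map

A stand holds a fixed total of `T` *tree-equivalents* — a live tree, a
standing dead snag, or a canopy gap where a seedling will establish. The
state in spring of year $n$ is

* $j_{n,k}$, juveniles in age class $k = 1, \dots, K$ (one class per year),
* $S_n$, susceptible (mature) trees,
* $I_n$, trees infested during year $n$ (they pass through a red-snag and a
  grey-snag year, so $I_{n-1}$ and $I_{n-2}$ are carried as lags),
* $F_n$, trees burned in year $n$.

Fire severity is limited by fuel memory. With burn history $F_1, \dots,
F_n$ and fuel decay rate $\kappa$,

$$P_n = \max\!\Big(0,\; T - \sum_{i\le n} F_i\, e^{-\kappa (n-i)}\Big),$$

so a stand that burned recently has little left to burn ($P$ is computed by
`fire_severity()`; the simulator maintains the sum recursively, which is
exact). The annual update is

$$
\begin{aligned}
j_{n+1,1} &= d\,J_n + I_{n-2} + F_n,\\
j_{n+1,k} &= \Big[(1-d) - \tfrac{\alpha_1}{T}P_n\Big] j_{n,k-1},
  \qquad k = 2,\dots,K,\\
S_{n+1} &= M_n - \Big(I_n + \tfrac{\alpha_2}{T}P_n I_n\Big)
  - \tfrac{\alpha_2}{T}P_n M_n - \sigma_F\gamma_n,
  \qquad M_n = S_n + (1-d)\,j_{n,K},\\
I_{n+1} &= r_1 I_n\, e^{-\beta_1 (T - S_{n+1})}
  - \tfrac{\alpha_2}{T}P_n I_n + \sigma_I\xi_n,\\
F_{n+1} &= P_n\Big[\tfrac{\alpha_1}{T}\textstyle\sum_{k<K} j_{n,k}
  + \tfrac{\alpha_2}{T}M_n + \tfrac{\alpha_2}{T}I_n\Big] + \sigma_F\gamma_n,
\end{aligned}
$$

with $J_n = \sum_k j_{n,k}$. Infestation follows Ricker-type growth damped
by host scarcity (the $e^{-\beta_1 (T-S)}$ search-failure factor);
dead juveniles, decayed grey snags and last year's burns all reopen ground
for seedlings. $\xi_n$ and $\gamma_n$ are independent standard-normal draws;
the *same* $\gamma_n$ is debited from $S$ and credited to $F$, so fire noise
transfers trees rather than creating them.

In deterministic mode ($\sigma_F = \sigma_I = 0$) the map conserves
tree-equivalents exactly:

$$T = I_{n-1} + I_{n-2} + F_n + J_n + S_n \quad\text{for every } n,$$

which the test suite verifies to relative $10^{-9}$ over millennia-long
runs (it holds to rounding error, $\sim 10^{-14}$). The infestation noise
$\sigma_I\xi_n$ has no compensating loss elsewhere, so stochastic runs
conserve only on average; `fb_params(strict_noise_balance = TRUE)` debits
that term from $S$ for users who want exact conservation with noise on. The
default implements the equations literally.

## Parameters

| symbol | argument | default | meaning |
|---|---|---|---|
| $r_1$ | `r1` | 1.8 | yearly beetle fecundity |
| $\beta_1$ | `beta1` | $10.8\times10^{-6}$ /tree | beetle search-failure rate |
| $d$ | `d` | 0.01 | annual juvenile mortality |
| $\alpha_1$ | `alpha1` | 0.02 | burning rate of juveniles |
| $\alpha_2$ | `alpha2` | 0.0025 | burning rate of adults |
| $\kappa$ | `kappa` | 0.1 /yr | fuel decay rate |
| $T$ | `T` | 110000 | stand size (tree-equivalents) |
| $K$ | `K` | 50 | juvenile age classes |
| $\sigma_F,\sigma_I$ | `sigma_F`, `sigma_I` | 20 trees | environmental noise |

The burning rates are the regime-controlling knobs; everything else is held
at the ecologically anchored defaults above. Two operating points recur
throughout the package: $(\alpha_1,\alpha_2) = (0.02, 0.0025)$, a regime of
recurrent beetle outbreaks, and $(0.01, 0.006)$, where fire already dampens
the beetle. They are also available as deterministic reference runs via
`make_fixture()`.

## Initial condition and burn-in

The update map needs a year-0 state that no published table fixes. The
package seeds 4% of the stand uniformly across the juvenile classes
(`j0_frac = 0.04`), 100 currently infested trees (`I0`), empty snag lags
and burn history, and puts the remaining 96% of the stand in the
susceptible pool — chosen so the conservation identity holds exactly from
the first year. All analyses discard a 1500-year burn-in (`burn_in`) and
summarise a 500-year window (`horizon`), long enough that the equilibrium
statistics are insensitive to the seed state. Both knobs are ordinary
parameters and appear in the YAML config schema.

## Noise, clamping and numerical choices

* Negative excursions caused by noise ($\sigma \approx 20$ trees against
  populations of $10^3$–$10^5$) are clamped at zero after each step; the
  count of clamp events is reported as `attr(traj, "n_clamped")`. In
  deterministic mode no clamp ever fires at the regimes studied (asserted
  in the tests).
* $P_n$ is clamped at 0: severity cannot be negative after extreme burn
  sequences.
* The reference R step function truncates the burn history once kernel
  weights fall below $10^{-12}$, so memory stays $O(1)$; the compiled loop
  uses the algebraically identical recursion
  $D_{n+1} = D_n e^{-\kappa} + F_{n+1}$.
* Populations are continuous (real-valued trees), matching the
  difference-equation formulation; nothing is rounded to integers.
* One seedable RNG stream drives each realization, with a fixed per-year
  draw order ($\xi_n$ then $\gamma_n$), so a seed reproduces a trajectory
  bit-for-bit across platforms.

## Management protocols

`fb_policy()` describes the two interventions, applied every `period` years
(years are counted from the start of the run, so equilibria reflect
sustained management):

* **FTP** (forest thinning protocol): after the juvenile vector advances,
  the `m` most-populated age classes are each thinned by the fraction
  `tau`, and the removed trees re-enter the seedling class.
* **CBP** (controlled burning protocol): identical removal, but the trees
  are diverted to the burned compartment (and hence into the fuel-memory
  kernel as ordinary burned material).

Selection (`select_classes()`) maximizes the treated population — the `m`
largest classes — breaking ties toward the *oldest* class, since management
targets old, large cohorts. Two design points deserve a note:

* *What gets thinned.* The removal term
  $\tau\big[(1-d) - \tfrac{\alpha_1}{T}P_n\big]j_{n,k'-1}$ equals $\tau$
  times the pre-control year-$(n{+}1)$ population of class $k'$, so the
  package advances the vector first and then thins the selected classes of
  the advanced vector — "remove a fraction $\tau$ of the trees standing in
  the largest classes". The alternative reading (select on the year-$n$
  vector and scale the *inflow* into selected classes) lets a traveling
  even-aged cohort stay one step ahead of the treatment forever; it
  produces a spatially flat ~27% outbreak reduction across the whole
  burning-rate plane, erasing the strong small-$\alpha_1$ gradient that the
  chosen reading produces and that motivates thinning in the first place.
* *The seedling class.* The youngest class only receives material (there is
  no thinning equation for it); if it is among the `m` largest it is
  selected but nothing is removed from it.

Either protocol only redistributes tree-equivalents; the conservation
identity survives management, which the tests check along whole managed
runs, including $\tau = 1$ and quinquennial schedules.

Mechanistically, thinning erodes the even-aged bump before it reaches
maturity: under FTP at the outbreak operating point the temporal
coefficient of variation of the maturation flux $(1-d)j_{n,K}$ roughly
halves, and peak outbreak sizes drop by about a third, even though the
*average* susceptible population barely changes — the point of the
protocol is heterogeneity, not host removal.

## Trajectory summaries

`fb_summarize()` reports, over the final `window` years: the largest
infested population (`max_I`), the largest fire season (`max_F`), the mean
susceptible population, and dominant periods. `dominant_period()` removes
the series mean, takes the plain DFT (bins $k/N$, no padding, no taper),
and returns $N/k^\*$ where $k^\*$ is the maximum-modulus bin over
$1 \le k \le N/2$; ties break toward the lowest frequency. A run whose
susceptible series has range below `steady_band` (default $10^{-3}T$, i.e.
110 trees — no published number exists, so the band is exposed as a
parameter and the regimes analysed here are insensitive to it) is
classified as a stochastic steady state and reports period 1. Both the
period and its reciprocal frequency are returned, so either plotting
convention is available.

`fb_ensemble()` averages replicate summaries; periods are averaged on the
*frequency* scale (steady replicates contribute frequency 1) and the mean
frequency is inverted back to a period, which behaves sensibly when some
replicates are steady and others cycle.

## Sweeps, seeding and paired comparisons

`fb_sweep()` crosses an $(\alpha_1, \alpha_2)$ grid with a list of
policies. Replicate seeds come from a fixed integer hash of
`(seed_base, i1, i2, rep)` — the cell's grid coordinates and replicate
index only — with two consequences: results are independent of evaluation
order, and all policies at a cell share noise realizations (common random
numbers), which sharply reduces the Monte-Carlo variance of the
percent-change columns without biasing ensemble means. A diverging cell is
flagged (`ok = FALSE`) rather than aborting the sweep. Percent changes are
relative to the `none` policy at the same cell and are `NA` (never
infinite) where the baseline is zero.

Default grid extents ($\alpha_1 \in [0, 0.03]$, $\alpha_2 \in [0, 0.008]$)
bracket both operating points above.

## What the tests do and do not show

All test inputs are generated by the model itself — there is no external
data. The suite therefore demonstrates internal correctness (oracle
equivalence of the compiled loop, the R step map and an independent naive
transcription; conservation; DFT argmax against a direct $O(N^2)$ sum;
brute-force subset selection) and the model's qualitative regime structure
(fires grow and outbreaks shrink along the burning-rate diagonal; FTP
always reduces peak outbreaks; CBP backfires where beetles are already
scarce). It does not validate the model against field observations of any
real stand: the noise is Gaussian and annual, fire has no spatial spread or
weather driver, beetle phenology has no temperature dependence, and snags
are not burnable material.

Problem sizes used by the checked-in analyses: single runs use the default
1500 + 500 years; paired policy contrasts use 100 replicates at the two
operating points; parameter-plane experiments use a 5×11 (tests) or 5×6
(acceptance script) grid with 50 paired replicates per cell and policy.
Ensemble standard errors at those sizes are a few percent of the means.

## Known limitations

* The Ricker infestation term can momentarily exceed available hosts for
  aggressive, unrealistic parameter combinations (very small $\beta_1 T$),
  where clamping then breaks exact conservation; the regime box used in
  the property tests documents where the model is well-behaved.
* Period estimates are quantized to $N/k$; a 500-year window cannot
  distinguish, say, a 38.5-year from a 41.7-year cycle.
* `dominant_period()` reports the maximum-modulus bin, not a spectral
  density estimate; no confidence interval beyond the ensemble SE of the
  frequency is attempted.

## A short session

```{r}
library(firebeetle)

p <- fb_params(alpha1 = 0.02, alpha2 = 0.0025)
tr <- fb_simulate(p, seed = 1, keep_ages = TRUE)
fb_summarize(tr)
plot(tr)

ftp <- fb_policy("ftp", tau = 0.15, m = 8)
fb_ensemble(p, ftp, n_reps = 100, seed_base = 1)

sw <- fb_sweep(seq(0.002, 0.03, length.out = 5),
               seq(0.0005, 0.008, length.out = 6),
               policies = list(fb_policy("none"), ftp), n_reps = 50)
plot(sw, field = "pct_change_max_I", policy = "ftp_tau0.15_m8_p1")
```
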