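---
title: "Private mobility matrices: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Private mobility matrices: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privmob)
```

## The problem

Daily origin-destination (O-D) matrices built from call detail records
(CDR) summarise population movement between administrative regions:
cell (i, j) counts the trips from region i to region j on one day, where
a trip is a subscriber producing an event in one region and their next
event in a different one. These matrices drive two classes of
humanitarian decision supported here: threshold-triggered
non-pharmaceutical interventions in an epidemic, and geographic targeting
of aid after a disaster. Because even aggregated counts leak individual
travel, `privmob` releases the matrices under ε-differential privacy and
quantifies what the privatization costs each downstream decision.

## The release mechanism

For privacy parameters (ε, T, τ):

1. **Censoring** (individual-level protection only). Each subscriber with
   θ > T trips keeps T of them, chosen uniformly without replacement.
   After censoring, adding or removing one *person* changes any release by
   at most T — the sensitivity the noise is calibrated to. With T = 1 the
   protected unit is a single trip and censoring is unnecessary.
2. **Noising.** Independent Laplace noise with scale T/ε is added to every
   off-diagonal cell. The noise standard deviation is T√2/ε.
3. **Thresholding.** If a noised cell falls strictly below τ it is
   *suppressed*: released as 0 and flagged, so consumers can distinguish
   "zero" from "withheld" while sums treat both as 0. Otherwise the value
   is rounded half-up to an integer and clamped at τ.

Consequences, all property-tested: released values are non-negative
integers, no value in (0, τ) is ever published, and — less intuitively —
a truly-below-τ cell is *more* likely to clear the threshold at small ε
(heavier noise tails), which makes windows of small counts more accurate
at ε = 0.1 than at ε = 1 in total even though each cell is noisier.

The step-3 semantics (suppress strictly below τ; round half-up; clamp)
are a design choice of this package — thresholding rules of this kind are
usually stated only loosely — and the suppress-to-zero-and-flag
convention was chosen so that downstream consumers never mistake
suppression for an observed zero.
The ε-DP guarantee is checked empirically by `audit_dp_mechanism()`:
under trip-level protection a one-trip change moves exactly one cell by
1 with all other cells distributionally identical, so the audit runs the
single-cell mechanism on neighboring counts c and c + 1 and bounds the
log-ratio of the empirical output histograms. At 10⁶ runs per arm the
bound is checked to within three binomial standard errors on the worst
output category; categories with fewer than 25 tallies in either arm are
excluded because their ratios measure Monte-Carlo noise, not the
mechanism.

## Choosing ε and τ

Two calculators, both exact closed forms:

* **Heuristic** (`heuristic_epsilon_for_error`): require the noise
  standard deviation T√2/ε to stay below an error tolerance α (trips),
  giving ε ≥ √2·T/α. Tolerances of 10 and 50 trips give ε of 0.1414 and
  0.0283.
* **Tail bound** (`epsilon_for_error_bound`): require
  P(|released − true| > α) ≤ δ for a non-suppressed cell. With rounding
  contributing up to half a unit, a Laplace(T/ε) tail gives
  ε ≥ −T·ln(δ)/(α + ½); at α = 10, δ = 0.05 this is 0.2853. The bound
  admits a *larger* ε than the heuristic for the same α because it uses
  the whole tail rather than the second moment. The (α + ½) term charges
  the integer rounding to the error budget; the form is validated by a
  Monte-Carlo tail-frequency oracle in the test suite (the empirical
  exceedance frequency at the returned ε stays at or below δ).

For τ, an organization with an existing suppression standard s (e.g. the
CDC's 15) can keep τ = s (the noise is mean-zero), lower it to
s − √2/ε to minimize suppression (data minimization does the protecting),
or raise it to s + √2/ε so noise is unlikely to surface small
sub-populations. Results are rounded half-up and floored at 0.

## Privacy accounting

Composition is linear. Trip-level: an individual's loss over releases
j = 1..J is ε·Σ n_j with n_j their trips in release j — the worst case
uses the maximum over individuals, the expected case
(`expected_privacy_loss`) the population mean (ε = 0.5 with a mean of 14
trips over a 305-day window gives 7). Individual-level: censoring bounds
the per-release sensitivity at T, the noise scale is T/ε, so each release
costs exactly ε and J releases cost ε·J. The `privacy_ledger` object
records releases one at a time and is additive under concatenation.
Population-vector releases (below) are budgeted separately rather than
added to trip ledgers, matching the trips-only convention of the
accounting examples the package reproduces; both can be reported side by
side.

## The mobility-informed SIR model

Per region i with time-invariant population N_i = S_i + I_i + R_i:

$$\frac{dS_i}{dt} = -\frac{\beta S_i I_i}{N_i}
  - \frac{\alpha \beta S_i \sum_j M_{ij} I_j / N_j}{N_i + \sum_j M_{ij}},
  \qquad \frac{dR_i}{dt} = \mu \frac{I_i}{N_i}, \qquad
  \frac{dI_i}{dt} = -\frac{dS_i}{dt} - \frac{dR_i}{dt}.$$

M is the day's O-D matrix; M_ij I_j/N_j is the expected infected exposure
of region i's residents through their visits to j, so infection travels
*against* observed flows (a region is seeded by its residents' visits to
infected places). Defaults β = 0.10, μ = 0.04 (COVID-era SIR fits),
α = 1 (visitors mix like residents); all per day.

Three deliberate numerical choices:

* **The infected balance.** Statements of this coupled model sometimes
  write dI = dS − dR, which cannot conserve N (both terms are
  non-positive whenever dS ≤ 0 ≤ dR). The package uses dI = −dS − dR,
  the unique choice conserving S + I + R.
* **Recovery form.** The μ·I/N recovery accompanying the coupled model
  differs from the classic Kermack-McKendrick convention μ·I ("a
  proportion μ of infecteds recovers each day"). Both are implemented
  (`recovery_form = "as-printed"` is the default, `"classic"` the
  alternative) so either behaviour is reproducible; note the as-printed
  form makes recovery negligible in large regions.
* **Integration.** Forward Euler with a 1-day step — the cadence at which
  matrices exist; the model itself does not dictate an integrator. Fluxes
  are limited (S
  outflow at −S, recovery at I) rather than compartments floored after
  the step, which enforces non-negativity *and* keeps conservation exact
  to floating-point rounding (tested at 10⁻⁹·N).

Epidemics start with 1% of the seed region infected; interventions
trigger at 20% prevalence (≥, so the boundary intervenes). In the private
regime both the matrices and the population denominators are privatized —
populations via Laplace(1/ε) noise, rounded and clamped at 1 so they
remain valid denominators — and suppressed matrix cells enter the force
of infection as the 0 they were released as.

## Aid targeting and evaluation

Out-migration from an affected region over a response week is the sum of
its matrix row across days; top-k targeting ranks the regions *receiving*
the most of that flow (an `origins` mode ranking by each region's own
out-flow is also provided, since "most out-migration" admits both
readings). Ties break by region id ascending — deterministic and
permutation-invariant.

Metrics: absolute cell error |private − nonprivate|; symmetric relative
error 2|p − q|/(p + q) ∈ [0, 2], defined as 0 at 0/0 (a suppressed cell
against a nonzero count hits the boundary value 2); percent error with
the non-private total as denominator; top-k accuracy as the mean daily
overlap |topk_priv ∩ topk_nonpriv|/k; and per-region
accuracy/precision/recall of intervention decisions averaged with equal
region weights. Degenerate confusion-matrix conventions are fixed
explicitly: a region with no true positives contributes recall 1, and
precision 1 if it also predicts none (0 if it predicts some).

## The synthetic generator

`mobility_scenario()` emulates the statistical structure the analyses
rely on, with defaults chosen once as the package's study conditions:

* **Regions**: k = 34 (a province-level setting), populations log-uniform
  on [10³, 10⁶], uniform planar coordinates for distances.
* **Trips**: subscribers get a home ∝ population and a personal daily
  rate from a gamma with mean 0.046 trips/day (≈ 14 trips over 305 days,
  the scale of real province-level CDR) and shape 0.3, so daily counts
  are negative-binomial marginally — a 5th percentile of zero and a long
  upper tail, as per-subscriber trip distributions show in practice.
  Destinations follow a gravity kernel N_j/d_ij^γ with γ = 1; movement
  chains (each trip starts where the last ended).
* **Shock**: from a start day, subscribers located in the affected region
  trip at `multiplier` times their rate — an out-migration surge. The
  post/pre flow ratio tracks the multiplier when the base rate is small;
  at high rates the region visibly depletes, which is realistic but makes
  the ratio an underestimate.
* **Events**: an optional CDR-style realization (one nighttime home event
  per subscriber plus one event per trip destination, seconds apart)
  constructed so trip extraction and home inference recover the simulated
  truth exactly — used to test the ingestion path end to end.

What the generator does **not** emulate: tower-level spatial noise and
multi-tower regions, call-frequency heterogeneity between events and
trips, weekly/diurnal seasonality, road networks, or any calibration to a
specific country's CDR. Passing tests therefore demonstrate correctness
of the pipeline and its statistical guarantees under realistic *scale and
tail behaviour*, not predictive fidelity to any real dataset — the
headline empirical tables of real deployments are not reproducible
without the proprietary data, and the package does not attempt them.

## Ingestion conventions

Trips are dated by the arrival (the later event); cross-midnight pairs
count by default (`within_day_only` excludes them); "daily" refers to the
matrix granularity. Home inference uses the modal tower over the
half-open nighttime window [20:00, 24:00) ∪ [00:00, 06:00), falls back to
the all-hours modal tower for subscribers with no nighttime events, and
breaks ties by smallest tower id. Unmapped towers are an error naming the
tower; unordered events are sorted, never rejected. Dates are ISO-8601;
region ids are opaque strings; the region index's order defines matrix
axes.

## Problem sizes in the test suite

The suite exercises the full study shape directly: the DP audit at 10⁶
mechanism runs per arm, suppression/error laws at 10⁵, a 305-day,
34-region epidemic on synthetic matrices from 2,000 subscribers
(seconds on one core), and 7-day disaster windows with 3,000–20,000
subscribers. These sizes were chosen as the smallest at which the
Monte-Carlo tolerances quoted above are meaningful.

## Known limitations

* Linear composition only; no advanced/Rényi accounting, no (ε, δ)-DP,
  and no continual-observation mechanism for long daily release streams.
* The tail-bound calculator covers non-suppressed cells only; suppressed
  cells carry the separate suppression-probability guarantee.
* The SIR harness does not fit β/μ to data, has no stochasticity, and
  interventions do not feed back into mobility.
* Suppression biases private totals downward by construction; no
  post-hoc debiasing is attempted.
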