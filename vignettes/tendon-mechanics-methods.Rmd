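---
title: "Tendon fascicle mechanics and fibril morphometry: models and methods"
author: "tendonmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tendon fascicle mechanics and fibril morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonmech)
```

# Scope

`tendonmech` re-implements, as a tested and reusable pipeline, the analysis
chain behind an age-graded mouse tail-tendon dataset: tensile testing of
fascicles from eight age groups (1.6 to 35.3 months, ids `01M` … `35M`),
and transmission-electron-microscopy morphometry of the collagen fibrils
that reinforce them. Four computational stages are covered:

1. **mechanics** — from a raw load–displacement record to the full tensile
   property set of one specimen, and aggregation to mice and age groups;
2. **fibril structure** — equivalent-circle diameters, per-image area
   fractions, group histograms, and the randomised image-sampling protocol;
3. **mixture decomposition** — a two-component Gaussian fit of the diameter
   histogram by simulated annealing;
4. **metrology** — add-in-quadrature uncertainty budgets and Welch
   two-sample power analysis.

A synthetic-data module generates ground-truthed inputs for every stage, so
the whole pipeline is validated by parameter recovery rather than by
inspection.

# The mechanics stage

## From raw signal to stress and strain

A raw record (the "mtt" dialect) has five columns: time (ms), displacement
and load transducer signals (mV), and their converted values in mm and
gram-force. The reader trusts the converted columns and carries the mV
channels untouched, because calibration constants are instrument-specific
and both representations are deposited together. Tabs are the only accepted
separator and the decimal separator is the period.

Specimens are stretched from a slightly slack state, so the record begins
with a toe of near-zero load. **Zeroing** finds the maximum load, takes the
first sample whose load reaches 1% of it (the `load_cutoff_fraction`,
configurable), declares that sample the origin, sets the nominal length
$L_0$ to the grip-to-grip displacement there, and subtracts the origin's
displacement and load from the remaining record. The comparison is `>=` and
ties break to the earliest sample, so the origin is deterministic. When
noise at low loads defeats the automatic rule, the manual mode
(`loadat1percent = FALSE`) accepts a caller-chosen start index instead —
this is also the right mode for records that are taut from the first
sample, since the automatic cutoff otherwise lands (by construction) a
little way up the toe and truncates about 1% of the peak load.

Conversion is then
$$\varepsilon = x / L_0, \qquad \sigma = P / A, \qquad A = \pi d^2 / 4,$$
with $d$ the mean fascicle thickness (mm) from repeated measurements along
the axis, and the load converted at standard gravity
($9.80665\times10^{-3}$ N per gram-force, exposed in the configuration
because the deposited sheets report stress in MPa without stating the
constant). With $A$ in mm$^2$ the stress is in MPa directly.

## Landmarks and derived properties

Four landmarks partition the curve: the origin O, the yield point p (point
of inflexion, where $d\sigma/d\varepsilon$ is maximal), the strength point
q (maximum stress $\sigma_U$ at strain $\varepsilon_U$), and the rupture
point r. The stiffness $E$ is the slope at p — the maximum modulus — and
$\sigma_Y, \varepsilon_Y$ are the stress and strain there.

The derivative is estimated by smoothing the samples between O and q with a
*moving* least-squares polynomial of degree `orderpoly` (2–7, the
Savitzky–Golay filter) whose window spans one fifth of the segment, and
differentiating the local fits on the sample grid. We chose the moving fit
over a single global polynomial of the same degree after measuring both: a
global degree-5–7 polynomial cannot track the derivative peak of a sharp
sigmoid (on a noiseless logistic test curve its yield strain lands 1–7 grid
steps off and its maximum slope is 8–17% low), while the moving fit of the
same degree locates the peak within a tenth of a grid step and the slope
within 0.1%, and still suppresses sensor noise (median stiffness error 0.6%
on the noisy synthetic suite, versus 4–5% for the global fit). The filter
runs on the sample index, and $d\sigma/d\varepsilon$ is formed as the ratio
of the filtered derivatives of stress and strain, so unevenly spaced strain
grids are handled without assuming a uniform step. Constant-slope ties
break to the earliest index; a maximum at either end of the segment is
flagged with a boundary warning. The yield stress is read from the smoothed
curve, not the raw samples (the smoothing is the point of the procedure;
this is flagged here because the alternative — raw stress at index p — is
equally defensible).

The rupture index r is the last sample whose strain does not exceed the
caller's rupture estimate (`laststrainpt`), provided that estimate lies
beyond $\varepsilon_U$; otherwise the final sample is used with a warning.
Where the original workflow confirmed the cut by eye, the package keeps the
processed curve and landmarks attached to the result for plotting.

Strain energy densities (MPa $\equiv$ MJ/m$^3$) are trapezium-rule
integrals of $\sigma\,d\varepsilon$: resilience $u_Y$ over [O, p], plastic
work $u_P$ over [p, q], rupture work $u_R$ over [q, r], with
$u_F = u_P + u_R$ and $u_0 = u_Y + u_F$. The per-interval trapezoid
contributions are computed once and summed per segment, and the totals are
*defined* as the sums of the parts, so $u_0 = u_Y + u_P + u_R$ holds to
machine precision on every curve — this additivity is asserted in the test
suite rather than assumed. The ratios $u_Y/\sigma_Y$ and $u_F/\sigma_U$
complete the per-specimen property set.

## Aggregation

Fascicle segments are technical replicates: they are averaged within each
tail (mouse), and tail means are averaged within each age group. Group
dispersion is the SEM over tails — $n$ is the number of mice, not the
number of specimens — and is reported missing for single-tail groups.
Specimen-level variance is deliberately not propagated upward, matching how
the deposited summary sheets are laid out.

# The fibril-structure stage

Fibril cross sections are modelled as circles, making area and diameter
exact inverses: $a_f = \pi D^2/4$, $D = \sqrt{4 a_f/\pi}$. The area
fraction of one image is $\rho = \sum a_f / S$ over the
$5\,\mu\text{m} \times 4\,\mu\text{m}$ field ($S = 2\times10^7$ nm$^2$).
Part-fibrils at the image boundary contribute their clipped areas to $\rho$
but are excluded from diameter statistics, because a clipped area
systematically underestimates $D$; whether the original tracing included
them in the histograms is not recorded, so the exclusion is this package's
documented choice.

The two-stage randomised image-sampling protocol is reproduced exactly:
every image in a group's pool is tagged with a uniform(0,1) draw and sorted
ascending (a stable sort, so tied tags preserve input order); the number of
images to keep is itself drawn uniformly from {4, …, 11}; the first $N_c$
sorted images are selected. The function is pure in (pool, seed).

Histograms use right-open fixed-width bins $[kw, (k+1)w)$ from zero; the
default width is 20 nm, chosen to resolve the 30–50 nm component SDs of the
observed subpopulations while keeping about 50–100 fibrils in the modal
bins at the deposited sample sizes. The deposited sheets do not state their
bin width, so the readers honour whatever edges a file declares and the
builder is for synthetic and replication work.

# The mixture-decomposition stage

Diameter histograms in this tissue are typically bimodal: a small-diameter
subpopulation D1 and a large-diameter subpopulation D2, with mean diameters
$D_{D1} < D_{D2}$. The decomposition fits, to the *normalised* frequency
profile on the bin centres, a sum of `ngauss = 2` unit-amplitude Gaussian
profiles $\exp(-(x-\mu_i)^2/2\sigma_i^2)$ scaled by amplitudes solved by
least squares. Choices that the original description leaves open, and how
they were fixed:

* **Objective.** The sum of squared residuals between the normalised
  histogram and the amplitude-solved composite. This matches the "linear
  regression of the component profiles onto the primary distribution"
  framing; a likelihood-based mixture fit (EM) is deliberately *not* the
  primary path, though it would serve as an independent cross-check.
* **Amplitudes.** Non-negative least squares (amplitudes are proportions);
  plain least squares is available behind `nonneg = FALSE` for fidelity
  experiments. For two components the NNLS solution is obtained exactly by
  KKT case enumeration; general component counts use the Lawson–Hanson
  solver.
* **Proposals.** The parameter file's MUA/MUB (SDA/SDB) "amplification"
  coefficients are interpreted as the affine map $\text{value} = A + Bu$
  with $u \sim$ uniform(0,1), i.e. proposal intervals $[A, A+B]$, clipped
  to the diameter limits `[lower, upper]`. Each proposal draws a fresh
  configuration (all means and SDs) from these intervals.
* **Annealing schedule.** Initial temperature 0.5, reduction factor 0.9 per
  step, at most 100 configurations per temperature step, 100 steps, and 10
  Metropolis acceptances ("successes") before moving to the next step —
  the schedule of the original program. A success is any acceptance,
  whether downhill or thermal. No early-exit criterion is added beyond the
  fixed number of steps, matching the original. The Metropolis rule accepts
  a proposal with $\Delta \le 0$ always, otherwise with probability
  $e^{-\Delta/T}$.
* **Output.** The best configuration ever visited, components sorted so
  $\mu_1 < \mu_2$; the per-step best-objective trace is returned and is
  non-increasing by construction. The reported component SDs are the fitted
  Gaussian widths (the ± values on subpopulation means are treated as
  component SDs, not run-to-run uncertainties).
* **Refinement.** A second run with proposal intervals re-centred on the
  first fit and widths shrunk to one quarter (the `shrink` parameter),
  seeded at `seed + 1`; the better of the two fits by objective is
  returned, so refinement can only improve the report.

Because proposals are drawn fresh from fixed intervals rather than
perturbed locally, the annealer behaves like a temperature-gated random
search with best-ever tracking; with the default schedule this evaluates at
most $10^4$ configurations, which recovers the means of a
0.5·N(100, 30²) + 0.5·N(250, 50²) population (n = 2000, 20 nm bins) within
±10/±15 nm in at least 4 of 5 seeded runs — the headline recovery property
asserted in the acceptance suite.

# The metrology stage

## Uncertainty budgets

Instrument uncertainties — displacement 0.01 mm, thickness 0.0025 mm, load
0.0001 g, TEM lengths 0.5 nm from the grating calibration — are propagated
with add-in-quadrature models: for sums,
$\delta Q = \sqrt{\delta a^2 + \delta b^2}$; for products and quotients,
$\delta Q = |Q|\sqrt{(\delta a/a)^2 + (\delta b/b)^2}$. A squared variable
contributes its relative term twice *as independent entries*, so
$\delta A = A\sqrt{2}\,\delta d/d$. That convention reproduces the
documented worked values $\delta\varepsilon = 0.002$,
$\delta A = 3\times10^{-4}$ mm$^2$ and $\delta\sigma = 2$ MPa (1 s.f.);
applied to the fibril area it yields $\delta a_f = 2\times10^2$ nm$^2$
where the correlated convention ($2\,\delta D/D$) would give
$3\times10^2$ — the two conventions cannot both be matched, so the
independent-entries form is used uniformly and only the strain and stress
checks are treated as authoritative. $L_0$ enters the strain budget as an
order of magnitude only, so $\delta\varepsilon = \varepsilon\,\delta x/x$.
A Monte-Carlo cross-check (`mc_propagate()`) perturbs the *assembled*
independent inputs (e.g. $P$ and $A$ with its already-budgeted
$\delta A$) and agrees with the quadrature deltas within 5% in the test
suite.

## Power analysis

`welch_power()` computes the analytic power of the two-sample t test for
unequal sample sizes and variances from the noncentral t distribution with
Welch–Satterthwaite degrees of freedom and noncentrality
$|\mu_1-\mu_2|/\sqrt{s_1^2/n_1+s_2^2/n_2}$, one- or two-sided, with alpha
defaulting to 0.05 (the original report names neither its software nor its
alpha, so published power values guide plausibility rather than equality
tests). Where only a printed SEM is available, `sd_from_sem()` recovers the
SD as SEM·$\sqrt n$. At zero effect the two-sided power equals alpha
exactly — an identity the suite asserts to $10^{-6}$. The analytic formula
treats the degrees of freedom as fixed; for very small groups (n of 3–4 per
arm) the true rejection rate of the estimated-df Welch test departs from it
by up to about 0.05, so the simulation-agreement checks use design-sized
fixtures (n ≥ 6 per arm), where agreement is within 0.02 at 2×10⁴
replicates.

# The synthetic-data generators

## Tensile traces

`simulate_trace()` emulates a slack-then-taut record: the grip-to-grip
displacement advances at the crosshead rate (0.067 mm/s, 100 Hz sampling by
default) from $L_0 - \text{slack}$, and once taut the load follows an
analytic stress–strain law chosen so every landmark is known exactly:

* a power-law toe $\sigma = \sigma_Y(\varepsilon/\varepsilon_Y)^m$ with
  $m = E\varepsilon_Y/\sigma_Y$, whose slope rises monotonically to exactly
  $E$ at the yield point (feasibility requires $m > 1$);
* a concave quadratic from yield to strength with slope continuity at
  yield, requiring $\sigma_U-\sigma_Y \le E(\varepsilon_U-\varepsilon_Y)
  \le 2(\sigma_U-\sigma_Y)$ so the maximum slope stays at yield and the
  stress peaks no earlier than $\varepsilon_U$;
* a linear post-peak decay to a configurable fraction of $\sigma_U$ at the
  rupture strain.

The segment energies integrate in closed form, so the generator's truth
includes $u_Y, u_P, u_R, u_F, u_0$. Gaussian load noise (default SD 0.02 g,
about 20× below the 1% zeroing cutoff at the default geometry) and affine
mV channels complete the record. Default magnitudes ($E = 600$ MPa,
$\sigma_Y = 20$, $\sigma_U = 50$ MPa, $\varepsilon_Y = 0.05$,
$d = 0.1$ mm, $L_0 = 5$ mm) sit in the middle of the observed mature-group
ranges; the recovery suites draw 50 parameter sets across $E$ 400–700 MPa
and toe exponents 1.3–1.8 to span young-to-old curve shapes. The recovery
suites pass `orderpoly = 7`: the power-law toe meets the quadratic cap with
a curvature jump, and the highest permitted order resolves the resulting
sharp derivative peak best. What these traces do *not* emulate:
viscoelastic rate dependence, grip compliance, partial fibre pullout before
the peak, and per-specimen manual truncation choices — so exact
reproduction of deposited group means is out of scope, and parameter
recovery on the synthetic family is the validation standard instead.

## Diameters and fields

`simulate_diameters()` draws from a two-component Gaussian mixture
(defaults 100/250 nm means, 30/50 nm SDs, equal weights — the scale of the
observed subpopulations), redrawing non-positive values, and keeps the
component assignments so per-component recovery is directly checkable.

`simulate_field()` packs non-overlapping discs with mixture-drawn diameters
into the nominal TEM field by random sequential placement, clipping
boundary discs to the field rectangle (clipped areas via piecewise adaptive
quadrature, split at the circle–edge crossings) and counting their clipped
area toward $\rho$ — mirroring how boundary part-fibrils are traced. The
record's area fraction equals the generator's bookkept truth exactly. The
hard feasibility cap is $\rho < 0.91$ (below close packing), but random
sequential placement jams near $\rho \approx 0.55$ for these diameter
ratios, so the default target is 0.5 and higher observed fractions
(up to 0.85 in mature groups) are *not* reproducible by this placement
process — the generator validates bookkeeping and readers, not packing
realism.

# Numerical and interface choices

* Canonical interchange is CSV mirroring the deposited worksheet layouts
  (specimen sheet columns A–O; per-mouse and per-group mean sheets; wide
  per-image area-fraction sheet; bin/frequency/normalised-frequency
  histogram sheet). Legacy binary workbook files are out of scope.
* Numeric fields are written with 17 significant digits, so write→read
  round trips are lossless to well below 1e-9.
* The histogram sheet reader infers the final bin edge from the declared
  uniform bin spacing; non-uniform deposited edges would need an explicit
  upper-edge column and are not claimed.
* Time monotonicity and crosshead monotonicity are validated on read and
  never repaired silently; rows with unparsable numerics are dropped with a
  warning, malformed specimen ids are kept as opaque text with a warning.
* Every stochastic routine (`sample_images`, `sa_fit`, the generators, the
  Monte-Carlo oracles) runs under a caller-supplied seed through an
  RNG-state-preserving wrapper, and is a pure function of its inputs
  including that seed.
* The run log is one `key=value` line per analysis with the four analysis
  inputs mandatory, URL-encoded values, and a parser that reproduces the
  entry map exactly.
* Problem sizes used by the validation suites: 50 synthetic traces of
  roughly 1,900 samples each for mechanics recovery; 5 seeded populations
  of 2,000 fibrils for mixture recovery; 10⁴ Metropolis draws; 2×10⁴
  Welch-test replicates per power fixture; 10⁵ draws per Monte-Carlo
  propagation check. These sizes give the comparison tolerances used in
  the tests at least a 3-sigma margin.

# Known limitations

* The yield stress/strain are read from the smoothed curve; deposited
  values may have used raw samples at the located index.
* Deposited group means reflect per-specimen manual truncation decisions
  that are not recoverable from the raw records, so numerical equality
  with them is not promised — property-based recovery on ground-truthed
  synthetic data is the acceptance standard.
* The fibril-field generator cannot reach the highest observed area
  fractions (see above), and no shrinkage correction for TEM processing
  artefacts is applied anywhere: measured $D$ and $\rho$ are reported
  as-is.
* The power routine's printed-value comparisons are plausibility checks
  only, because the original analysis' alpha and software are unstated.
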