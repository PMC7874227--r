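---
title: "Space-time variogram modelling and network coverage: methods"
author: "STCoverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time variogram modelling and network coverage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(STCoverage)
```

## The problem

A fixed air-quality monitoring network measures pollutant concentrations at a
few dozen stations. How much of the surrounding territory does each station
actually *represent*? STCoverage answers this with a purely geostatistical
argument: estimate how far in space (and how long in time) measurements stay
correlated, and draw a circle of that spatial correlation range around each
active station. The union of those circles is the network's coverage for that
pollutant and year. No interpolation of concentrations is needed — only the
correlation range.

The pipeline is: weekly aggregation of hourly records → empirical space-time
semivariogram → exhaustive fit of five space-time covariance structures →
coverage maps from the fitted spatial range.

## Weekly aggregation

Hourly values are averaged per ISO-8601 calendar week (Monday–Sunday). A
station's week is kept only when **more than 5 calendar days** of that week
each contain **at least 17 non-missing hourly records**; otherwise the cell is
missing. Both thresholds are arguments of `aggregateWeekly()`
(`minDaysPerWeek = 6`, `minHoursPerDay = 17`). The weekly mean uses *all*
non-missing hourly values of the week, not only those of qualifying days — the
qualifying-day rule is a gate, not a filter. Empty cells, `"NA"` and negative
values in the source CSV are treated as missing: public network exports mark
gaps with negative sentinels such as `-99`, and true concentrations are
non-negative. Timestamps are used as given (no time-zone conversion), and "a
day with 17-h records" means 17 distinct hourly slots, which duplicate-record
detection enforces.

`completenessMatrix()` reports, per station-week, the fraction of the 168
possible hourly records present — the tile-plot view used to spot late
activations, outage blocks and permanent shutdowns.

## Empirical space-time semivariogram

For stations $s_a, s_b$ at great-circle distance $h$ (haversine, Earth radius
6371 km — ranges are wanted in km, so no map projection is involved here) and
weeks $t, t+u$:

$$\hat\gamma(h, u) = \frac{1}{2N(h,u)} \sum \left[Z(s_a, t) - Z(s_b, t+u)\right]^2$$

over all pairs whose distance falls in the spatial bin of $h$ and whose lag is
exactly $u$ weeks. Conventions, fixed once:

* 15 equal-width distance bins from 0 to the maximum inter-station distance
  (the data never dictate a bin count; 15 gives stable pair counts for
  networks of 20–50 stations), plus a zero-distance bin holding same-station,
  purely temporal pairs;
* integer week lags $0 \ldots \lfloor T/3 \rfloor$ by default — the panel is
  already discrete in time, so there is no temporal binning;
* station pairs are unordered; time pairs are ordered, so for $u > 0$ both
  orientations $(a,t),(b,t{+}u)$ and $(b,t),(a,t{+}u)$ contribute, while at
  $u = 0$ a pair contributes once; a station is never paired with itself at
  lag 0;
* any pair with a missing value is dropped; cells record their pair count
  $N(h,u)$, which later serves as the fitting weight.

These conventions are pinned by an $O(n^2 T^2)$ brute-force oracle in the test
suite, with exact (1e-12 relative) agreement required.

## Component families and space-time structures

Three bounded component families with nugget $n$, sill $s$, range $r$ and the
practical-range constant $a = 1/3$:

$$\gamma_{exp}(h) = (s-n)\,(1 - e^{-h/(ra)}) + n\,H_{(0,\infty)}(h)$$
$$\gamma_{sph}(h) = (s-n)\left[\left(\tfrac{3h}{2r} - \tfrac{h^3}{2r^3}\right)
  H_{(0,r)}(h) + H_{[r,\infty)}(h)\right] + n\,H_{(0,\infty)}(h)$$
$$\gamma_{gau}(h) = (s-n)\,(1 - e^{-h^2/(r^2 a)}) + n\,H_{(0,\infty)}(h)$$

With $a = 1/3$ the exponential and Gaussian families first reach 95.02% of
the partial sill exactly at $h = r$, so $r$ is comparable across families
(the spherical family attains the sill there exactly). $\gamma(0) = 0$ exactly:
the Heaviside factor excludes the origin, which keeps the comparison with the
empirical surface well defined at zero lag; the nugget is the right-limit at
$0^+$.

Five space-time structures compose these components
(`stModel()`, `evalSTVariogram()`):

* **separable** $\; sill\,(\bar\gamma_s + \bar\gamma_t - \bar\gamma_s\bar\gamma_t)$,
  components standardized to sill 1 (the constructor rescales arbitrary
  components and absorbs their sills);
* **productSum** $\;(k\,sill_t+1)\gamma_s + (k\,sill_s+1)\gamma_t - k\gamma_s\gamma_t$,
  with overall sill $k\,sill_s\,sill_t + sill_s + sill_t$ (`productSumSill()`);
  its components are kept unstandardized, with the sill identity emerging from
  the fitted component sills;
* **metric** $\;\gamma_{joint}\!\left(\sqrt{h^2 + (\kappa u)^2}\right)$, the
  anisotropy $\kappa$ (km/week) converting one week into km;
* **sumMetric** $\;\gamma_s + \gamma_t + \gamma_{joint}(\cdot)$ and
* **simpleSumMetric**, the same with all component nuggets zero and a single
  overall nugget.

All three metric-type structures use the joint lag
$\sqrt{h^2 + (\kappa u)^2}$. Printed forms of the sum-metric structures are
sometimes seen with $\kappa u^2$ inside the root; that variant is not
dimensionally consistent ($h$ in km against km·week), so the $(\kappa u)^2$
convention — the one the reference geostatistics ecosystem implements — is
used uniformly.

## Fitting

**Initial values** come from the empirical surface, read as a matrix (spatial
bins × temporal lags): the nugget guess is the median of the means of the
first three rows (columns, for the temporal axis), the sill guess the median
of the means of the last five; the spatial range guess is one third of the
maximum binned distance and the temporal range guess the maximum lag. With
fewer than three (five) populated rows, all available ones are used.

**Anisotropy** $\kappa$ is initialized by a linear model through matched
marginal levels: the purely spatial (lag-0) and purely temporal
(zero-distance) marginals are scanned for the lags at which each first
reaches a common set of semivariance levels, and a least-squares line through
the origin of the matched (temporal, spatial) lag pairs gives km-per-week.
Flat marginals fall back to the ratio of the range guesses. This recovers a
known $\kappa$ exactly on noise-free metric surfaces and within ±30% on
simulated metric fields (test suite).

**Weighted least squares.** Each candidate minimizes
$\mathrm{WMSE} = \sum_c w_c\,(\hat\gamma_c - \gamma_{model})^2 / \sum_c w_c$
over non-empty cells with pair-count weights $w_c = N(h_c, u_c)$ — cells
backed by more pairs count more, and the criterion is invariant to weight
rescaling. Optimization is bound-constrained quasi-Newton (L-BFGS-B) from the
single rule-based start (no multistart). Components are parameterised as
(nugget, partial sill, range) so every constraint — $n \ge 0$,
$s \ge n$, $r > 0$, $k > 0$, $\kappa > 0$ — is a box constraint.
Convergence uses `factr = 1e7` (about 1e-9 relative on the objective) with at
most 500 iterations; non-convergence is reported, with the best iterate kept.

**Grid search.** Every structure × family assignment is fitted:
9 separable + 9 productSum + 3 metric + 27 sumMetric + 27 simpleSumMetric
= 75 candidates. The winner minimizes WMSE; ties go to the first candidate in
the deterministic enumeration order (structures in the listing order above,
families cycling exponential, spherical, Gaussian with the last component
fastest). Richer structures contain simpler ones, so on data simulated from a
separable truth the winner is frequently a sum-metric model that fits
sampling noise marginally better — that is a property of pure-WMSE selection,
not a defect, and the winner's surface still tracks the truth.

**The coverage radius.** Winners of different structures carry their spatial
structure in different components, so the radius is extracted
structure-agnostically: `effectiveSpatialRange()` finds the smallest $h$ at
which the spatial marginal $\gamma(h, 0)$ first reaches 95% of the value it
attains at the largest observed distance. Referencing the level *within the
observed domain* matters: a fitted surface is unconstrained beyond the data,
and extrapolated asymptotic sills can push the nominal 95% point far outside
the region the variogram ever saw.

## Coverage maps

`bufferUnion()` places a circle of the fitted radius around each station
active in a year (`activeStations()`: at least `minWeeks = 1` non-missing
weekly value). Geometry is computed in a local azimuthal equidistant
projection centred on the network centroid — distances from the centre are
preserved exactly, and at metropolitan scale (≤ ~100 km) the distortion of
inter-station distances is far below the 0.5% tolerance of the area checks.
The union area is **exact**, not polygonal: each circle's boundary is
decomposed into the arcs not covered by any other disk (interval merging on
angles), and Green's theorem sums the arc contributions, which handles
disjoint components and interior holes alike. The boundary rings exported to
GeoJSON are discretized at 64 segments per quadrant (area error well under
0.5%); the union area statistic does not depend on that discretization.

The fraction of the study-region polygon covered is evaluated on a
deterministic 200×200 grid of cell centres inside the region (even-odd
point-in-polygon, exact point-in-circle). A fixed grid makes the fraction
monotone in the radius and exactly 1.0 at saturation. One whole-period radius
is applied to every year, so year-over-year changes in the maps isolate
changes in the active network.

Study regions are read from GeoJSON (`readRegionGeoJSON()`); stations outside
the region still contribute circles, while the region fraction is computed
against the region polygon only.

## The synthetic-data generator

`generateNetwork()`, `simulateField()` and `applyMissingness()` emulate the
data the method is designed for: 20–50 stations uniform in a ~60 × 60 km
metropolitan box, weekly panels over multiple years, values drawn from a
zero-mean Gaussian random field with a *known* space-time semivariogram, and
the observed gap patterns (late activation, outage blocks, permanent
shutdown, random dropout). Simulation happens directly at the weekly
resolution the estimator consumes, keeping the covariance dense-factorizable;
`writeSyntheticMeasurements()` optionally expands a panel into hourly CSV
records (7 × 24 identical values per kept week) so the ingest path and
completeness rules are exercised end-to-end.

The field uses $C(h,u) = sill_{total} - \gamma(h,u)$ over all cell pairs,
Cholesky-factorized with diagonal jitter escalating to $10^{-8} \times$ sill
(some variogram-valid corners are numerically borderline); failure beyond
that aborts with the offending structure named. The separable structure
factorizes as a Kronecker product and is simulated per axis, which makes the
30 × 200 study grids cheap. All randomness flows from one seed through a
saved-and-restored RNG state, so simulations are reproducible and do not
disturb the caller's stream.

What the generator does **not** emulate: non-Gaussian marginals (real
concentrations are skewed and non-negative), seasonality and trend, emission
physics, and instrument-level error structure. Passing tests therefore
demonstrate that the estimator and fitter recover known correlation
structure from realistically sized, realistically gappy panels — not that any
particular city's pollution field satisfies the model.

## Study sizes and what the checks show

The bundled checks run at sizes chosen to finish in minutes on one core while
still being informative: exact-oracle comparisons on panels up to 6 stations
× 10 weeks; parameter recovery on 30 stations × 200 weeks with 20 seeded
replicates of a separable exponential truth (spatial range 40 km, temporal
range 8 weeks, sill 1, nugget 0.1), requiring the fitted spatial range within
±25% of truth in at least 80% of replicates; one full 75-candidate grid
search per study. With a 40 km range on a ~60 km domain, a single
realization's empirical variogram carries substantial sampling variability —
the ±25%/80% criterion is about as tight as that setting permits, and
recovery is assessed by fitting the truth's own structure; a free grid-search
winner may legitimately reallocate structure between components.

## Known limitations

* WMSE model selection has no complexity penalty; leaderboard inspection (or
  an information criterion, out of scope here) is advised when structures tie.
* The anisotropy "linear model" is a documented stand-in for an unspecified
  convention; it only initializes $\kappa$, which the metric-type fits refine.
* Region input is GeoJSON only; shapefiles are not read.
* Union rings assume circles in generic position; exactly tangent circles can
  degrade ring chaining (the area statistic is unaffected).
* The dense simulator is limited to ~20,000 cells; larger grids need the
  separable (Kronecker) path.
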