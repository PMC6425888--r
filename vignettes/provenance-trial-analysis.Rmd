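---
title: "Methods: tree-ring analysis of provenance trials under marginal climate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tree-ring analysis of provenance trials under marginal climate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendroprov)
```

## The scientific question

A provenance trial grows several seed-origin populations (provenances) of one
tree species side by side, so that differences in growth behaviour can be
attributed to origin rather than environment. `dendroprov` implements the
dendrochronological analysis chain for such trials — ring-width indexing,
drought indices, individual-tree ordination, pointer years, clustering — and
a synthetic trial generator built around one idea: **when a site sits at the
climatic margin of the species' range, a single limiting factor (here, the
water balance) caps the growth of every tree, and between-provenance
differences in growth pattern shrink**. This is Liebig's law of the minimum
acting on a common garden: at a mild site the provenances express their own
climate responses; at a marginal site they synchronize onto the shared
water-limited signal.

The package makes that phenomenon quantitative and testable without field
data: the simulator has a `marginality` knob in [0, 1], and the analysis
returns a scalar *differentiation score* per site — the fraction of
provenance pairs whose growth-pattern ordinations differ significantly.

## Chronology building

Each tree's ring-width series (mm, 0.01 mm precision) is divided by a fitted
growth curve, giving a dimensionless ring-width index (RWI) near 1. The
growth curve is a penalized discrete smoother minimizing
$\sum_t (w_t - s_t)^2 + \lambda \sum_t (\Delta^2 s_t)^2$, whose frequency
response is known in closed form,

$$H(f) = \frac{1}{1 + \lambda\,(2 - 2\cos 2\pi f)^2},$$

so the stiffness $\lambda$ can be set exactly from the conventional
*50 % frequency cutoff*: $H = 0.5$ at wavelength 30 years by default. We
deliberately verify this relation empirically rather than trust it: the test
suite probes the fitted curve with 150-year sinusoids and requires amplitude
response 0.5 ± 0.05 at 30 years, at least 0.9 at 100 years (age trends must
pass) and at most 0.1 at 5 years (interannual signal must be rejected).
Because the penalty's null space contains straight lines, linear growth
trends are tracked essentially exactly.

Division (not subtraction) is used for detrending, the convention for
conifer ring widths; a zero width (locally absent ring) becomes index 0 and
is retained. A non-positive fitted curve aborts with the offending year
named — no silent clamping.

Serial autocorrelation is then removed by an AR(1) fit ("prewhitening"):
$x_t = c + \phi x_{t-1}$ estimated by least squares on lagged values,
residuals re-centered to mean 1, first year dropped. The order is fixed at
one by design, not selected by information criterion. For a correctly
prewhitened AR(1) input the residual lag-1 autocorrelation has sampling
s.d. $\approx \phi/\sqrt{n}$, so individual draws can legitimately exceed
0.1; the suite therefore checks the mean over 100 draws (≈ 0.04) and that
at least 90 % of draws fall below 0.1.

Provenance chronologies are per-year Tukey biweight robust means across
trees (tuning radius 9 × MAD, ≤ 50 iterations, tolerance 1e-8, median
fallback when the MAD is zero), with the sample depth recorded. Descriptive
statistics per provenance × site follow the conventional set: mean raw ring
width, Gleichläufigkeit (sign-coherence of year-to-year changes; one zero
change in an interval scores 0.5), mean sensitivity (pairs summing to zero
are skipped and counted), and rbar (mean pairwise Pearson correlation over
each pair's common period). glk for a provenance is the mean over all
within-provenance tree pairs; all three index-based statistics are computed
on the prewhitened RWI (whether detrended-only or prewhitened series should
be used is genuinely ambiguous in the field; we fix prewhitened and say so).

## Climate indices

Potential evapotranspiration uses the Hargreaves equation,
$PET = 0.408 \times 0.0023\,(T_{mean} + 17.8)\sqrt{T_{max}-T_{min}}\;R_a$
(mm day⁻¹), with extraterrestrial radiation $R_a$ from FAO-56 solar
geometry evaluated at the mid-month representative day
$J = \lfloor 30.4\,m - 15 \rfloor$. The implementation is pinned to the
published FAO-56 worked example (20°S, 3 September → 32.2 MJ m⁻² day⁻¹,
within 2 %). Polar latitudes are refused rather than mishandled. The
climatic water balance is $CWB_m = P_m - PET_m$, month by month, so
$CWB + PET = P$ holds exactly.

SPEI-k sums $D = P - PET$ over backward k-month windows and fits, per
calendar month, a three-parameter log-logistic distribution by unbiased
probability-weighted moments over the full provided series (the calibration
period), mapping probabilities to standard normal deviates. Two numerical
points deserve note. First, under the CDF parameterization
$F(x) = (1 + (\alpha/(x-\gamma))^\beta)^{-1}$ the textbook moment-ratio
estimator returns the shape with inverted sign; we take $|\beta|$ so that
$F$ is increasing and SPEI is monotone in $D$ (verified by
parameter-recovery simulation). Second, the location parameter absorbs any
constant shift of $D$, making SPEI shift-invariant — checked numerically.
Calibration quality is asserted per calendar month: |mean| < 0.05 and s.d.
in [0.9, 1.1] on 50 simulated years, and the fitted transform is
cross-checked against empirical-quantile (Gringorten) z-scores.

The 19 bioclimatic variables are computed from 12-month normals with
wrap-around three-month quarters (December–January wraps), extreme quarters
chosen per definition with first-window tie-breaks, bio4 = s.d. of monthly
mean temperature × 100, and bio15 the precipitation CV in percent without a
stabilizer (zero-mean precipitation flags bio15 undefined, as a zero annual
temperature range does bio3). The aridity summary is pluggable with the
de Martonne index $P/(T+10)$ as the recorded default; the Palmer drought
severity index is only ever *read* from an external file, never computed.

## Individual-tree ordination (PCGA)

Principal component gradient analysis orders individual trees along a
growth-pattern gradient: PCA of the tree × year RWI matrix over the common
period (each tree centered on its own mean), each tree's loadings on the
first two components expressed in polar form, and trees ranked by polar
angle. Two reflection ambiguities are fixed deterministically: PC1 is
oriented so its mean loading is positive, PC2 so its largest-magnitude
loading is positive — making angles invariant to tree column order. Angle
ties are broken by stable series order, so ranks are always a permutation.

The pairwise refinement runs PCGA on *only two provenances at a time* and
applies a two-sided Wilcoxon rank-sum test to the gradient ranks split by
provenance (ranks, not raw angles, so any monotone angle transform is
irrelevant). The rank-sum test enumerates all assignments exactly when the
combined sample is ≤ 12 without ties, and otherwise uses the normal
approximation with tie and continuity corrections; it agrees with
`stats::wilcox.test` to 10 decimal places in both regimes but is authored
independently so the test suite can keep a genuine dual route. No
multiple-testing correction is applied across the 45 pairs — the p-value
matrix is presented raw, with 0.05/0.01 tiers.

The differentiation score of a site is the fraction of provenance pairs
with p < α (default 0.05). Its null calibration is a property of the whole
chain (simulation → detrending → prewhitening → PCA → ranks → test): on a
null scenario with two identical provenances (15 trees, 35 years), the
rejection fraction over 500 seeds is ≈ 0.05.

## Pointer years

Event years per tree use Cropper values: each year standardized within a
5-year window centered on it, with the sample (n−1) standard deviation.
Edge years with no full window are undefined rather than computed from
truncated windows (this avoids edge bias, at the cost of losing
(window−1)/2 years per end). Intensity classes follow the conventional
thresholds |C| > 1 (weak), > 1.28 (strong), > 1.645 (extreme), signed. A
provenance flags a pointer year when at least 65 % of assessable trees
(≥ 5 trees with defined values — our guard against tiny denominators) reach
at least the weak class of one sign; the pointer's intensity is the
strongest class still reached by that fraction. A *common pointer year*
(CPY) requires at least 6 provenances with same-sign pointers at one site.

A consequence of the moving-window metric, reproduced by a dedicated
fixture: a sustained multi-year depression does *not* produce CPYs in its
interior years, because the window statistics are depressed too — only
isolated extreme years are flagged. This behavioural property matters when
interpreting real trials where a drought initiates a lasting decline.

## Clustering and bioclim ordination

Provenance chronologies are clustered on Euclidean distances over their
common period with four linkages (single, complete, UPGMA, Ward). "Ward"
here means minimum-variance on squared Euclidean distances with heights
reported on the distance scale (`ward.D2`); we spell this out because the
name is ambiguous across toolkits. The agglomerative coefficient
$1 - \mathrm{mean}_i\,(h_{first}(i)/h_{final})$ selects the linkage, and
the Mojena stopping rule (first fusion exceeding mean + c × s.d. of fusion
heights; c = 1.25 by default, configurable) selects the cluster count,
returning 1 when nothing exceeds the threshold.

Bioclim vectors across locations are ordinated by PCA on standardized
variables; eigenvalues sum to the number of retained variables, variance
shares are eigenvalue/n × 100, and each component is oriented so its
strongest variable correlation is positive. Zero-variance variables are
dropped with a warning. With only two trial sites the ordination needs
additional locations (e.g. provenance origins) to be meaningful; the
pipeline runs it only when at least three climate tables are supplied.

## The synthetic trial generator

The generator is first-class, tested code; its defaults *are* the study
conditions of the package.

**Climate.** Two contrasting sites: a mild, moist north-eastern lowland
site (`MOIST`: cooler, wetter, drought probability 0.10) and a
drought-prone western site (`DRY`: warmer, drier summers, drought
probability 0.25 with 45 % summer precipitation reduction). Temperature
anomalies are additive Gaussian (interannual s.d. 0.8–0.9 °C, a shared
annual anomaly plus monthly noise); precipitation is gamma-distributed
around monthly normals (CV 0.30–0.35), which keeps P ≥ 0, the standard
weather-generator practice. Drought years multiply May–August precipitation
and add a 1.5 °C summer warming, matching the summer-drought focus of the
analysis. Tmax/Tmin sit a fixed 4.5 °C on either side of Tmean.

**Growth.** Tree t of provenance p in year y has
$w = a(y)\, s_t \exp\!\big((1-m)\,g_{p,y} + m\,L_y + \varepsilon_{t,y}\big)$,
rounded to 0.01 mm and floored at 0.01 mm: a negative-exponential age trend
$a(y)$ with a 30 % asymptote, a tree-level level factor $s_t$
(log-s.d. 0.1), the provenance climate term $g_p = Z w_p$ on standardized
monthly anomalies $Z$, the site's water-limited signal $L$, per-tree noise
(log-s.d. 0.15), and the marginality blending weight $m$. $L$ is the
standardized May–August water balance *capped above* at +0.5 s.d. and
scaled by 0.35 — the Liebig mechanism: wet years cannot push growth past a
ceiling, dry years drag every tree down together. At $m = 0$ growth is pure
provenance response; at $m = 1$ all trees share $L$ exactly.

**Response vectors.** Every provenance shares a common base response
(norm 0.3: growth favoured by growing-season moisture, disfavoured by
summer heat) — the positive within-stand common signal any conifer trial
shows — plus a provenance-specific deviation of norm 0.15 placed on a
semicircle spanned by a spring-temperature and a late-summer-precipitation
pattern. Neighbouring provenances deviate similarly, distant ones
orthogonally. An earlier design without the common base made distant
provenances anti-correlated within a site, which is neither biologically
plausible nor compatible with site-first clustering; the shared-plus-
deviation structure fixes both. No field study quantifies these effect
sizes — the amplitudes are this package's documented choice, picked to give
chronology statistics (glk ≈ 0.8, rbar ≈ 0.5–0.9, MS ≈ 0.5) in the range
reported for real spruce trials, and then frozen.

**Reproducibility.** One master seed spawns per-tree sub-seeds (recorded in
the ground-truth record with every parameter), so a tree's draw survives
reordering and any scenario can be reconstructed bit-for-bit from its
ground truth. `make_fixture_suite()` bundles three canned scenarios —
`"null"` (identical provenances), `"divergent-mild"` (distinct responses,
m = 0.1) and `"uniform-marginal"` (same responses, m = 0.9) — with the mild
and marginal members sharing one climate and one trial seed, forming a
matched pair that differs only in marginality.

**What the generator does not emulate.** No mortality or bark-beetle
dynamics, no spatial block effects, no soil heterogeneity, no
multi-century spans, and climates at different sites are fully independent
(real neighbouring stations share regional signal). Passing tests therefore
show that the *methods* behave as specified under the stated statistical
structure — not that any particular field result is reproduced.

## Problem sizes and numerical choices

The simulation experiments use 10 provenances × 15 trees × 40 years (the
canonical trial layout), 500 seeds for the null rejection rate, 20 matched
seeds for the mild/marginal contrast, and a 5-point marginality grid
averaged over 20 seeds; smaller end-to-end runs in the unit tests use 6
trees. Degenerate inputs fail loudly by policy: constant series cannot be
prewhitened, zero-variance calendar months abort the SPEI fit with the
month named, a provenance with fewer than 4 trees is excluded from pairwise
PCGA with a warning and a missing matrix row. Ties are always broken
deterministically (stable series order for angle ranks, first window for
bioclim quarters, midranks in the rank-sum approximation).

## Known limitations

* The aridity index is a configurable annual summary, not a reconstruction
  of any specific published value; published Walter–Lieth values cannot be
  recomputed without the underlying station data and an explicit formula.
* The GEE/mixed-model stage of a full trial analysis is out of scope: the
  package exports the long-format single-tree RWI table such a fit consumes
  (`export_long_table()`), nothing more.
* Pointer-year analysis offers only the Cropper/intensity-class
  normalization, not the relative-growth-change alternative.
* PCGA reports no bootstrap uncertainty on loadings and applies no
  rotation; the p-value matrix is unadjusted for multiplicity by design.
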