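---
title: "Methods: potential enzyme activities and enzyme lifetimes in subsurface sediments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: potential enzyme activities and enzyme lifetimes in subsurface sediments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedenz)
```

## The measurement and its model

Heterotrophic microbes in marine sediments hydrolyze organic
macromolecules with extracellular enzymes before taking up the products.
`sedenz` implements the full analysis chain for potential-activity assays
of such enzymes in sediment slurries, using small fluorogenic substrate
proxies: a substrate analog is hydrolyzed to release a fluorophore (AMC
from peptidase substrates, MUB from glycosylase and phosphatase
substrates), so fluorescence tracks accumulated product.

The measurement model, which the synthetic-data generator also uses, is

$$F(t) = b + m\,P(t) + \varepsilon, \qquad
  P(t) = v(S)\,t, \qquad
  v(S) = \frac{V_\max S}{K_m + S},$$

with $F$ the fluorescence reading, $(m, b)$ the standard-curve slope and
intercept for the relevant fluorophore, $P$ the product concentration in
the cuvette (µM), and $\varepsilon \sim N(0, \sigma_F)$. The initial
hydrolysis rate $v_0$ is the OLS slope of calibrated concentration on
time; per-gram rates follow from the assay geometry (3 g sediment in
100 ml buffer, 1 ml reactions by default), so a cuvette rate in µM h⁻¹
is multiplied by 100/3 to give nmol (g sed)⁻¹ h⁻¹.

Two assay designs are supported. The single-concentration design measures
potential activity at 400 µM substrate (20 µl of a 20 mM stock in
1000 µl), reported *as is*, without saturation correction — on noiseless
data it underestimates true $V_\max$ by exactly $S/(K_m+S)$, a property
the tests exploit. The saturation design spans 11 levels from 0 to
800 µM and is fitted by Levenberg–Marquardt least squares to the
Michaelis–Menten form, initialized at $V_\max^0 = \max v$ and $K_m^0$ =
the level nearest half-max, with standard errors from the Jacobian-based
covariance. Fits that do not converge or see no positive signal are
flagged, never silently returned.

Every sample is assayed live and after autoclaving (60 min); the
autoclaved control measures how much activity survives sterilization,
i.e. enzyme stability plus any abiotic hydrolysis. "Detectable activity"
is operationalized as a one-sided Welch t-test of live > killed at
α = 0.05; the underlying field protocol does not name a test, and Welch
is the conservative default for triplicates with unequal variances.

## Calibration choices

Standards are matrix-matched: fluorophore dilutions are prepared in the
sample slurry itself, so humic quenching is absorbed into the slope, and
each fluorophore (and, in principle, each sample) gets its own curve.
Back-calculated concentrations below the intercept are kept negative
rather than clipped — truncation would bias the rate regressions; flags
happen downstream at the detection limit. Detection limits can be
empirical (3 × SD of blank rates), model-based
($k\,\sigma_F / (m\,T)$ for horizon $T$, converted to per-gram units), or
supplied as constants when a limit has been established externally.

## Depth profiles and cell-specific rates

Cell counts are rarely measured at exactly the assay depths, so the
package interpolates log10(cells) with locally fitted polynomials
(degree 2 by default, clamped to $n-1$), **separately above and below
the stratigraphic unconformity** at 51.7 mbsf that divides organic-rich
marine muds from organic-poor lacustrine clays. Counts decline roughly
exponentially, hence the log scale; the regimes differ, hence the
segmentation, and perturbing one segment never moves interpolates in the
other. Queries outside a segment's measured span are errors — the
package refuses to fabricate counts by extrapolation. Cell-specific
activities are reported in amol cell⁻¹ h⁻¹
($v / \mathrm{cells} \times 10^9$); this is the dimensionally consistent
unit for (nmol g⁻¹ h⁻¹)/(cells g⁻¹).

## Retention statistics

The fraction of activity retained after autoclaving is
$100 \cdot v_{\text{killed}} / v_{\text{live}}$ per enzyme × depth; it
may legitimately exceed 100 % under noise. Pairs whose live rate is
below $k_{\text{excl}} \times$ detection limit (default
$k_{\text{excl}}=3$) are excluded — "close to the detection limit" is
not a quantified notion in the field protocol, so the multiplier is an
explicit free parameter and both the excluded and included records are
kept. Group summaries use the linear-interpolation quantile convention
(R type 7), recorded in the output, because reported IQRs are otherwise
convention-dependent.

Class differences are tested with Kruskal–Wallis (tie-corrected,
chi-square reference) followed by Conover–Iman pairwise comparisons:
t statistics on mean ranks with the pooled rank variance scaled by
$(N-1-H)/(N-k)$ on $N-k$ degrees of freedom. Holm adjustment is the
default for the pairwise p-values — the choice is conservative and
explicit because adjustment practice varies; unadjusted values are
emitted alongside.

## The enzyme-lifetime lower bound

If enzyme production and decay are in quasi-steady state and all biomass
production were diverted to extracellular enzymes, the standing enzyme
pool divided by biomass production bounds the enzyme turnover time from
below. Writing biomass production as growth efficiency times community
respiration (all in carbon units):

$$\tau \;\ge\; \frac{E}{GE \times R_c}, \qquad
  E = \frac{V_\max}{SA / f_s},$$

where $E$ is the enzyme pool (mol C g⁻¹) inferred from the measured
potential activity $V_\max$ (mol bonds g⁻¹ h⁻¹) and a literature
specific activity $SA$ (mol bonds h⁻¹ per mol enzyme C), $GE$ is growth
efficiency, and $R_c$ is community respiration converted from its
customary nmol C cm⁻³ day⁻¹ to mol C g⁻¹ h⁻¹ via a bulk density
$\rho_s$ (default 1 g cm⁻³ — the conversion is exposed so other
densities propagate exactly). The sorption factor $f_s \ge 1$ encodes
that mineral-bound enzymes are slower than the same enzymes in buffer,
where specific activities are measured; it divides $SA$ and therefore
multiplies the inferred pool and the bound. Every step is an inequality
in the same direction, so $\tau$ is always labelled a lower bound.

Uncertainty is propagated by Monte Carlo: $SA$ (and optionally $GE$,
$R_c$) are drawn from configurable distributions — point mass,
log-uniform (the default reading of "a literature range"), or
log-normal — and $\tau$ is summarized by its median, IQR and 5th/95th
percentiles in days. With point-mass inputs the median collapses to the
closed form exactly; with log-uniform $SA$ it converges to the closed
form at the geometric mean of the bounds, which the tests verify. The
shipped sensitivity scenario combines $f_s = 3$ with $GE = 3.7\%$
against the 10 % baseline; because $\tau \propto f_s/GE$, the median
ratio is exactly $3 \times 0.10/0.037 = 8.108$, often quoted as "about
an order of magnitude".

## What the synthetic generator does and does not emulate

`truth_spec()` fixes ground truth for twelve enzymes (six peptidases,
five glycosylases, alkaline phosphatase) on an eleven-depth grid from
4.5 to 77.9 mbsf: peptidase activity peaking near 11 mbsf and vanishing
below the unconformity, β-glucosidase active only above ~30 mbsf,
phosphatase detectable throughout, class-typical retention fractions,
and per-enzyme $K_m$ values of a few tens to ~1000 µM. Calibration
slopes (1000–1200 RFU µM⁻¹) and fluorescence noise
($\sigma_F$ = 5 RFU) are free parameters of the generator — the
instrument scale is arbitrary; what matters for recovery is the
noise-to-slope ratio, here 0.005 µM of apparent product, small relative
to the µM-scale signals.

Simplifications, by design: product accumulation is linear (no substrate
depletion) unless the integrated-rate mode is requested, noise is
homoscedastic Gaussian (the cuvette protocol's noise structure is not
characterized; this is an assumption, not an inference), and there is no
sorption kinetics, quench drift, or temperature dependence of noise.
Passing recovery tests on these data therefore demonstrates estimator
correctness, not robustness to every field artifact.

## Numerical and testing choices

Rates use all timepoints by OLS by default; an `initial-window` mode
maximizes r² over prefixes (≥ 3 points) for late-time nonlinearity.
Degenerate inputs have defined behaviour throughout: constant series
give $v_0 = 0$ with r² reported as 0; all-tied rank tests return
$H = 0, p = 1$; zero-variance Welch comparisons return $p = 1$ when
means agree. Temperature projection uses the exponential Q10 form
$Q_{10}^{\Delta T/10}$; note that for $\Delta T = 12$ °C and
$Q_{10} = 2$ this gives 2.30, although a factor of 2.4 circulates in the
literature for the same adjustment — the package implements the
exponential form.

Test and acceptance problem sizes were chosen once for statistical
resolution at interactive runtimes: 200 simulated saturation curves
(triplicates, noise at 5 % of $V_\max$) for the 3-SE recovery rate, 2000
null replicates with 20 observations per group for the empirical size of
the Kruskal–Wallis test (at triplicate-scale groups the chi-square
reference is visibly conservative, which is a property of the test, not
of this implementation), 10⁵ draws for Monte-Carlo medians, and a
49-cell assay campaign for the retention recovery check.

## Limitations

The lifetime bound inherits every caveat of its inputs: literature
specific activities are measured on purified enzymes in buffer, growth
efficiencies in the deep subsurface are bounded rather than measured,
and attributing *all* biomass production to one enzyme makes the bound
deliberately loose in the conservative direction. The pipeline does not
model inhibition, multi-enzyme substrate overlap, integrated
(substrate-depleting) Michaelis–Menten fitting, or error propagation
from cell counts into cell-specific rates.
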