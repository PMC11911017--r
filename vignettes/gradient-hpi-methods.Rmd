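---
title: "Highest-probability intervals on environmental gradients: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Highest-probability intervals on environmental gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichegradient)
```

## The question

The environmental center-periphery (abundant-center) hypothesis holds
that a species occurs most frequently near the center of its
environmental niche, declining toward the edges. `nichegradient` tests
this one gradient at a time. Working unidimensionally is sufficient
because displacing the preferred position by $d_i$ on any single
gradient displaces it by $\sqrt{\sum_i d_i^2}$ from the multidimensional
niche centroid — a single nonzero $d_j$ moves the position exactly
$|d_j|$ away (`centroid_displacement_distance()` implements this small
geometric fact, and the tests verify it).

For each species-variable combination the package asks two things:

1. Does the interval on the gradient where occurrence probability is
   highest contain the midpoint of the species' observed range?
2. If not, could the shorter tail of the distribution ever be extended
   far enough — by collecting more data — to make the mode sit at the
   midpoint, given the variable's *natural truncation* (precipitation
   cannot be negative, a precipitation ratio cannot exceed 1)?

## The per-combination procedure

Given a sample of $n$ raw values of one variable at one species'
collection sites, `run_combination()` executes the following stages.

**Binning.** The default rule (`fd_as_written`) uses bin width
$w = 2\,\mathrm{IQR}/n^{1/3}$, the first edge at the sample minimum and
$K = \lceil(\max-\min)/w\rceil$ bins. Quartiles use linear interpolation
(R's default type 7); this convention is fixed and documented because
different quartile definitions shift $w$ slightly. An alternative
(`sturges_r`) takes $K = \lceil\log_2 n\rceil + 1$ equal-width bins on
"nice" edges. Bins are half-open $[e_i, e_{i+1})$ with the last bin
closed so the maximum is counted exactly once. A zero IQR (heavily tied
data) degenerates the default width; the Sturges rule is then used and
the fallback recorded in the combination's flags.

**Proportions and simultaneous confidence intervals.** Each bin count
is divided by $N = n$ to give a proportion, interpretable as an
occurrence probability at the bin midpoint. Exact Clopper–Pearson
intervals are computed for each proportion at the Bonferroni-adjusted
level $\alpha_{adj} = \alpha/k$ with $\alpha = 0.05$. The divisor $k$
defaults to the number of bins $K$; `bonferroni_k_rule = "n_marked"`
exposes the alternative of counting only the marked points (in which
case the intervals are rebuilt after a first marking pass and the
marking repeated once). The choice matters little in practice — CP
intervals widen slowly in $\log k$ — but it is genuinely ambiguous what
"number of groups compared" should count, so both are available and the
rule used is written to the run metadata.

**Exclusion and the omnibus test.** Two bins differ significantly when
their simultaneous intervals are strictly disjoint; intervals that
merely touch count as overlapping (not significant), since
*non-overlap* is the criterion. If no pair anywhere in the histogram is
significant, the combination carries no usable shape information and is
excluded (flagged, never silently dropped). Independently, a Pearson
chi-squared goodness-of-fit test against equal expected counts $N/K$ is
reported. Uniformity is the natural omnibus null here: every specimen
falls in exactly one bin, so "no differences among the proportions"
means equal expected occupancy. This is an interpretive choice — the
omnibus test is reported as evidence strength, and plays no role in the
exclusion decision, which uses only the pairwise intervals.

**Marking rules and polynomial degree.** (i) Mark the highest
proportion; ties resolve to the leftmost bin — any tied bin would be
admissible, so a deterministic rule is fixed for reproducibility.
(ii) From the highest point outward on each side, repeatedly mark the
nearest bin whose interval does not overlap that of the most recently
marked bin on that side. (iii) Mark both endpoint bins, anchoring the
regression at the range limits and preventing endpoint extrapolation.
(iv) The number of polynomial terms (including the intercept) equals
the number of marked points, so the degree is one less. A configured
per-combination override of ±1 term (`degree_overrides`) reproduces
manual adjustments where a fit behaves erratically.

**Polynomial logistic regression.** Bin $i$ is treated as a binomial
observation of $c_i$ successes in $N$ trials at the bin midpoint
$x_i$, and

$$p(x) = \frac{1}{1 + \exp(-(b_0 + b_1 x + \dots + b_D x^D))}$$

is fitted by maximum likelihood (IRLS via `stats::glm.fit`, at most 100
iterations, deviance tolerance $10^{-8}$). Using $N$ as the trial count
at every bin matches the confidence-interval construction but makes the
$K$ observations non-independent; that is accepted because the curve is
used only as a smooth descriptor of density shape — no inference is
ever performed on its coefficients. The predictor is affinely mapped to
$[-1, 1]$ before the polynomial expansion: raw powers of, say,
elevations up to 2800 m at degree 5 would destroy the conditioning of
the design matrix. Coefficients are reported on both scales and the
tests verify the two parameterizations evaluate to the same curve
within $10^{-6}$. If the fit fails to converge or yields non-finite
coefficients, the degree is reduced by one and refitted, each reduction
flagged — a deterministic stand-in for manual visual adjustment.

**Highest-probability interval (HPI).** The area under $p$ over the
sample range $[x_{min}, x_{max}]$ can be read as an unnormalized
probability density; because the HPI is defined by a *relative*
fraction of area, normalization cancels. The HPI is the contiguous
interval around the global mode containing 25% of the total area at
the highest densities: bisect on a density threshold $c$, take the
connected component of $\{x : p(x) \ge c\}$ containing the mode (edges
refined by root finding), and integrate until the component's area is
$0.25$ of the total within $10^{-4}$. For a unimodal curve this is the
shortest interval holding that mass, which the tests verify against an
exhaustive grid scan. When the mode lies on a range endpoint the
component is one-sided from that endpoint. The connected-component
construction (rather than a union of disjoint high-density regions) is
deliberate: the interval is meant to be a single preference region, and
the rare two-peak fits are caught by the mass-shortfall flag. The 25%
mass is an arbitrary but reasonable convention (`hpi_mass` exposes it).

**Relative distance.** With $x_{mid} = (x_{min}+x_{max})/2$ and HPI
$[x_L, x_U]$,

$$\mathrm{relDis} = \begin{cases}
(x_L - x_{mid})/(x_{max}-x_{min}) \cdot 100\% & x_{mid} < x_L\\
0 & x_L \le x_{mid} \le x_U\\
(x_U - x_{mid})/(x_{max}-x_{min}) \cdot 100\% & x_{mid} > x_U
\end{cases}$$

positive when the interval lies above the midpoint, negative below; the
mathematical domain is $[-50\%, 50\%]$, the extremes approached only as
the interval collapses onto a range endpoint. The tests sweep admissible
positions and check the bounds and the mirror antisymmetry
$x \mapsto -x \Rightarrow \mathrm{relDis} \mapsto -\mathrm{relDis}$.

**Symmetry and truncation.** With tail lengths
$d_1 = \min(\mathrm{mode}-x_{min},\, x_{max}-\mathrm{mode})$ and
$d_2 = \max(\cdot)$, symmetry of the mode about the (possibly expanded)
limits requires moving the short-side limit to $\mathrm{mode} \pm d_2$.
The signed expansion factor is $\pm d_2/d_1$ (positive rightward),
undefined when the mode sits exactly on an extreme ($d_1 = 0$; the true
mode is unknown beyond the truncation). Classification per combination:
*centered* when relDis $= 0$ (decided by the HPI containing the
midpoint, not by $d_1 = d_2$ — the two notions differ);
*undefined_d1_zero* when $d_1 = 0$; *expansion_impossible* when the
required limit falls outside the variable's natural domain;
*expansion_possible* otherwise — note a truncated variable remains
expandable while the required limit does not reach the bound, and
boundary equality counts as possible because the bound itself is
attainable. The shipped domain registry marks 11 variables nonnegative,
the summer-to-total precipitation ratio unit-bounded, and the three
temperature variables plus soil pH unbounded. Soil pH is chemically
bounded, but its extremes never act as a truncating bound on real
gradients, so the registry treats it as unbounded; the registry is a
YAML file and can be edited.

## Study-level aggregation

`run_study()` iterates the full species-by-variable grid (each
combination failure is captured, never fatal), then pools all specimen
rows into one Pearson correlation screen across variables — a check
that the gradients are not largely redundant; significance of $r$ is
deliberately not tested — and tallies verdicts: centered/below/above
counts, per-species centered percentages, and an exact two-sided sign
test of below vs. above counts against probability one half, defined as
twice the smaller binomial tail capped at 1 (for a symmetric null this
coincides with the standard exact test).

## The synthetic generator

`synthetic_spec()`/`generate_study()` produce occurrence tables with
known ground truth so every stage is testable without external data.
Four families cover the behaviours that matter: normal
(symmetric interior peak), gamma (skewed, naturally nonnegative —
emulating precipitation-like variables), scaled beta (unit-bounded
ratio), and a two-component normal mixture (bimodality, the pathological
case). Sampling is rejection-truncated to the variable's domain;
acceptance below 1% is an error rather than a silent distortion. Sample
sizes default to the 70–321 range typical of per-species herbarium
collections. The truth sidecar stores the generating density's mode and
25% highest-density interval *restricted to the sample's observed
range* — the quantity the pipeline estimates — computed by direct
numeric integration with a density-sorting construction that shares no
code with the pipeline's threshold bisection. Correlated variables use
a Gaussian copula with inverse-CDF marginals; this is a testing device
for the correlation screen, not a biological model, and the copula path
uses inverse-CDF truncation because rejection would distort the target
correlation.

What the generator does *not* emulate: spatial autocorrelation among
collection sites, uneven sampling effort along gradients, measurement
error in the environmental layers, or niche interactions between
variables. Passing recovery tests therefore shows the estimator chain
is correct under clean unimodal sampling — not that field data meet
those conditions.

## Numerical choices and problem sizes

* Grids: density evaluation, mode search and interval search use 2001
  points (configurable, minimum 101, forced odd for Simpson
  integration); component areas use 801-point Simpson per bisection
  step; threshold bisection caps at 50 iterations, tolerance $10^{-4}$
  on the achieved mass fraction.
* Mode refinement uses golden-section/parabolic search in the grid cell
  bracketing the argmax; an endpoint mode is snapped to the endpoint
  when the argmax falls within one grid cell of it and the curve is
  monotone into it.
* The test suite's simulation sizes are chosen to give stable
  verdicts at modest cost: $10^4$ replicates for interval coverage and
  test size, 200 replicate pipeline runs at $n = 300$ for mode/side
  recovery, and a single 12 × 16 grid (sample sizes 70–321) for the
  structural checks.
* Reruns with identical inputs and configuration are deterministic end
  to end, including byte-identical result files.

## Known limitations

* The polynomial logistic curve can oscillate at high degree when many
  bins are marked; the degree-reduction ladder and the ±1-term override
  are blunt instruments compared to human inspection of a specific fit.
* The HPI of a genuinely bimodal density is forced contiguous; the
  mass-shortfall flag marks such combinations but the interval itself
  remains a single component around the global mode.
* The binomial weighting of bins (all at $N$ trials) reproduces the
  interval logic but is not the only defensible likelihood for binned
  proportions; coefficients can differ in late decimals from other
  weightings, which is immaterial to the shape-derived quantities used
  downstream.
* Expansion feasibility is purely mathematical: whether a species could
  biologically tolerate the required parameters is a separate question
  the package does not address.
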