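# nichegradient

Statistical tests of the environmental center-periphery
(abundant-center) hypothesis, one environmental gradient at a time.

Ecologists have long asked whether a species occurs most frequently at
the center of its niche. `nichegradient` answers this per species and
per environmental variable: from the raw values of one variable at a
species' collection sites it derives a continuous
occurrence-probability curve, extracts the interval where 25% of the
occurrences are concentrated at the highest probability, measures how
far that interval sits from the midpoint of the observed range, and —
the conceptual core — classifies whether symmetry around the mode is
even *attainable*, given the variable's natural mathematical domain
(precipitation cannot be negative; a precipitation ratio cannot exceed
1). Natural truncation turns out to make a centered distribution
impossible for many species-variable combinations, which conditions the
hypothesis rather than merely refuting it.

## The method in brief

For a sample of n values of one variable at one species' sites:

1. **Histogram**: bin width `2·IQR/n^(1/3)`, first edge at the minimum.
2. **Proportions + CIs**: bin counts / n, with exact Clopper–Pearson
   intervals at the Bonferroni-adjusted level `α/k` (α = 0.05,
   k = number of bins), plus an omnibus chi-squared test. Combinations
   with no significantly different bin pair are excluded.
3. **Marking rules → degree**: mark the highest bin, then outward each
   side every bin whose CI is disjoint from the last marked one, then
   both endpoints; the polynomial degree is the number of marked points
   minus one.
4. **Polynomial logistic regression**:
   `p(x) = 1/(1 + exp(−(b₀ + b₁x + … + b_D x^D)))`, fitted by maximum
   likelihood on the binned proportions.
5. **Highest-probability interval (HPI)**: the contiguous interval
   `[xL, xU]` around the mode holding 25% of the area under p(x)
   (one-sided when the mode sits on a range endpoint).
6. **Relative distance**: `relDis = 0` if the midpoint
   `(xmin+xmax)/2` lies in the HPI, otherwise the signed distance from
   the midpoint to the nearest HPI limit in % of the range
   (domain −50%…50%).
7. **Truncation/symmetry**: with tail lengths d1 ≤ d2 around the mode,
   symmetry requires moving the short-side limit to `mode ± d2`; the
   expansion factor is `±d2/d1`. The required limit is checked against
   the variable's natural domain: `centered`, `expansion_possible`,
   `expansion_impossible`, or `undefined_d1_zero` (mode on an extreme).

A synthetic-data module generates occurrence tables from known
unimodal, skewed, truncated or bimodal densities with an analytically
known mode and an independently computed true 25% interval, so the
whole chain is testable without any download.

## Worked example

```r
library(nichegradient)

# a skewed, naturally nonnegative gradient (gamma, mode at 600)
spec <- synthetic_scenario("skewed_interior",
                           species = "Inga_synthetica",
                           n = 300, seed = 42)
g   <- generate_sample(spec)
res <- run_combination(g$sample, spec$domain)
print(res)
#> Combination: Inga_synthetica / mean_annual_precipitation (n = 300)
#>   degree 3; mode 634.49; HPI [483.73, 791.92]
#>   relDis -26.56% (below); category expansion_impossible
```

Reading this: the fitted curve peaks at 634 mm; the quarter of the
occurrences with highest probability sits between 484 and 792 mm, which
is 26.6% of the observed range *below* its midpoint; and making the
mode symmetric would require extending the lower limit to a negative
precipitation — impossible, so this combination can never satisfy the
center-periphery expectation, no matter how much more data is
collected.

The classic desk case — a species whose mean annual temperature runs
17.5–27.5 °C with the mode at 26.02 °C:

```r
lim <- required_symmetric_limit(17.5, 27.5, 26.02)
lim$required_limit                                    # 34.54 (°C)
expansion_factor(lim$d1, lim$d2, lim$expansion_side)  # 5.76
```

The upper limit would have to reach 34.54 °C — an expansion 5.76 times
the observed upper tail — for the mode to sit at the midpoint.

Full studies run over a species × variable grid:

```r
tab   <- generate_study(specs, seed = 1)   # or load_occurrence_table(path)
study <- run_study(tab, load_variable_domains())
print(study)                                # tallies, sign test, |r| screen
write_study_results(study, "out/")          # results.csv, symmetry.csv, ...
```

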