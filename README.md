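# commsync

Multi-scale analysis of **synchrony versus compensation** in multispecies
abundance time series.

Long-term monitoring of a community — e.g. monthly bird counts in a wetland
reserve over several decades — raises a basic dynamical question: do species
fluctuate together (synchrony), or do increases in some offset declines in
others so that the community total is buffered (compensation)? The answer
can differ between seasons, between taxonomic or functional groups, between
management periods, and between temporal scales (a community can be
synchronous at the annual scale yet compensatory over five-year swings).
commsync implements a complete, tested pipeline for this question; it is
aimed at quantitative ecologists working with long count series.

## Statistics

**Year-to-year synchrony index.** For n species with seasonal-mean yearly
abundances X_i,

    eta = (1/n) * sum_i Corr(X_i, sum_{j != i} X_j)

the mean Pearson correlation between each species and the rest of the
community: -1 = perfect compensation (constant total), +1 = complete
synchrony, 0 = independence; independent of richness n, and equal to the
plain correlation between two summed groups in the two-group case.
Significance comes from surrogate nulls that erase cross-correlation while
preserving each series' own structure — circular **toroidal shifts** (exact
value multiset and circular autocorrelation) within guilds, **IAAFT**
surrogates (exact value distribution, near-exact spectrum) between two
groups — with count p-values (r+1)/(n+1) and Benjamini–Hochberg control over
the 2-season x 3-period test family.

**Wavelet modulus ratio.** With w_i(t, s) the continuous Morlet wavelet
transform of species i and G_s a Gaussian kernel of width s in time,

    rho(t, s) = [G_s * | sum_i w_i(., s) |](t) / [G_s * sum_i | w_i(., s) |](t)

lies in [0, 1] at every time t and scale s: smoothed modulus of the
coefficient sum (total community variation) over smoothed sum of moduli
(summed species variation). rho = 1 marks scale-specific synchrony, rho near
0 compensation. Pointwise significance contours come from IAAFT surrogates
of every species; cells inside the cone of influence are masked.

**Community simulator.** A seasonally forced Ricker/Lotka–Volterra model
with two guilds responding to a shared environmental driver with equal or
opposed sign generates communities of known regime, used to calibrate the
tests (rejection rate under the null, sign recovery under compensation,
robustness to exact zeros and skewed abundance distributions).

## Worked example

Simulate a two-guild community in the compensatory regime (opposed driver
responses), then run the year-to-year track at every grouping level:

```r
library(commsync)
cfg <- simulation_config(n_species_per_guild = 5, n_months = 300, seed = 1)
m <- simulate_forced_community(cfg)     # 300 months x 10 species
scheme <- setNames(sub("_.*", "", colnames(m)), colnames(m))
run <- analysis_config(input = m, scheme = scheme, n_surrogates = 199,
                       cut_year = 2012, seed = 1)
res <- run_eta_track(run)
res[res$period == "all", ]
```

```
  grouping season period    eta n_units n_years p_greater p_less p_two_sided p_adjusted bh_reject
 community   warm    all -0.287      10      25     0.985  0.020        0.04      0.060      TRUE
 community   cold    all -0.418      10      24     1.000  0.005        0.01      0.030      TRUE
 within_g1   warm    all  0.800       5      25     0.005  1.000        0.01      0.010      TRUE
 within_g1   cold    all  0.920       5      24     0.005  1.000        0.01      0.010      TRUE
 within_g2   warm    all  0.900       5      25     0.005  1.000        0.01      0.010      TRUE
 within_g2   cold    all  0.811       5      24     0.005  1.000        0.01      0.010      TRUE
   between   warm    all -0.901       2      25     1.000  0.005        0.01      0.012      TRUE
   between   cold    all -0.938       2      24     1.000  0.005        0.01      0.012      TRUE
```

The structure built into the simulator is recovered: strong synchrony
*within* each guild (eta 0.80–0.92, significant against the toroidal null),
strong compensation *between* the summed guilds (eta about -0.9 against the
IAAFT null), and mild net compensation at the whole-community level. The
wavelet track resolves the same community in time and scale:

```r
w <- wavelet_modulus_ratio(m)
w
#> Wavelet modulus ratio map: 300 times x 63 scales, 10 units
#>   unmasked cells: 15312; rho range 0.032..0.973
```

`run_wavelet_track(run)` adds the IAAFT significance masks and writes
`rho_<subset>.tsv` / `masks_<subset>.tsv` per subset. Real data enter the
same pipeline as delimited text (`year, month, species, count`) via
`read_count_records()` / `build_monthly_matrix()`, with optional
species-to-group and body-mass tables.

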