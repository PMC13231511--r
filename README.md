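# fightdyn

Fight dynamics from line-mounted jerk accelerometry.

When a fish is hooked in a rod-and-reel fishery, the ensuing fight drives
its physiological disturbance: burst swimming forces anaerobic metabolism,
plasma lactate accumulates and blood pH falls, and together these shape
whether a released fish recovers. Accelerometers attached to the fishing
line record the fight non-invasively. The tags emulated here log, every
2 s, mean jerk (rate of change of acceleration, g s⁻¹) on three axes —
X along the line, Y and Z perpendicular — plus an activity vector sum
(ActVSum), the vectorial jerk magnitude bounded to [0, 2] g s⁻¹.

`fightdyn` is a toolbox for researchers and fishery managers who want to
turn such recordings into quantitative fight phenotypes and physiological
predictions:

* **Summary fight metrics** per fish: mean ActVSum and its CV, total
  effort (cumulative ActVSum), discrete bursts (maximal runs strictly
  above 1.25 g s⁻¹, by run-length encoding), early/late intensity
  (means over the first/last ⌊n/3⌋ samples), and a fatigue index
  (max(0, −slope) of the OLS fit of ActVSum on sample index from the
  first global peak onward).
* **Dynamic time warping (DTW)** dissimilarities between whole fights
  under 12 processing variants ({raw, 4-s high-pass, first derivative} ×
  {X, Y, Z, XYZ}), using the symmetric step pattern with double-weighted
  diagonal:
  g(i,j) = min{ g(i−1,j)+d, g(i,j−1)+d, g(i−1,j−1)+2d }, g(1,1) = d₁₁.
* **Ordination and clustering**: PCA of the z-scored metric matrix or
  classical scaling (PCoA) of each DTW matrix, three dimensions retained;
  Ward ("ward.D", un-squared distances) agglomeration with the gap
  statistic (uniform reference, bootstrap SE, one-SE selection rule)
  choosing the number of clusters.
* **Bayesian physiology linkage**: a bivariate Gaussian regression of
  (normalized blood pH, normalized plasma lactate) on the three retained
  dimensions plus species, z-scored body mass and water temperature (and
  fight duration for the summary pipeline), with estimated residual
  correlation ρ, MCMC sampling, split-chain R̂ and ESS diagnostics,
  10-fold cross-validation IC, Bayesian R², envfit-style vector fitting
  (999 permutations) and back-transformed marginal effects.
* A **13-pipeline comparison** table ranked by K-fold IC, and a seeded
  **synthetic capture-event generator** so every stage is testable
  without field data.

Body mass is estimated from fork length and girth (cm) as
Mass = FL × girth² / 27120 (kg).

## Worked example

```r
library(fightdyn)

ds <- simulate_dataset(sim_scenario(seed = 42))
ds
#> <capture_dataset> 14 fish (11 chinook, 3 coho)
#>   fight durations 62-172 s; water temp 12.0-17.8 C

fight_metrics(ds$traces[["fish401"]])
#>   fish_id fight_duration mean_actvsum cv_actvsum total_effort n_bursts
#> 1 fish401            164    0.8838335  0.5681248     72.47435        9
#>   early_intensity late_intensity early_late_ratio fatigue_index
#> 1       0.9231515       1.026363        0.8994398             0
```

Fish 401 fought for 164 s at a mean intensity of 0.88 g s⁻¹, spent a
cumulative 72.5 g s⁻¹ of effort in 9 discrete bursts, and fought slightly
harder late than early (ratio 0.90); no post-peak decline was detectable
(fatigue index 0).

```r
dtw_align(c(0, 1, 2), c(0, 2))
#> <dtw_alignment> 3 x 2: distance 1.0000 (normalized 0.2000), path 3 steps

ord <- pcoa_ordination(pairwise_dissimilarity(ds, "highpass", "Y"))
ord
#> <fight_ordination> PCOA, 14 fish, 3 dims retained
#>   variance explained: 23.4%, 13.8%, 12.3% (Dim1-3 cumulative 49.4%)

res <- run_pipeline(ds, "hp_Y", fit_settings(reduced = TRUE), seed = 1)
res$artifacts$fit
#> <linkage_fit> bivariate Gaussian, 14 fish, 6 predictors, 2 x 500 draws
#>   residual correlation rho = -0.26 [-0.76, 0.43]
#>   significant dims: none; significant covariates: none
```

The high-pass-Y pipeline's three principal coordinates capture 49.4% of
the DTW dissimilarity structure; in this particular 14-fish simulation no
coefficient's 95% credible interval excludes zero (expected at n = 14 —
intervals are wide), and the residual correlation between the two
responses is weak with a wide interval. `compare_all(ds, seed = 1)` runs
all 13 pipelines and returns the comparison table sorted by K-fold IC.

A thin command-line front-end ships in `inst/cli/fightdyn`
(`simulate`, `metrics`, `dtw`, `compare` subcommands).

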