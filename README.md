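# perdixsel

Habitat electivity analysis for farmland birds surveyed on a grid of survey
squares, with accelerated-bootstrap inference and a synthetic-landscape
generator for end-to-end validation.

Farmland birds such as the grey partridge are mapped in winter (coveys, > 2
birds) and spring (territories) inside survey squares whose land cover is
mapped each survey year. The question the package answers: which habitat
types do the birds select or avoid, relative to what each square offers, and
how does that interact with a landscape that fragments and accumulates
infrastructure over the years? It is written for quantitative ecologists who
want a tested, reproducible version of this analysis — and for anyone who
needs a use/availability electivity pipeline whose every stage can be
verified against synthetic ground truth.

## The statistic at the core

Use `r_i` is the habitat composition of 3.14 ha circular plots (100 m radius)
around bird locations; availability `n_i` comes from reference plots at
square centres (averaged over squares, or kept per square). For `m` available
habitat types:

```
alpha_i = (r_i / n_i) / sum_j (r_j / n_j)        Manly's selection index
eps_i   = (m alpha_i - 1) / ((m - 2) alpha_i + 1)   Chesson's electivity
```

`eps` lives in [-1, 1]: 0 is use proportional to availability, +1 exclusive
use, -1 complete avoidance, comparable across units that see different
numbers of available types. Per habitat, the mean of unit-level
electivities gets a bias-corrected accelerated (BCa) bootstrap confidence
interval (1500 resamples); selection is significant only when both interval
endpoints share a sign, and habitats observed in fewer than 7 units are
reported `not_tested`. Landscape change is summarised by plot-sampled patch
counts and sizes, infrastructure growth (with a Pearson trend correlation),
Shannon–Wiener diversity of used vs available habitat, and distances to the
nearest infrastructure by season.

## Worked example

The repository is organised as an analysis workflow: numbered scripts under
`analysis/` drive the package functions in `R/` and write tables under
`results/`.

```sh
Rscript analysis/01_simulate.R          # synthetic 20-square, 3-year study
Rscript analysis/02_electivity.R        # electivity + BCa summaries
Rscript analysis/03_recovery.R          # pipeline vs analytic ground truth
Rscript analysis/04_landscape_change.R  # change tables, diversity, distances
```

`analysis/03_recovery.R` prints (seed 1):

```
recovered vs true electivity (winter units, first scenario year):
    habitat true_epsilon mean_epsilon    error ci_low ci_high n_units significance sign_match
     meadow        0.441        0.419 -0.02192  0.401   0.435      40    preferred       TRUE
       road        0.224        0.219 -0.00584  0.182   0.245      40    preferred       TRUE
 field_path       -0.103       -0.107 -0.00462 -0.149  -0.069      40      avoided       TRUE
   vineyard       -0.189       -0.193 -0.00368 -0.231  -0.158      40      avoided       TRUE
     arable       -0.286       -0.275  0.01068 -0.295  -0.255      40      avoided       TRUE
   hedgerow       -0.516       -0.489  0.02667 -0.519  -0.458      40      avoided       TRUE

max |error| = 0.027; sign agreement on strong (|eps| >= 0.4) types: yes
```

Every recovered mean electivity sits within 0.03 of the value implied by the
generator's placement weights, and each strong preference (meadow) or
avoidance (hedgerow) is classified with the correct sign. The landscape layer
(`analysis/04_landscape_change.R`) shows the configured trends coming back
out of the maps — patches sampled per 3.14 ha plot rising 3.7 → 7.8 while
mean patch area falls 6.2 → 1.6 ha across the three survey years, total
infrastructure growing 102 → 150 ha (Pearson r = 0.98 against year), and
winter birds sitting nearer infrastructure (median 27.8 m) than spring birds
(41.3 m).

To analyse your own data, point `analysis_config()` at an observation CSV
(`obs_id, square_id, x, y, year, season, unit_kind, group_size`) and a
directory of per-square ASCII-grid maps with CSV legends (GeoJSON polygon
input is also supported), then call `run_analysis()`; it validates inputs,
runs the per-year electivity analysis at square/individual/territory level,
and writes the full report bundle with a run-metadata JSON.

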