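# retinomap

Activity-dependent development of the primary visual cortex (V1)
retinotopic map, for computational neuroscientists studying cortical map
formation.

In primates, the retinotopic map of V1 lays **eccentricity** (`r`, degrees
from fixation) and **meridional angle** (`theta`) out along roughly
orthogonal cortical axes, an organization classically approximated by the
complex-logarithmic transform

```
u + iv = log(x + iy + a),      x + iy = r e^{i theta},   a > 0
```

`retinomap` simulates how such a map can *develop* from activity alone:

* a **Kohonen SOM** trained on rotated and dilated rectangular bars
  (9 rotations x 16 dilations = 144 binary stimuli) self-organizes the two
  stimulus features onto locally orthogonal output axes;
* a **LISSOM** cortical sheet (25x25 retina, 48x48 cortex; afferent plus
  modifiable lateral excitatory/inhibitory connections, multi-step
  settling, normalized Hebbian learning) — constrained by the complex-log
  boundary `u = log sqrt(a^2 + (a tan v)^2)` and seeded with a coarse
  initial retinotopy — develops a genuine point-to-point retinotopic map,
  which the package validates against the analytic transform;
* **retinal lesion** experiments on the trained sheet demonstrate lateral-
  connection plasticity: the cortical lesion projection zone (LPZ) shrinks
  during recovery training and disappears when it fits within the
  excitatory radius.

The model covers the central 4 degrees of one hemifield. Species presets
change the boundary constant (`a` = 1 squirrel monkey, 2.5 owl monkey,
4 cat).

## Worked example

```r
library(retinomap)

## published radius arithmetic: sheet units -> grid units -> cortex mm
sheet_to_grid(0.55, 48)        # 26.4  (inhibitory radius, grid units)
grid_to_cortex_mm(26.4)        # 9.9   (mm of cortex)
count_excitatory_neighbors(1.44)  # 8   (Moore neighborhood)

## the complex-log boundary leaves ~75% of the sheet available
m <- make_boundary_mask(c(48, 48), map_params(a = 1))
mean(m)                        # 0.7456597

## train a LISSOM briefly and inspect it
bars <- enumerate_bar_set(c(25, 25))   # 144 rotated/dilated bars
st <- init_lissom(lissom_params(rng_seed = 1))
st <- train_lissom(st, bars, 20)
tail(st$metrics, 3)[, 1:5]
#    iteration mean_activity dW_aff dW_exc dW_inh
# 18        18        0.0587 2.2518 0.7949 1.0333
# 19        19        0.1823 4.0107 1.5992 1.9381
# 20        20        0.1182 2.7572 1.0110 1.2451

y <- settle(st, make_bar(c(25, 25), bar_spec(40, 15)))
sum(y > 0.1)                   # 221 active cortical cells for this bar
```

`mean_activity` is the average settled activity of in-mask neurons for the
presented bar; `dW_*` are the Frobenius norms of each projection's weight
change, which decay as the map stabilizes. After a full 900-iteration run,
`probe_point_map()` + `meridional_preference()` yield the developed map;
`map_monotonicity()` reports Spearman correlations of preferred
eccentricity vs. cortical column and preferred meridional angle vs. row
(|rho| >= 0.8 for both, ~0.97 and ~0.87 in the default seeded run), and
`rms_vs_complexlog()` scores responses against the analytic reference.

End-to-end experiments (stimuli -> training -> analysis -> CSV/PNG
artifacts) run through the config-driven runner:

```r
run_experiment(experiment_config("lissom_bounded", seed = 7, out_dir = "runs/demo"))
```

or the CLI in `inst/scripts/retinomap`:

```sh
Rscript inst/scripts/retinomap run --experiment lissom_species --out runs/species
Rscript inst/scripts/retinomap stimgen --kind bars --grid 81x81 --out stimuli/
```

Experiments: `som_basic`, `som_bounded`, `lissom_bounded`,
`lissom_unbounded`, `lissom_species`, `lissom_lesion`.

## Package layout

| module | contents |
| --- | --- |
| `R/stimuli.R` | bars, rings, point probes, lesioned discs; PGM/CSV I/O |
| `R/complexlog.R` | forward map, boundary curve/mask, image transform, species presets |
| `R/som.R` | Kohonen SOM with boundary mask, annealing, orthogonality/stability statistics |
| `R/lissom.R` | LISSOM sheet: settling, normalized Hebbian learning, radius growth, lesions |
| `R/analysis.R` | point-probe map, meridional preference/selectivity, RMS vs theory, angle histograms, LPZ |
| `R/runner.R` | config-driven experiments with self-describing run directories |

The methods vignette (`vignettes/retinomap-methods.Rmd`) documents the
model equations, every calibrated default (initial radii, growth
schedules, retinotopy jitter), the estimator choices, and known
limitations.
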