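# driftreg

Non-rigid point-set registration for 2-D contours — organ boundaries
extracted from CT/MRI slices, shape-benchmark curves, any ordered or
unordered planar point clouds — by a structure-informed Coherent Point
Drift (CPD) algorithm.

Classical CPD treats the model set $Y = \{y_m\}_{m=1}^M$ as Gaussian-mixture
centroids fit to the scene set $X = \{x_n\}_{n=1}^N$ by EM, moving the
centroids through a smooth kernel displacement field $T(Y) = Y + GW$
(with $G_{ij} = e^{-\lVert y_i-y_j\rVert^2/2\beta}$) and absorbing clutter
in a uniform component of weight $\omega$. It has two practical weaknesses:
correspondence is driven by Euclidean distance alone, and $\omega$ must be
guessed in advance. `driftreg` implements both remedies inside one engine:

* **shape-context weighting** — each membership is multiplied by
  $C_{nm} = \exp\!\big(-\frac{1}{2\gamma}\sum_k
  \frac{[h_n(k)-h_m(k)]^2}{h_n(k)+h_m(k)}\big)$, the exponentiated $\chi^2$
  distance between rotation/translation/scale-invariant log-polar
  histograms, so structurally similar points attract each other even when
  far apart;
* **automatic outlier ratio** — $\omega$ is re-estimated every iteration
  from its exact minimizer $\omega^{\text{new}} = 1 - \sum_{mn}P_{mn}/N$,
  damped by a $1/t$ learning ratio.

Switching both off (`structure = FALSE, auto_omega = FALSE`) yields the
plain CPD baseline, which the test suite verifies per-iteration against an
independent scalar transcription of the textbook updates. The package also
ships a Chui-Rangarajan-style synthetic degradation generator (smooth warp,
Gaussian jitter, contiguous occlusion, uniform clutter) with exact ground
truth, the standard evaluation metrics (point/image RMSE,
recall/precision/F1, recall-accuracy curves), degradation and
outlier-ratio sweeps, and a command-line interface.

## Worked example

Generate the clutter benchmark case at the published cardinalities (98
model points, 196 scene points at outlier-to-data ratio 1.0), register, and
evaluate:

```r
library(driftreg)

case <- make_benchmark_case("outlier", 1.0, template = "fishlike",
                            n_points = 98, seed = 5)
case
#> <benchmark_case: outlier level 1 on 'fishlike' (98 model / 196 scene points, 98 truth pairs)>

fit <- cpd_register(case$scene, case$model,
                    omega0 = default_omega0("outlier", 1.0))
glance(fit)
#> # A tibble: 1 × 8
#>   n_scene n_model n_iter converged sigma2    omega     Q n_matched
#>     <int>   <int>  <int> <lgl>      <dbl>    <dbl> <dbl>     <int>
#> 1     196      98    100 FALSE     0.0184 0.000672 -584.       196

evaluate_fit(fit, case$truth, threshold = 0.1)
#> # A tibble: 1 × 8
#>     rmse    tp    fp    fn recall precision    f1 recall_accuracy
#>    <dbl> <int> <int> <int>  <dbl>     <dbl> <dbl> <list>
#> 1 0.0754    83   154    15  0.847     0.350 0.496 <tibble [5 × 2]>
```

`rmse` is the root-mean-square distance between each scene point and its
aligned ground-truth partner, in normalized units (1 = the RMS radius of
the shape): 0.075 here, under heavy clutter, against ~0.12 for the frozen
baseline on the same cases. `recall` says 85% of true pairs landed within
the 0.1 threshold; precision is low because the posterior argmax also
pairs the 98 clutter points, which have no truth entry. `omega` is the
automatically estimated outlier weight — on unit-RMS-normalized synthetic
data its equilibrium is small and what matters is that it is independent of
its initialization (see the vignette for why the level is scale-relative).

`tidy(fit)` gives the per-scene-point correspondence table, `augment(fit)`
binds aligned coordinates onto the scene, `autoplot(fit)` draws the
alignment, and `autoplot(fit, type = "trace")` the EM diagnostics
(objective, variance, outlier ratio, penalized negative log-likelihood per
iteration). `degradation_sweep()` and `omega_sweep()` reproduce the
benchmark-style error-bar and initialization-consistency experiments;
`plot_sweep()` draws the former.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "driftreg", package = "driftreg"))')
Rscript $CLI synth --kind outlier --level 1.0 --template fishlike --n-points 98 --seed 5 --out-dir case
Rscript $CLI register case/scene.txt case/model.txt --truth case/truth.tsv --out-dir out
Rscript $CLI eval out/aligned.txt case/truth.tsv case/scene.txt --out metrics.json
Rscript $CLI sweep --kind noise --levels 0.01,0.03,0.05 --trials 5 --seed 1 --out sweep.tsv
```

Point files are plain text (one point per row, whitespace- or
comma-separated, `#` comments); correspondence and truth TSVs use 0-based
indices (noted in their headers); reports are JSON with the full config
echo and per-iteration traces, so a run is reproducible from its report.

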