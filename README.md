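# skigears

Automatic classification of cross-country ski-skating sub-techniques
("gears") from a chest-worn triaxial accelerometer.

Skating skiers cycle through five gears — G2 with the left or right pole
dominant (G2L/G2R) on climbs, the symmetric G3, and the faster G4L/G4R —
and which gear is used where is useful training information that is
tedious to extract from video.  The catch is that gears differ in the
*shape* of the movement, not in amplitude or frequency (any gear can be
skied fast or slow), and phone accelerometers sample irregularly.
`skigears` implements a pipeline built for exactly that setting:

1. **Smoothing** by time-domain Gaussian kernel regression
   (Nadaraya–Watson over the actual timestamps), exact under irregular
   sampling: σ = 370 ms isolates the very-low-frequency vertical
   oscillation, whose local minima define **movement-cycle boundaries**;
2. **Normalization** of each cycle by a second kernel pass (90 ms
   bandwidth at the nominal 1.4 s cycle, scaled with cycle duration) at
   100 uniformly spaced time steps × 3 axes, giving a 300-dimensional
   trajectory in acceleration space that is invariant to sampling rate
   and cycle speed;
3. **Classification** by per-gear first-order Markov chains of
   multivariate Gaussians,
   `v1 ~ N(mu1, S1)`, `v_t | v_{t-1} ~ N(A_t v_{t-1} + b_t, Q_t)`,
   fitted by step-wise least squares with ridge-stabilized covariances
   (~2.1k parameters per gear).  Each cycle gets the maximum-likelihood
   gear.

On top sit an evaluation layer (confusion matrix in `n (%)` form,
overall/per-gear accuracy, startup/transition/other error breakdown,
paired t-test, Pearson correlation), a calibrated synthetic-session
generator standing in for real recordings, and a small
command-line front end.  The methods vignette
(`vignettes/gear-classification.Rmd`) documents the model, the parameter
choices and the generator's scope in detail.

## Worked example

Train a classifier on five synthetic fixed-gear trials (50 cycles per
gear), then classify a synthetic variable-protocol session (~140 cycles,
~23 gear changes) and score it against its ground-truth labels:

```r
library(skigears)

train <- lapply(seq_along(gear_levels()), function(i)
  extract_cycles(simulate_trial(gear_levels()[i], 50,
                                sim_config(seed = i))$stream))
names(train) <- gear_levels()
clf <- train_classifier(train)
clf
#> <gear_classifier> regime=collective, n_steps=100
#>   training cycles: G2L=49, G2R=49, G3=49, G4L=49, G4R=49

session <- simulate_variable_protocol(sim_config(seed = 101))
preds <- classify_stream(clf, session$stream)
head(preds[1:3], 4)
#>     start_s    end_s gear
#> 1 0.7539694 2.191745   G3
#> 2 2.1917454 3.496569   G3
#> 3 3.4965686 4.925521  G4L
#> 4 4.9255213 6.409156  G4L

ev <- evaluate_predictions(preds, session$labels)
ev$confusion
#> <gear_confusion> reference (rows) vs predicted (columns), n (%)
#>          predicted
#> reference G2L      G2R      G3       G4L      G4R
#>       G2L 28 (93%) 0 (0%)   0 (0%)   1 (3%)   1 (3%)
#>       G2R 2 (8%)   23 (88%) 0 (0%)   1 (4%)   0 (0%)
#>       G3  1 (4%)   2 (7%)   24 (86%) 0 (0%)   1 (4%)
#>       G4L 0 (0%)   1 (4%)   2 (7%)   25 (89%) 0 (0%)
#>       G4R 2 (8%)   1 (4%)   0 (0%)   0 (0%)   23 (88%)
#> total scored cycles: 138
ev$accuracy$overall
#> [1] 89.13043
ev$breakdown
#> <error_breakdown> 15 errors / 138 cycles: startup 1, transition 14, other 0 (k=3, w=1)
```

Read it as: each detected cycle (rows of `preds`) is assigned a gear;
89% of the 138 labeled cycles match the ground truth, and 14 of the 15
errors sit within one cycle of a gear change — a gear change mid-session
produces a hybrid cycle that genuinely belongs to no single class.  On
held-out *fixed*-gear trials, with no transitions, classification is
100% correct.

## File formats and CLI

A *trial* is a directory with `stream.csv` (header `time_s,ax,ay,az`;
seconds and m/s², gravity-inclusive, x lateral / y vertical / z
horizontal) and `labels.csv` (header `start_s,end_s,gear`, gears from
`G2L,G2R,G3,G4L,G4R`).  Models are JSON.  The same pipeline is scriptable
from a shell via the installed `cli/skigears` Rscript (or
`skigears::cli_main()`):

```sh
skigears simulate --gear G3 --cycles 50 --seed 7 -o trial1/
skigears train -i trial1/ -i trial2/ -o model.json     # >1 input: collective
skigears classify -m model.json -s stream.csv -o pred.csv
skigears evaluate -p pred.csv -l labels.csv -o report.json
```

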