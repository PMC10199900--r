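# porecall

Simulation and analysis of single-amino-acid nanopore recordings.

Atomically thin MoS2 nanopores have a sensing region comparable to the
size of one amino acid, which makes the *relative current blockade*
dI/I0 of a translocation event — together with its dwell time dt — a
discriminating fingerprint for single amino acids, down to sub-Dalton
chemical-group differences and post-translational modifications such as
tyrosine phosphorylation. porecall packages the full analysis chain for
this kind of measurement, for researchers developing or benchmarking
nanopore protein-identification pipelines:

* a **generative simulator** of ionic-current recordings whose
  per-analyte blockade statistics (one- or two-component Gaussians on
  dI/I0 or dI) are the published per-device population values shipped in
  `inst/extdata/signal_library.tsv`, with lognormal dwell times, Poisson
  arrivals, calibrated Gaussian noise, and a 10 kHz low-pass acquisition
  filter at 100 kHz sampling — plus exact ground truth for every event;
* a **Transalyzer-style event detector**: zero-phase 2nd-order
  Butterworth at 10 kHz, 300 ms moving-average baseline with event
  masking, 5-sigma detection / 2.5-sigma boundary hysteresis, and the
  standard "dwell < 0.1 ms excluded" filter;
* **population statistics**: Gaussian-kernel density fits with mode
  calling (`kde_fit`), two-component Gaussian-mixture EM fits for
  bimodal populations (`fit_gaussian_mixture`), Welch two-sample z-tests
  (`two_sample_ztest`), and dwell-vs-blockade heatmaps;
* **per-event classifiers**: a transparent Gaussian-Bayes baseline and
  an LSTM sequence network (LSTM → mean-over-time pooling → four fully
  connected layers → softmax, implemented in base-R matrix operations),
  with confusion-matrix / precision / recall / F1 evaluation.

The statistical core is the recovery question: given events whose
relative blockade is distributed as N(mu, sigma^2) (or a two-component
mixture for orientation-split populations), does the full
filter → baseline → detect → dwell-filter → density-fit chain return
the population peak mu unbiased, and do two populations with published
means separate at the published identification accuracy? The z-statistic
used throughout is

    z = (x̄_a − x̄_b) / sqrt(s_a²/n_a + s_b²/n_b)

and peak calling is the mode of a normal-kernel KDE (Silverman
bandwidth) for unimodal populations or EM component means for bimodal
ones.

## Worked example

Simulate a glycine measurement on the Device #4 context, detect events,
and recover the blockade peak:

```r
library(porecall)
lib <- load_signal_library()

run <- recover_blockade_peak(lib, "G", "Device #4", n_events = 1000, seed = 7)
nrow(run$events)   # 1000   events surviving detection + dwell filter
run$sigma          # 0.0083 nA post-filter baseline noise (MAD)
run$peak           # 0.2271 recovered KDE mode of dI/I0
```

The generative model for G on this device is dI/I0 ~ N(0.229, 0.016²):
the chain recovers the population peak to ~0.002, i.e. within the
sampling error of a KDE mode at n = 1000. A two-class identification
experiment on the same device context:

```r
cls <- classification_experiment(lib,
  data.frame(label = c("G", "A"), device = "Device #4"),
  n_per_class = 2000, classifier = "bayes", seed = 1)
cls$report
#> <classifier_report> accuracy 96.33% on 600 events
#>      predicted
#> truth   A   G
#>     A 288  12
#>     G  10 290
#>   class precision recall    f1
#> 1     A     0.966  0.960 0.963
#> 2     G     0.960  0.967 0.963
```

against an analytic (quadrature) Bayes optimum of
`bayes_accuracy_two_class(...)` = 0.963 for these two Gaussians — the
held-out accuracy of the transparent baseline sits at the optimum, well
above the published 88.41% average identification accuracy for this
pair.

The `analysis/` directory chains these steps as a narrative workflow
(`01_simulate_traces.R` → `02_detect_events.R` →
`03_blockade_statistics.R` → `04_classify_events.R`), writing traces,
event tables, density fits, z-tests, and classifier reports under
`results/`.

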