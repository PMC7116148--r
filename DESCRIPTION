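Package: hippens
Title: Hippocampal Cue Ensembles, Representational Similarity, and
    Sharp-Wave Ripple Coactivation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for sensory-preconditioning
    electrophysiology sessions: decision-point filtering of behavior,
    cue-ensemble identification from spike trains via per-neuron GLMs with
    a 2-SD assignment rule, cross-stage representational similarity
    analysis on population vectors with permutation inference, spike-timing
    order statistics (cross-correlograms and spike-triggered averages),
    and sharp-wave ripple detection with normalized joint-firing
    coactivation probabilities. Includes a synthetic-session generator with
    planted ground truth so every stage is testable without real
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    mgcv,
    boot
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
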