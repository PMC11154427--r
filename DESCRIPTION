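Package: laborgp
Title: Multi-Output Gaussian Process Models of Labor Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Causal, real-time-capable models of intrapartum labor
    progression. Predicts cervical dilation and fetal station at the next
    pelvic exam from the previous exam and cumulative cardiotocography
    context, using a sparse variational multi-output Gaussian process with
    a composite (squared-exponential + Matern + linear) kernel, an
    intrinsic-coregionalization output covariance and a neural-network
    mean function, trained by maximizing the collapsed evidence lower
    bound over per-delivery meta-tasks with optional per-delivery test
    adaptation.  Includes the exam preprocessing pipeline (20-hour window,
    descending-dilation and short-gap filters, interpolation, cumulative
    contraction counts, intervention flags), a mechanistic labor
    simulator and a GP-prior sampler with known ground truth, a linear
    mixed-effects baseline fit by profiled likelihood, a univariate
    time-only baseline, and a grouped cross-validation evaluation harness
    with paired model comparisons, elapsed-time-binned summaries and
    interval-coverage diagnostics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
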