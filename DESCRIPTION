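Package: slicephys
Title: Slice Electrophysiology and Seizure-Diary Analysis for Interneuron
    Graft Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for whole-cell patch-clamp and local field
    potential (LFP) recordings from hippocampal slices, and for behavioural
    seizure diaries, as used in studies of grafted GABAergic interneurons in
    epileptic tissue. Detects spontaneous postsynaptic currents by template
    correlation; detects and scores epileptiform discharges with an adaptive
    power threshold (4 x median x kurtosis) including peak-to-peak amplitude,
    peak power and coastline index; quantifies paired dark/light optogenetic
    stimulation effects; extracts passive membrane properties (series and
    input resistance, capacitance by charge integration) and action-potential
    features; summarizes seizure diaries (frequency, duration, severity,
    status epilepticus episodes). Ships synthetic-signal generators with
    known ground truth so every stage is testable without raw recordings,
    plus exact small-sample implementations of the Mann-Whitney, Wilcoxon
    signed-rank, binomial proportion, Kolmogorov-Smirnov and Spearman tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
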