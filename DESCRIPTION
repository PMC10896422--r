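Package: dualtaskEF
Title: Dual-Task Executive-Function Analysis of EEG Band Power and Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dual-task (cognitive plus walking)
    executive-function studies. Builds graded Go/NoGo and N-Back stimulus
    schedules and scores response logs; simulates multichannel EEG with
    controlled band-power modulations and transient artifacts, and gait
    trials with condition-dependent spatial-temporal effects; cleans EEG
    with a zero-phase Butterworth bandpass and a variance-threshold
    subspace artifact remover; extracts the 112 absolute/relative
    band-power features per condition via Welch spectra; computes gait
    spatial-temporal parameters, Gait Variable Scores and the Gait
    Profile Score; and screens features for monotone modulation across
    difficulty levels with Spearman rank correlation followed by Friedman
    tests with Kendall's W effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
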