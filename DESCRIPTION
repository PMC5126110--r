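Package: envlrtc
Title: Long-Range Temporal Correlations in EEG Amplitude Envelopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detrended fluctuation analysis (DFA) of the amplitude envelope of
    band-pass filtered EEG oscillations, yielding per-electrode, per-band Hurst
    exponents as measures of long-range temporal correlations (LRTC); cohort-level
    inference on Hurst exponents (type-II general linear models, rank-based
    follow-ups, bootstrap correlation profiles) and spatio-spectral
    threshold-free cluster enhancement (TFCE) with Monte-Carlo permutation
    familywise correction over electrode-by-band lattices. Includes a synthetic
    data generator (exact-covariance fractional Gaussian noise, amplitude
    modulated narrowband oscillations, two-group cohorts with planted
    insomnia-severity associations) so the full pipeline is testable without
    external recordings, plus EDF and delimited-matrix readers and a scripted
    end-to-end pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    car,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
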