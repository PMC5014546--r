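Package: tonescenes
Title: Tone-Pip Scene Synthesis and Evoked-Response Statistics for
    Auditory Change Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying change detection in multi-source auditory
    scenes. Synthesises artificial acoustic scenes of concurrent pure-tone
    sources with regular or random temporal structure on the ERB-number
    scale, including matched change/no-change stimulus pairs with an
    appearing source. Simulates multichannel evoked magnetoencephalography
    (MEG) epochs and behavioural detection tables with a configurable
    planted effect structure, and implements the corresponding sensor-space
    analysis chain: zero-phase low-pass filtering and resampling, epoching
    and baseline correction, outlier-trial rejection, denoising source
    separation (DSS), root-mean-square time-courses, cluster-based
    permutation tests with family-wise error control, jackknife onset
    latency estimation with corrected standard errors, channel-subset
    polarity analyses, and signal-detection (d-prime) behavioural
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
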