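Package: xtalknet
Title: Global Transcriptional Crosstalk in Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium thermodynamic analysis of global transcriptional
    crosstalk in many-gene, many-transcription-factor regulatory networks.
    Provides the closed-form and numerically minimized global crosstalk of the
    symmetric activator/repressor model, the 'busy' versus 'idle' regulatory
    design comparison over the (p, q) plane, Poisson-binomial distributions of
    transcription-factor availability and of minimal crosstalk under stochastic
    gene activity, a motif pipeline that turns position count matrices into
    mismatch-energy models and inter-factor binding energies, Monte-Carlo
    concentration-optimized crosstalk for arbitrary networks with an effective
    similarity fit, and a synthetic motif-network generator for subnetwork
    sampling studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
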