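Package: symtvd
Title: Multi-Channel Noise-Masking Model of Mirror-Symmetry Detection
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling mirror-symmetry detection in random-dot
    displays under noise masking. Implements a two-stage signal-detection
    model in which orientation-selective symmetry channels respond to dot
    density through an expansive nonlinearity with divisive inhibition, and
    a max-rule decision stage monitors one (cued) or four (non-cued)
    channels. Provides random-dot stimulus generation with aperture masks
    and reverse-mapping symmetry counts, threshold-versus-density (TvD)
    curve prediction with component ablation, Gaussian order-statistic and
    weight-of-evidence baseline predictions, maximum-likelihood psychometric
    fitting, nine-parameter model fitting with nested F comparison, a
    synthetic-observer trial generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
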