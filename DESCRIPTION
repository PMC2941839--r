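Package: steroidscreen
Title: Urinary Steroid Metabolome Interpretation and Steroidogenesis Pathway Simulation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Interpretation of quantified urinary steroid metabolite profiles for
    the diagnosis of inborn errors of steroidogenesis and steroid metabolism.
    Ships a versioned knowledge base of urinary steroid metabolites, the adrenal
    and gonadal steroidogenesis pathway with enzyme and cofactor dependencies,
    and the precursor/product diagnostic ratio panel for congenital adrenal
    hyperplasia and related disorders (including P450 oxidoreductase deficiency
    and apparent cortisone reductase deficiency). Builds empirical reference
    centiles (mean, 5th, 95th) from normal cohorts, flags analytes, metabolite
    groups and diagnostic ratios against them, and calls disorders from the
    ratio panel. A steady-state pathway-flux simulator generates synthetic
    24-h urinary excretion profiles under configurable enzyme blocks, so the
    whole diagnostic engine is testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
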