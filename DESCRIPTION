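Package: iredpanel
Title: Structure-Based Prioritization of Imine Reductase Screening Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate imine reductase (IRED) sequences into small
    screening panels for reductive amination. Candidate sequences are
    matched to characterized IRED templates, homology-search hits are
    filtered and clustered, structure models are qualified on the
    Ramachandran plot and superposed onto a dimeric template with the
    NADPH cofactor transferred in, docked substrate poses are screened by
    the C4-to-imine-nitrogen hydride-transfer distance, and survivors are
    rescored with a linear function combining the docking score with
    counts of acidic, basic and histidine residues in the active-site
    shell. Includes panel evaluation against screening outcomes (hit
    rates, best-hit retrieval, analytic and resampled random baselines),
    grid-search weight tuning, and deterministic fixture generators for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
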