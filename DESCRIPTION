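Package: itraqnull
Title: Empirical-Null Differential Abundance Calling for Isobaric-Tag Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls differential nuclear protein and phosphopeptide abundance
    from multi-channel isobaric-tag (iTRAQ 8-plex) ratio tables. Each
    experiment carries an internal technical replicate (the control sample
    labelled in two channels); its control-vs-control ratios form an
    empirical null from which a per-experiment significance interval and a
    signed confidence score are derived. Per-experiment change calls are
    combined across biological replicates by a majority consensus rule with
    an internal-replicate veto. Also provides phosphopeptide spectrum
    filtering and collapsing to distinct phosphoentities with
    error-factor-weighted ratios, phosphorylation stoichiometry,
    protein/mRNA and nuclear/cytosolic concordance classification,
    transcription-factor-stratified concordance summaries, oncogene
    clustering, multi-set Venn region counts, and a synthetic-data generator
    with spike-in ground truth for validating the caller.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
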