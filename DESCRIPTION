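Package: pathwaybf
Title: Bayes Factor Evidence for Basal Ganglia Action-Control Pathways from
    fMRI ROI Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring the direct, indirect and hyperdirect
    cortico-basal-ganglia action-control pathways against region-of-interest
    (ROI) fMRI data. Per-contrast percent BOLD signal change is collapsed into
    compound estimates per participant, ROI and behavioural condition
    (response execution, proactive inhibition, reactive inhibition); each ROI
    is tested for activation with a Jeffreys-Zellner-Siow (JZS) default
    Bayes factor for the one-sample t-test; interrelations between active
    ROIs are screened with partial moderator/mediator intercept tests; and
    each pathway model is scored by the product of member Bayes factors and
    non-member inverse Bayes factors across the twelve lateralised
    subcortical ROIs. A synthetic-data generator with known ground truth
    supports end-to-end validation and parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
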