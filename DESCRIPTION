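Package: epimem
Title: Windowed Differential Methylation Analysis for MeDIP-Chip Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Window-based calling of differentially methylated regions
    (DMRs) from normalized MeDIP-chip probe signals: per-chromosome
    reference means estimated from a random probe subset with a
    two-component Gaussian mixture diagnostic, 50 kb analysis windows,
    one-sample Wilcoxon signed-rank tests against the reference mean,
    false discovery rate control, and ternary methylation scores.
    Includes cross-experiment DMR signature comparison (conserved and
    inversed DMRs, hypergeometric over-representation tests, overlap
    with differentially expressed genes), global DNA methylation (%mC)
    genotype-by-environment statistics from HPLC nucleoside tables, and
    a seeded synthetic-data generator with planted DMRs so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
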