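Package: histoneacyl
Title: Derivatization-Aware Quantification of Endogenous Histone Acylations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bottom-up mass-spectrometry analysis of endogenous
    histone propionylation and butyrylation under chemical-derivatization
    protocols. Provides an in-silico ArgC-like digestion and derivatization
    engine that computes monoisotopic peptidoform masses and predicts which
    endogenous acylations are isobaric with (and chromatographically
    indistinguishable from) chemical labels under each protocol; merging of
    parallel single-acylation search results with score-based conflict
    resolution and confidence filtering; percent relative abundance and
    light/heavy SILAC ratio quantification against a super-SILAC spike-in,
    with quantifiability filtering, normalization, Tukey-fence outlier
    removal and mean imputation; two-sample Student t comparisons and
    reporting tables; and a seeded synthetic-data generator emulating
    search-engine and extracted-ion-chromatogram inputs with known ground
    truth, so every pipeline stage is testable without raw data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
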