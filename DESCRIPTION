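Package: asymkit
Title: Hemispheric Asymmetry Indices for Bilateral Cortical Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes three per-region asymmetry indices over bilateral cortical
    morphometry tables (34 Desikan-Killiany cortical parcels per hemisphere): a
    global distance index based on the correlation of cross-hemisphere
    difference-vector profiles, the classic absolute laterality index, and a raw
    subtraction index. Includes readers for FreeSurfer aparc-style tables, BIDS
    participants files and MRIQC-style image-quality metrics, a synthetic cohort
    generator with controllable cross-hemisphere coherence noise and pairwise
    left-right offsets, random-forest sex classification with Cohen's kappa and
    no-information-rate testing, image-quality stratified robustness analysis,
    and group contrast and sex-correlation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
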