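Package: stemspat
Title: Spatial Pattern Analysis of Rainforest Stem Maps Along Transects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing marked tree point patterns mapped along long,
    narrow forest inventory transects. Implements the pair correlation function
    and Ripley's K with translation edge correction and Monte-Carlo envelopes
    under complete spatial randomness, distance-class Moran's I correlograms of
    stem diameter including an intertype (cross-species) variant, Mantel
    permutation tests, and canonical correspondence analysis with permutation
    pseudo-F tests, backward elimination and per-variable variance shares.
    A synthetic-forest generator emulates the transect sampling design and the
    spatial structure predicted by disturbance-cohort, random-placement and
    environmental-filtering hypotheses, so every statistic can be exercised
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
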