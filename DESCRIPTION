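Package: onophon
Title: Phonological Feature Decoding of Multisensory Onomatopoeia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how improvised onomatopoeias encode the
    sensory properties of the events they depict. Words transcribed in the
    International Phonetic Alphabet are decomposed into binary distinctive
    features and IPA place/manner/height classes, averaged into per-word
    feature profiles, screened feature-by-feature with repeated-measures
    ANOVAs under Bonferroni correction, and decoded with regularized linear
    discriminant analysis under speaker-grouped cross-validation, scored by
    the macro-averaged Matthews correlation coefficient. Includes
    cross-modality transfer of trained decoders, application of a trained
    decoder to cross-linguistic onomatopoeia word lists with comparison to
    human ratings, and a synthetic corpus generator that plants tunable
    sound-symbolic effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    stringi
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    lmerTest,
    jsonlite
Config/testthat/edition: 3
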