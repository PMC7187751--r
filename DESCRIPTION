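Package: affectseq
Title: Affect-Transition and Content-Originality Analysis of Social Media
    Posting Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes longitudinal social media posting histories as symbol
    sequences over affect polarities (positive, negative, mixed, neutral)
    with explicit silence days, counts bidirectional transitions between
    adjacent symbols, and screens the resulting per-user transition
    features against personality traits (OCEAN), satisfaction with life,
    and CES-D depression scores using permutation Pearson correlation
    tests with bootstrap confidence intervals. Also provides a
    threshold-based cosine-similarity classifier for non-original
    (quoted or lyric) content, a participant-selection funnel with an
    audit report, inter-rater agreement (Cohen's kappa), partial
    correlation for mediation-style checks, and a seeded synthetic-cohort
    generator with trait-modulated Markov posting dynamics for end-to-end
    testing without access to any closed dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
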