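Package: webvalence
Title: Affective Valence of Browsed Web Text and Its Relation to Mental Health and Mood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the affective valence of the text people
    read online and relating it to mental-health measures and mood. Provides
    webpage paragraph extraction and cleaning, threshold-based lexicon affect
    scoring (valence and discrete emotions), factor-weighted transdiagnostic
    psychopathology dimension scores, and the statistical battery used in
    digital-phenotyping studies of browsing and mood: intraclass correlations,
    standardized regression with derived effect-size r, linear mixed models
    with Satterthwaite degrees of freedom, repeated-measures ANCOVA, Welch and
    paired t tests, and estimated marginal means. A synthetic-data generator
    produces complete cohorts with known ground truth (lexicons, webpages,
    browsing sessions, questionnaires, moods, interventions) so every stage of
    the pipeline can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
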