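---
title: "Measuring the affective valence of browsed text: models and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the affective valence of browsed text: models and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(webvalence)
```

This vignette is the package's own account of its methods: what each stage
computes, the assumptions baked into it, the parameters that matter and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and the places where the design was genuinely open and a
choice had to be made.

## 1. From HTML to tokens

Webpage text is taken to be the content of `<p>` elements only, concatenated
in document order (`extract_paragraphs()`). This deliberately excludes
headings, navigation, menus and boilerplate, which dominate many pages but
are not what a reader "consumes". Parsing is tolerant: malformed markup is
handled by the HTML parser's error recovery, and an unparseable document
yields an empty page rather than an error, because in a browsing-history
corpus unparseable submissions are data, not bugs.

Cleaning (`clean_text()`) applies three rules, in order:

1. URLs (scheme- or `www.`-prefixed spans) are removed first, so that their
   alphanumeric fragments never become tokens;
2. the remainder is lowercased (lexicons are lowercase);
3. every run of non-alphanumeric characters — punctuation, symbols, emoji —
   is a token separator, so tokens match `[a-z0-9]+`.

Digit tokens are retained: they never match a lexicon entry, so their only
effect is to enlarge the denominator, which is the honest reading of a
"proportion of all words" score. Cleaning is idempotent, which the test
suite asserts: re-cleaning cleaned text changes nothing.

Consecutive duplicate visits (reloads, redirects bouncing back) are removed
by exact URL match after trailing-slash normalization. Fragment identifiers
(`#...`) are kept distinct because fragments can change the visible content
of single-page applications. Non-adjacent revisits are real revisits and are
kept.

**Inclusion filter.** A participant's data is analysed only if every
required day has at least 3 non-empty pages and at least 1,024 bytes of
cleaned text in total. The byte threshold is applied to *cleaned* text
(UTF-8 bytes of the space-joined tokens) because cleaned text is what is
scored; a page of pure boilerplate should not qualify a participant. The
threshold is read as a per-day total from at least three pages, not a
per-page minimum. Pages with no extractable text count toward neither
threshold. Single-day designs are the same filter with one required day,
not a separate code path. Inclusion is monotone: adding a page can never
exclude a previously included participant (tested as a property).

## 2. Lexicon scoring

A word is a *positive term* when its lexicon valence is at least 0.75 and a
*negative term* when it is at most 0.25, both bounds inclusive; the interval
between is neutral. Scores are occurrence proportions: every token
occurrence is counted, and the denominator is all tokens including
out-of-lexicon words. Scores are stored as proportions in [0, 1] (a page
with negative score 0.031 has 3.1% negative word occurrences). Emotion
scoring is the same construction per emotion with the same 0.75 threshold;
binary association lexicons (0/1 entries) work under the identical rule.
Opinion-list scoring is unweighted membership.

There is deliberately no stemming, lemmatization, negation handling or
stop-word removal: the scoring model is bag-of-words, and the validation
machinery (segment sampling, attended-region models) exists precisely to
check how much signal that simple model carries. The known limitation is
shared by all context-free lexicons: "not dangerous" scores as negative.

Aggregation is mean-over-pages within day, then mean-over-days, with equal
day weights. A day with 40 pages and a day with 3 pages contribute equally
to a participant's overall score; the alternative (pooling pages) lets
heavy-browsing days dominate and is not what a "daily tendency" construct
means. The two aggregations coincide exactly when all days have equal page
counts, which the tests assert.

**Stimulus classification** (`classify_stimulus()`) implements the z-score
rules used to assemble experimental stimulus pools: "extreme negative"
(negative score more than 2.5 s.d. above the reference mean; neutral within
±1 s.d.) and the two-axis rule for choice experiments (extreme on exactly
one axis; pages extreme on both axes are left unclassified because stimulus
pools must be mutually exclusive). The reference mean and s.d. are always
supplied explicitly — pooling reference populations is a caller decision,
never implicit.

## 3. Psychopathology dimension scores

Items are Z-scored across participants (sample s.d., n − 1), multiplied by
their published factor weight, and *summed* within each dimension's item
set; the composite is the unweighted *mean* of the three dimension scores.
Sum-within, mean-across follows the source scoring procedure. The composite
uses the raw dimension scores, not re-standardized ones; a toggle is not
provided because the three scores are already on comparable Z-derived
scales and re-standardizing would silently change the composite's weighting
across cohorts of different dispersion.

Factor weights are an input table (the published loading set is external to
this package); the generator ships a synthetic weight fixture for tests.
Missing weighted items abort scoring by default (`on_missing_item =
"error"`) because silently dropping items changes the construct; `"skip"`
is available and warns. Reverse-scored items are assumed already oriented:
orientation is questionnaire metadata, not a computation this package can
infer.

## 4. The statistical battery

**ICC.** The default form is ICC(3,1), two-way mixed, consistency, single
measurement: the "raters" (days, scoring methods) are fixed facets, and
day-level shifts in overall tone should not count against a participant's
stability. One-way and average-measure forms are available and every result
records the form used. Confidence intervals and p-values use the classical
mean-squares F construction. The implementation is validated two ways:
against the analytic value σ²_b/(σ²_b + σ²_w) on simulated
subject-plus-noise data, and against an independent `lme4`
variance-components route on balanced designs.

**Standardized OLS and effect r.** All variables are Z-scored before
fitting (so coefficients are standardized betas) and each predictor's
effect size is r = t/√(t² + df) with df = n − p − 1. This identity is
asserted on every fitted model, and reproduces published effect sizes from
their printed t statistics to three decimals in the acceptance suite.
Collinear predictor sets are rejected with the offending columns named,
rather than silently dropped.

**Mixed models.** REML estimation with Satterthwaite denominator df (the
fractional dfs this literature reports), via `lmerTest`. Random-effect
structure follows the design: participant random intercepts plus a random
slope of the focal predictor, backing off to simpler structures on singular
or non-convergent fits. The backoff is logged on the result (`singular`,
`converged`, the formula used), never hidden; the final fallback is
fixed-effects least squares, used only when even the intercept-only mixed
fit is impossible (e.g. exactly zero residual variance in a degenerate
identity check). Balanced two-level designs are verified against the
closed-form group-mean solution to 1e-6, and zero-between-variance data
against OLS to 1e-8.

**Mixed ANOVA with a continuous within-subject covariate.** Implemented as
the equivalent two-stage GLM: between-subject tests come from the
participant-mean response regressed on the covariates (so the covariate
main-effect F is exactly the squared t of the corresponding OLS — asserted
in tests), and within-subject tests (dimension main effect, covariate ×
dimension interactions) from regressions of orthonormalized within-subject
contrasts, with sums of squares pooled across contrasts. Sphericity is
tested with Mauchly's criterion on the residual contrast covariance;
Greenhouse–Geisser correction is applied when Mauchly rejects at p < 0.05.
Partial eta squared is SS_effect/(SS_effect + SS_error) from this module's
own decomposition. A degenerate within stratum (identical scores across
levels) yields F = 0 rather than 0/0.

**t tests.** Welch (fractional df) for independent groups with pooled-s.d.
Cohen's d; paired t with mean-difference/s.d.-of-differences d. All
p-values everywhere are two-sided, recorded on each result object.

## 5. The synthetic-data generator

The generator exists so that every pipeline can be exercised against known
truth. Its structural model is deliberately parameterized on *standardized*
scales: all latent variables are unit-variance, and the couplings are
standardized path coefficients, which makes "the true coupling" directly
comparable with the standardized coefficients the pipelines estimate. Per
participant i and day d:

- latent psychopathology factors f_i ~ MVN(0, Σ), Σ compound-symmetric with
  correlation ρ = 0.4 (the three dimensions are substantially correlated in
  real cohorts); z_g is the standardized factor mean;
- questionnaire items: x_ik = w_k f_i,dim(k) + ε, with weights uniform on
  [0.4, 0.9] and item noise s.d. 0.5 — item-level reliability in the range
  typical of symptom questionnaires;
- pre-browsing mood: z_pre = −λ z_g + residual, with λ = 0.30; the residual
  is split half participant-level, half daily (κ = 0.5), giving plausible
  day-to-day mood correlation; mood is mapped to the −50..+50 slider scale
  with s.d. 15;
- daily negativity target: z_ν = γ_g z_g + b2 z_pre + residual, with the
  residual split so that the participant-level share of latent negativity
  variance is 0.55 (day-to-day stability in the moderate range that
  browsing data shows); the observation scale is ν = 0.03 + 0.01 z_ν,
  matching the observed magnitude of page negativity scores (~3% of
  tokens);
- post-browsing mood: z_post = ρ_m z_pre + δ z_ν + residual, ρ_m = 0.7;
- pages: token counts per page are drawn from the exact multinomial law
  implied by i.i.d. token draws at (ν, π) — distributionally identical to
  materializing every token, and what keeps 200-replicate calibration runs
  inside minutes. `materialize = "html"` generates the actual tokens and
  HTML instead, and the test suite verifies the two paths agree in law and
  that the HTML path round-trips exactly.

Default couplings are γ_g = 0.09, b2 = −0.08, δ = −0.05 — the standardized
effect range (|β| ≈ 0.05–0.15) that observational browsing studies report —
so power at realistic sample sizes is realistic.

Two consequences of this design are worth stating. First, because the
structural equations are exactly linear and the observation scales are
chosen so clipping to valid ranges essentially never binds, recovery
simulations have a well-defined truth and coverage checks are meaningful.
Second, measured scores contain page-sampling (multinomial) noise on top of
the latent targets; standardized estimates are therefore mildly attenuated
relative to the latent couplings (by the factor σ_latent/σ_measured, about
0.9–0.95 at the default page counts and word counts). This is a property of
measurement, not a bug, and the acceptance tolerances (±0.03 on the
recovered coupling) accommodate it.

What the generator does **not** emulate: real text's topical and linguistic
structure (tokens are i.i.d. within a page — no burstiness, no discourse),
recommendation-algorithm feedback, device or platform effects, item-level
questionnaire idiosyncrasies (reverse-coded wording, response styles), or
demographic realism beyond age and a binary-coded gender covariate. Passing
tests therefore show that the *pipeline* is correct and calibrated — not
that the substantive findings would replicate on any particular real
corpus.

The intervention generators follow the same philosophy:
`simulate_manipulation()` shifts post-exposure mood by a configured number
of standard deviations (default −0.5) and free-browse negativity by a
configured pooled-s.d. gap (default 0.4); `simulate_label_study()` draws
choices from a softmax whose utilities shift under labels — the default
shift moves the choice distribution from uniform to (0.45, 0.30, 0.25) for
(positive, neutral, negative) — and updates trial mood by a standardized
gain per valence step (default 0.09).

## 6. Numerical and coding choices

- Gender enters regressions as a Z-scored numeric covariate, matching how
  such covariates are handled in the analyses this package reproduces; the
  caller supplies the numeric coding (the generator uses 0/1), and
  observations that cannot be coded numerically should be recoded or
  excluded upstream.
- Mood is coded −50..+50 before any model.
- Tie-breaks: the valence thresholds are inclusive (≥ 0.75, ≤ 0.25); words
  on both opinion lists count toward both with a warning; two-axis stimulus
  classification leaves both-extreme pages unclassified.
- Degenerate inputs error loudly: empty token lists cannot be scored, zero
  total variance has no ICC, all-neutral choices cannot identify a valence
  effect (flagged `degenerate`), reference s.d. must be positive.
- Every stochastic routine takes an explicit seed; fixed seed implies
  byte-identical output (asserted for the generator).
- Duplicate lexicon words keep the last entry with a warning; duplicate
  (participant, day, order) visits are an error, not a warning, because
  they violate the history's identity invariant.

## 7. Problem sizes used in validation

The validation suites run at deliberately chosen scales: scoring-oracle
equivalence on 1,000 random token lists; round-trip exactness on 100
generated pages; ICC calibration at n = 2,000 × 5; type-I error over 200
replicate null cohorts of n = 450; parameter recovery over 100 replicates
at n = 450 (valence–psychopathology) and n = 160 × 5 days (mood couplings);
intervention sign recovery over 100 replicates at n = 55 vs 54. These sizes
make Monte-Carlo error small relative to the tolerances being asserted
(e.g. binomial s.e. ≈ 0.015 on a 0.05 rejection rate at 200 replicates)
while keeping the full suite runnable in minutes on one CPU.

## 8. Known limitations

- Context-free scoring: negation, sarcasm and topic are invisible to the
  lexicon approach by construction.
- The ICC form for stability and method agreement is a modelling choice
  (consistency, fixed facets); absolute-agreement forms would penalize
  day-level mean shifts and give systematically different values.
- Partial eta squared depends on the error decomposition; values from
  other software's repeated-measures ANCOVA implementations are not
  guaranteed to match term-for-term.
- The mixed-model backoff chain resolves under-identified random-effect
  structures automatically; users who need a fixed structure should call
  `fit_lmm()` directly and inspect `singular`/`converged`.
- The generator's standardized parameterization means raw-scale effect
  sizes (e.g. mood points per percentage point of negativity) are derived
  quantities; analyses that need them must multiply back the observation
  scales.
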