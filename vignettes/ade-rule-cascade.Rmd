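---
title: "Detecting adverse drug event mentions with a removal/retain rule cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting adverse drug event mentions with a removal/retain rule cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ademiner)
```

## The problem

Clinical free text is full of adverse-drug-event (ADE) vocabulary that does
*not* describe an event the patient experienced. A note may negate the term
("denied any dystonic reactions"), warn about it ("possibility of dystonia
with this medication"), describe monitoring ("check for any dystonic
reaction"), discuss somebody else ("mother had developed dystonia"), name an
organisation ("Dystonia Society"), pose a hypothetical ("If dystonia develops
give procyclidine"), or use a homonym ("ego dystonia"). A keyword search over
psychiatric records therefore has high recall but poor precision, and any
prevalence estimate built on raw keyword hits is badly inflated.

`ademiner` implements a dictionary-plus-rules pipeline for this setting. It
targets mention-level classification: each located occurrence of an ADE term
is classified positive (a real event for this patient, past events included)
or negative (any of the contexts above). Patient-level flags, stratified
prevalence tables and chi-square heterogeneity tests are built on top of the
mention-level decisions. The rule set is deliberately ADE-agnostic: it was
shaped around the four extrapyramidal side effects (EPSEs) of antipsychotic
treatment — dystonia, akathisia, Parkinsonism, tardive dyskinesia — but the
same stages apply unchanged to any user-supplied lexicon (starter lexicons
for eight unrelated ADEs, from alopecia to tachycardia, ship with the
package).

## The cascade

Candidate identification is case-insensitive, token-boundary-aligned,
longest-match dictionary lookup: when both "dystonic reaction" and "dystonic
reactions" are lexicon terms the plural span wins, and no candidate is a
sub-span of another. Hyphens count as token boundaries, so "tardive-dyskinesia"
matches the two-token term. Spelling variants (e.g. *acathisia*, *akithisia*
for akathisia) are curated lexicon entries, not automatic edit-distance
expansions — misspelling handling is exactly as good as the term list.

Each candidate then passes through eleven **removal stages**, in a fixed
order (negation before; negation after; organisation; adjacent `?` `/` `@`
symbols; other person; monitoring; side-effect warnings; single-word cues;
diagnosis homonyms; drug-effect listings; hypotheticals). Every stage is
driven by its own gazetteer, so the behaviour is data, not code. All stages
are always evaluated even after one has fired: the decision list is an audit
trail, and cumulative ablation (`cumulative_stage_report()`) needs per-stage
attribution. Finally, **retain rules** can override any removal when context
makes the event unambiguous: a definite article or possessive pronoun
immediately before the term ("her dystonia had become worse"), a diagnostic
phrase ("diagnosed with"), or a patient reference co-occurring with an
indication term. Retain precedence is absolute — no voting or weighting —
so "The patient does not think the dystonia was painful" ends positive
despite the negation.

The cascade is tuned for precision over recall: an ambiguous construction
should be removed. A missed mention is usually recoverable because real ADEs
tend to be recorded repeatedly across a patient's documents, whereas a false
positive silently inflates prevalence.

### Parameters that matter

* **Context windows** (`window_before`, `window_after`, default 5 non-space
  tokens each side). Published descriptions of this kind of rule set speak
  of "close proximity" without quantifying it; 5 tokens is the smallest
  window that decides every shipped worked example correctly, and it is the
  package's fixed default. The other-person stage deliberately ignores the
  window and scans the whole sentence ("if other person is discussed in the
  sentence" is inherently sentence-scoped), and the diagnosis-homonym stage
  uses phrase containment.
* **Scope**: no rule ever crosses a sentence boundary. Sentences end at
  `.`, `!`, `?` or a newline run; this is crude but errs on the side of
  smaller scopes, which again favours precision.
* **Symbol set**: stage 4 covers `?`, `/`, `@` only. Treating `;` as a
  removal cue as well is defensible but would remove mentions in ordinary
  clause-separated lists, so it is excluded by default.
* **Patient references** (`patient_refs`, default `patient`, `pt`, `he`,
  `she`): real patient names never survive de-identification, so generic
  references stand in for the "near the patient's name" retain condition.
  The list is configurable.
* **Stage order** is fixed. Because stages are independent predicates and
  status depends only on the *set* of fired decisions, order affects only
  the ablation labels, not the final classification.

### Gazetteers are seeds, not the product

The stage dictionaries shipped under `inst/extdata/gazetteers/` are small
seed lists reconstructed from the published examples of each context family
(the full production lists behind the original application were never
published). They decide every worked example and every generator template,
which is what the test suite demonstrates — no more. Deploying on real
records means growing these lists against local annotation batches, which
is exactly the iterative develop–test–refine loop the evaluation module
supports.

## Evaluation protocol

`score_annotations()` computes the mention-level confusion (TP/FP/FN,
precision, recall) against gold labels. The default matching policy is
*overlap* — any span intersection for the same document and ADE counts —
because gold labels produced by classifying pre-located term hits rarely
share exact boundaries with longest-match spans. Undefined ratios are
reported as `NA` with a warning, never as 0; an ablation row with no
predicted positives should not pretend to perfect precision.

`cumulative_stage_report()` re-annotates a corpus thirteen times (keyword
only; stages 1..k for k = 1..11; full cascade with retain) and scores each
row. Two monotonicities are guaranteed by construction and asserted in the
tests: the positive-mention count never increases as removal stages are
added and never decreases when retain is enabled; consequently pipeline
recall never exceeds keyword-only recall. The report uses one fixed corpus
for all rows (per-iteration test sets of the original development loop may
well have been different documents, but a fixed corpus is the only
reproducible choice).

`inter_annotator_agreement()` reports percent agreement and unweighted
two-rater Cohen's kappa, $\kappa = (p_o - p_e)/(1 - p_e)$, with chance
agreement from the marginal products. Labels are binary, so weighting has
nothing to add.

## Prevalence and chi-square

`patient_level_flags()` lifts mentions to patients (positive if any mention
anywhere is positive), `build_stratified_table()` splits a cohort by one
attribute with an explicit `"unknown"` stratum, and
`prevalence_chi_square()` runs Pearson's $X^2 = \sum (O-E)^2/E$ with
df $= (r-1)(c-1)$ and **no continuity correction**. The package also ships
the published EPSE reference table for a 12,879-patient cohort with serious
mental illness (`epse_prevalence_reference()`), which prints per-stratum
prevalences but not counts; `epse_reference_counts()` reconstructs the
counts as round-half-up(prevalence × cohort). Two numerical choices are
pinned by that table and validated in the acceptance tests:

* *Half-up rounding*: the reconstructed counts sum to the printed per-EPSE
  totals (390/750/440/324) under **all four** partitions of the cohort —
  banker's rounding does not achieve this.
* *No Yates correction*: the uncorrected statistic reproduces the printed
  2×2 gender statistics exactly to their three printed decimals (e.g.
  gender × dystonia 10.881); the corrected one does not. Statistics over 3+
  strata inherit a little noise from two-decimal prevalence rounding and
  are reproduced to ±0.005.

P-values come from the chi-square survival function and are reported but
never treated as reproduction targets (reference tables print only bounds
such as "<0.001"). The age-band statistics of the reference table are
internally inconsistent (the same statistic is printed for two different
EPSEs with different p-values — evidently a typo) and are therefore not
asserted anywhere.

## The synthetic corpus generator

No real psychiatric records can ship with a package, so all end-to-end
testing runs on `generate_corpus()`: a seeded generator that emulates the
*contextual* structure the rules target. Each document is 1–6 sentences —
one or two templated mention sentences plus neutral filler — with the
mention context drawn from eleven families (plain positive, retain-cue
positive, negation before/after, monitoring, warnings, other person,
organisation, hypothetical, diagnosis homonym, symbol-adjacent, drug
listing). The default mix (30% plain, 15% negation, 10% each retain and
warning, the rest shared across the remaining families) reflects the broad
observation that affirmative and negated mentions dominate clinical ADE
contexts; it is a fixed modelling choice, not a fitted quantity. Casing
jitter and a 10% misspelling rate (variant surfaces drawn from the starter
lexicons) guard against matches being positional or casing artefacts.
Patient attributes (8 age bands, gender, 4 ethnic groups, 3 SMI diagnoses)
are sampled with the reference cohort's category frequencies so the
prevalence stage runs end-to-end on generated data. The diagnosis-homonym
family is generated only for dystonia — the only ADE with a shipped homonym
phrase ("ego dystonia") — and requesting it without dystonia among the
embedded ADEs is a validation error.

Two properties make the generator a sharp test instrument, and both are
asserted in the suite: with the full cascade every template is decided
correctly (precision = recall = 1 against generator gold), and disabling
stage *k* flips exactly the template negatives of family *k* into false
positives and nothing else. Templates are therefore crafted so that exactly
one stage decides each negative family.

What passing these tests does **not** show: performance on real clinical
text. Real notes contain cue variants outside the seed gazetteers, broken
grammar, section headers, long-range discourse effects and drug–event
temporal structure that the generator does not attempt to model (nor does
it model dosing syntax or letter formatting). The generator validates the
*machinery* — offsets, windows, precedence, monotonicity, scoring algebra —
not clinical accuracy.

## Problem sizes and determinism

The shipped tests run the cascade on corpora of roughly 20–120 documents
(up to ~350 patients for the binomial-proportion check), which exercises
every code path in well under a minute on a single core; the acceptance
script uses a 150-patient corpus. All randomness flows through a single
integer seed (`withr::with_seed`), and the same seed reproduces a corpus
byte for byte.

## Known limitations

* Retain precedence is absolute, so a retain cue inside a negated
  construction wins: "no history of his dystonia" would be retained. The
  seed `retaindiag` list is kept conservative for this reason.
* Sentence segmentation is terminator-based; abbreviations ("Dr. Smith")
  split too eagerly, which shrinks rule scopes and can only cost recall.
* The hypothetical stage requires an "if" token in the pre-mention window;
  long conditional clauses can put the "if" out of reach.
* Mention-level classification ignores time: past events are positive by
  design, so prevalence figures read as "ever recorded", not "current".
* No causality: a positive mention is an event compatible with an ADE, not
  an established drug reaction.
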