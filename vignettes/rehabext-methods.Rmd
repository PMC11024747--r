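---
title: "Extracting rehabilitation-exercise information from therapy notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting rehabilitation-exercise information from therapy notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabext)
```

## The problem

Physical-therapy treatment is documented as free text. A therapeutic-procedures
section of a clinical note is typically a numbered list of terse, abbreviation-heavy
exercise descriptions:

```
1: AROM right elbow flx/ext HEP (right arm supported on table)
2: foam Lunges: x 20 B/L
3: Nustep: L5 x 10' (LEs only)
```

Turning such text into structured data — which joint, which side, what kind of
motion, how many sets and reps, whether the exercise was actually performed in
the clinic — is the prerequisite for any downstream modelling of rehabilitation
treatment and outcome. `rehabext` implements a complete pipeline for this task:
a clinical ontology with surface-form lexicons, note preprocessing and section
sampling, a rule-based tagger with numeric dosage parsing, per-concept
bag-of-words classifiers, prompt generation for chat-model backends, a
synthetic note generator with gold labels, and an evaluation harness.

## The ontology

The label space is organized into categories: exercise description (performed
in-office, home exercise program, not performed), type of motion (ROM and its
active / active-assisted / passive refinements), side of body (6 lateralities),
location on body (21 anatomical sites), plane of motion (41 movement
directions), duration, sets and reps (integer-valued), exercise purpose (14),
exercise type (10), and body position (2). The enumerated and binary categories
carry exactly 101 binary-classifiable concepts; duration, sets and reps are
numeric and are handled by the rule-based parser only.

Concept names alone do not match clinical text, so every concept carries a
lexicon of surface patterns: full words ("flexion"), abbreviations ("flx",
"AROM", "B/L"), and compounds ("LUE" — left upper extremity — which names a
side *and* a location at once). Short all-caps abbreviations are matched
case-sensitively; everything else case-insensitively, and always under token
boundaries so that "extension" can never fire inside "hypertension". The
ontology ships as a versioned YAML file (`default_ontology_path()`) because the
lexicon is the natural refinement surface: tuning rules means editing data, not
code.

Two deliberate attribution conventions are worth spelling out:

* **Bare "ROM"** is listed both as a type of motion and as an exercise type.
  A free-standing "ROM" token is attributed to *both* concepts, by the tagger
  and by the synthetic generator's gold labels alike. The refined phrases
  ("AROM", "active ROM") absorb the bare reading and carry only the refined
  motion-type concept.
* **Containment.** A lexicon match strictly inside a longer match of the same
  category is compositional and is pruned: "lateral flexion" is one plane of
  motion, not three. Containment across categories is genuine co-mention and
  survives: "UE strengthening" names the upper-extremity-strength exercise
  type, the upper-extremity location and the strength purpose at once. This
  keeps the label semantics consistent between a note that says "LE strength"
  and one that says "quad sets for LE strength" — both exercise the lower
  extremity.

## Preprocessing and enrichment scoring

Notes are filtered by filename (the literal substring `THERAPY`,
case-sensitive by default since note types are conventionally upper-cased; a
flag relaxes it). The therapeutic-procedures section is located by a
configurable header pattern — the default matches a THERAPY/THERAPEUTIC header
line and runs to the next all-caps header — because real sectioning varies by
facility and no single expression is always right. Empty sections are allowed;
truncated notes produce them.

Because most sections are brief or uninformative, sections are scored 0–9 by
counting how many of the nine scoring categories (type of motion, side,
location, plane, duration, sets-and-reps, purpose, exercise type, body
position) have at least one keyword present. Sets and reps share one scoring
group, which is why three integer categories contribute two scoring groups.
Scoring uses case-insensitive whole-token matching throughout, consistent with
the uncased text model. `sample_sections()` then builds an enriched set (all
maximum-score sections plus a uniform draw of score-8 sections, 300 by
default) and a disjoint uniform random set (300 by default, at least 200
characters long — the floor is attached to the random set only). Score-8
sampling is uniform; nothing in the sampling is stratified beyond the score.

## Rule-based extraction

`segment()` splits a section into exercise sequences at enumerated-list
markers: `N:` anywhere (run-on notes are common) and `N.` / `N)` at line
starts. Printed numbers are preserved, including gaps — notes really do skip
from 7 to 9. Sequence spans tile the section, so no character is ever in two
sequences.

`tag()` runs every lexicon pattern plus a small set of context rules that
handle the abbreviations dictionary lookup cannot:

* `L` / `R` followed by a body-location word is a side ("L knee"); `L5` or a
  free-standing `L` is not. The letter after a slash ("B/L") never fires.
* `SL` followed by a limb/stance word (leg, stance, squat, ...) is single-leg,
  i.e. unilateral; `SL` otherwise is side-lying, a posture outside the
  ontology, and matches nothing.
* A bare `A` is never matched for anterior — too noisy to be worth it.

Deidentification placeholders (`[PERSONALNAME]`, `[ADDRESS]`) are opaque:
no rule may match inside them.

`resolve_status()` gives each sequence one of three exercise statuses with the
precedence *not performed* > *home exercise program* > *performed in-office*
(the default). "Deferred to HEP" therefore resolves to not-performed while
both description labels stay in the binary label set — the item was prescribed
for home, and it did not happen in the clinic.

`parse_numeric()` recognizes the dosage notations: `2x10` (sets x reps),
`x 20` and `20 x` (reps), `3 rep`, `2 sets`, explicit time units (minutes and
hours normalized to seconds), and the apostrophe-minutes idiom (`x 1'` is 60
seconds). An apostrophe quantity shortly preceded by a locomotion word
("tandem walking: 25' x 2") is a distance in feet: it is recognized and
reported separately but never emitted as a duration, since distances are not
part of the numeric label space. Each notation consumes its matched characters,
so `2x10` can never additionally yield reps 2. The window for the locomotion
check is 30 characters, a sequence-local horizon: wider context windows invite
overfitting of rules to a particular corpus.

`project()` collapses mentions to sequence-level labels: the binary set is the
union of mention concepts plus the status concept; numeric fields take the
first finding of each kind in span order, with collisions logged.

## Per-concept classifiers

The sequence-classification reformulation trains one binary model per concept
over an uncased bag-of-words space fitted to the training set only (tokens are
casefolded and split on non-alphanumeric runs; `2x10` survives as one token).
Four families are provided, one model per (family, concept) — 404 slots over
the shipped ontology:

* **Logistic regression** — ridge-penalized binomial fit (`glmnet`), balanced
  class weights, convergence tolerance `1e-4`. The tolerance setting follows
  the convention that a quoted "learning rate" for an LBFGS-style fit is its
  convergence threshold; it is configurable. A class with a single training
  observation is duplicated at half weight, which leaves the weighted
  likelihood unchanged but satisfies the fitting routine's two-per-class
  minimum.
* **SVM** — polynomial kernel of degree 2 (`e1071`), balanced class weights.
* **AdaBoost** — SAMME over depth-1 `rpart` stumps, 100 estimators, written
  in-package since no installed library ships stump-boosted AdaBoost.
* **Gradient boosting** — `xgboost`, 50 estimators, learning rate 0.1, depth-3
  trees, with leaf regularization disabled (`lambda = 0`,
  `min_child_weight = 0`) to match the classic gradient-boosted-trees
  formulation in which leaf values come from unpenalized line search.

The estimator counts follow the stated configuration read in sentence order:
AdaBoost 100, gradient boosting 50. Concepts whose training labels are
single-class are recorded as skipped and predict their constant class. No
TF-IDF, no n-grams: the input representation is deliberately plain, and
extensions sit behind flags, off by default.

## Prompt generation

For chat-model extraction, each concept gets an automatically generated yes/no
prompt from a single template instantiated with the concept's display name.
The few-shot variant carries exactly 4 worked exchanges — 2 positive and 2
negative example texts interleaved positive/negative/positive/negative, each
answered "Yes." or "No." — followed by the unanswered query turn (10 turns in
all); the zero-shot variant is just the system turn and the query. The
candidate pool excludes the three exercise-description concepts (in-office /
home / not performed are statuses, not extractable mentions) and then drops
concepts with fewer than 2 positive training sequences, which could not fill a
few-shot prompt. Backends are pluggable behind a `function(turns) -> text`
contract; the shipped mock answers deterministically from a keyword table so
the whole path tests offline, and indeterminate replies score as negative
predictions (conservative, precision-favoring) with the raw text kept for
audit.

## The synthetic generator

The corpus the original annotations came from is private, so the package
ships a generator that emits therapy-note sections in the same documentation
style: run-on numbered lists, abbreviation variants, occasional skipped list
numbers, deidentification placeholders, status markers at item ends. Emission
is grammar-based — optional status, motion, side, location, plane (sometimes a
`flx/ext`-style pair), exercise type, purpose, position, and a numeric dosage
slot — with surfaces drawn from the ontology lexicon. Gold labels are written
at emission time from a fixed per-surface mention table computed once from the
lexicon, not by re-parsing generated text, so gold is by construction and
every label has a witnessing span.

Default slot probabilities and within-slot concept weights are loosely
calibrated to the per-concept training-set counts reported for the real,
inaccessible corpus, with a floor weight of 40 for concepts whose prevalence
is unreported; the status mix is 65% in-office, 10% home-program, 25%
not-performed. These are the package's fixed study conditions, documented as
approximations. Two harder tiers exist for benchmarking: an ambiguity channel
(rate configurable, off by default) injects the genuinely context-dependent
abbreviations — `L knee`, bare `L`, `SL stance`, `SL rolling`, bare `A` for
anterior, locomotion distances — with their intended readings recorded, some
of which are deliberately unrecoverable; and a typo channel mutates filler
words at a configurable character rate.

What the generator does *not* emulate: the length and vocabulary distribution
of real notes, misannotation noise, cross-sequence context, and free-text
variation beyond the lexicon. A perfect score on clean synthetic text
therefore demonstrates the internal consistency of tagger and label
conventions — not real-world accuracy, which for the original corpus is
reported only in the source study and requires its private gold standard.
On defaults with the ambiguity channel off, rule extraction recovers gold
exactly; at a 10% ambiguity rate the unrecoverable injections put a measured
dent in the affected concepts (left side, anterior) while the macro average
stays high. The test suite verifies both, along with parameter recovery for
the classifiers (F1 at or above 0.9 on held-out data for every concept with
at least 100 positive training sequences, logistic regression and gradient
boosting).

## Evaluation

`sequence_metrics()` scores per-concept binary labels over sequences;
`span_metrics()` scores mention spans under both exact and overlap matching,
since which of the two a reported NER figure used is often unstated;
`numeric_metrics()` compares duration/sets/reps as exact integers after unit
normalization (no tolerance), multiset-matched within each sequence. The
zero-denominator conventions are: precision (or recall) is 0 when its
denominator is 0, F1 is 0 when P + R = 0, and concepts with neither gold nor
predicted positives are dropped. Macro averages run over concepts with at
least 10 gold-positive sequences by default, mirroring the practice of
omitting sparsely attested concepts from reported tables; the threshold is
configurable.

`fleiss_kappa()` implements the standard chance-corrected multi-rater
agreement statistic; when every rating falls in one category the chance
agreement is 1 and the statistic is undefined, which is reported as `NA` with
an explanation rather than a number. `split_train_test()` performs the
stratified split used for gold-standard corpora: 125 sections per stratum
(enriched / random) to training, the rest to test — 250/50 on a 300-section
corpus — with a proportional 5:1 fallback and a warning for smaller strata.

## Numerical and scale choices

Offsets are 0-based, half-open, in characters, after LF normalization.
Numeric parsing is integer-only; durations are stored in seconds. The test
suite runs the full pipeline at desk scale: 300-section corpora (roughly
2,400 sequences) for the acceptance properties, 1,000 training / 300 test
sequences for classifier recovery, 10,000 items for the agreement-statistic
null check. These sizes keep the suite comfortably reproducible on a single
CPU while leaving the binomial checks enough resolution to detect
miscalibrated marginals at three standard errors.

## Known limitations

* The lexicon was refined against the printed examples and the generator's
  output, not against a real gold corpus; recall on real notes will be lower,
  and facility-specific vocabulary needs lexicon additions (edit the YAML).
* Technique names (PNF patterns, D1/D2 diagonals) are not mapped to motion
  types.
* Distances are recognized but not labeled, matching the numeric label space.
* Spelling correction is not attempted; the typo channel only measures the
  damage.
* The live chat-model adapter is a thin HTTP contract; no live calls are made
  anywhere in the test suite, and reported chat-model scores from the source
  study are not reproducible without its private data and model access.
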