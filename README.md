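# rehabext

Extraction of physical-rehabilitation exercise information from the free
text of clinical therapy notes.

Therapeutic-procedures sections of therapy notes are numbered lists of
terse, abbreviation-heavy exercise descriptions ("1: AROM right elbow
flx/ext HEP", "5: foam Lunges: x 20 B/L"). `rehabext` structures them: for
each enumerated exercise it extracts which joint and side were exercised, in
which plane, what kind of range-of-motion work it was, the dosage (sets,
reps, duration), and whether the exercise was performed in the clinic,
prescribed for home, or not performed at all.

The package is a complete pipeline for this task, aimed at clinical-NLP
researchers working with rehabilitation notes:

* a **clinical ontology** of 101 binary concepts across the exercise-relevant
  categories — type of motion, side of body, body location, plane of motion,
  exercise purpose, exercise type, body position, exercise status — plus
  three integer categories (duration, sets, reps), shipped as editable YAML
  with surface-form lexicons (`AROM`, `B/L`, `flx`, `LUE`, ...);
* **preprocessing**: therapy-note filename filtering, therapeutic-procedures
  section extraction, a 0–9 category-enrichment score used to oversample
  information-dense sections, and enriched/random section sampling;
* a **rule-based extractor**: list segmentation, lexicon + context-rule
  concept tagging with character spans, status resolution (not performed >
  home exercise program > in-office), and numeric dosage parsing (`2x10`,
  `x 20`, `20 x`, `3 rep`, `x 1'` = 60 s, with the minutes-vs-feet
  apostrophe disambiguated by locomotion context);
* **per-concept classifiers** over an uncased bag-of-words space: logistic
  regression, degree-2 polynomial SVM, AdaBoost (100 stumps), and gradient
  boosting (50 trees) — one model per concept and family;
* **prompt generation** for chat-model extraction: per-concept yes/no
  prompts, zero-shot or few-shot with 2 positive + 2 negative worked
  examples, a pluggable backend contract and a deterministic offline mock;
* a **synthetic note generator** that emits gold-labeled sections in the
  real documentation style (the private corpus behind the original
  annotations is not redistributable), making every stage testable;
* an **evaluation harness**: per-concept precision/recall/F1 at sequence,
  span (exact and overlap) and numeric levels, macro averages with a
  minimum-support rule, Fleiss kappa for interannotator agreement, and the
  stratified 250/50 train/test split.

## Worked example

```r
library(rehabext)

ontology <- load_ontology()
ontology
#> Clinical rehabilitation-exercise ontology (version 1.0)
#>   11 categories, 101 concepts (101 binary-classifiable)
#>   scoring groups: type_of_motion, side_of_body, location_on_body,
#>     plane_of_motion, duration, sets_and_reps, exercise_purpose,
#>     exercise_type, body_position

rules <- build_ruleset(ontology)
section <- "1: AROM right elbow flx/ext HEP 2: tandem stance on foam x 1' 3: SLR- 2x10 deferred to HEP"
res <- extract_labels(section, rules)

str(res[[1]]$labels)
#> List of 5
#>  $ binary          : chr [1:6] "desc.hep" "loc.elbow" "motion.active_rom" "plane.extension" ...
#>  $ duration_seconds: int NA
#>  $ sets            : int NA
#>  $ reps            : int NA
#>  $ status          : chr "desc.hep"
```

Item 1 is an active-range-of-motion exercise of the right elbow in flexion
and extension, prescribed as a home exercise program. Item 2 shows the
apostrophe-minutes convention (`x 1'` is one minute, normalized to seconds):

```r
res[[2]]$numerics
#>               kind value start end unit_normalized
#> 1 duration_seconds    60    25  27            TRUE
```

Item 3 ("SLR- 2x10 deferred to HEP") was prescribed for home but not
performed in the clinic; both description labels stay in the binary set and
the status takes the stronger reading:

```r
res[[3]]$labels$binary
#> [1] "desc.hep"           "desc.not_performed" "extype.le_strength"
res[[3]]$labels$status
#> [1] "desc.not_performed"
```

On a synthetic gold corpus the rule extractor can be scored end to end:

```r
out <- run_end_to_end(list(out_dir = "run1", seed = 1, n_sections = 100))
out$report$rules_sequence
#> Evaluation report (sequence level): 101 concepts scored
#>   macro over 61 concepts (support >= 10): P=1.000 R=1.000 F1=1.000
```

(`run1/` now holds the gold corpus and predictions as standoff JSONL, the
report as JSON, and a run manifest with seeds and component versions.)

The perfect score says the tagger and the generator's label conventions are
mutually consistent on clean text — see the methods vignette
(`vignettes/rehabext-methods.Rmd`) for what that does and does not imply
about real notes, and for the ambiguity tier that deliberately breaks it.

A thin command-line wrapper is included at `inst/cli/rehab-extract`
(subcommands `simulate`, `run`, `eval`, `pipeline`, `--version`).

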