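---
title: "A modular minimum-information schema for nanosafety: model, matching and coverage methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A modular minimum-information schema for nanosafety: model, matching and coverage methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitschema)
```

## The problem

Nanosafety experiments produce data whose re-use depends on metadata:
what engineered nanomaterial (ENM) was tested, how it was characterized,
which biological model was exposed, how the dose was delivered, what the
readout instrument measured, and how the numbers were analysed. A
*minimum information table* (MIT) organizes this as a catalogue of
**labeled fields** — named slots that are either *grouping* fields
(structural headers) or *content-bearing* fields (slots that hold a
value in an actual metadata record).

`mitschema` implements that catalogue as a machine-readable schema and
provides the bookkeeping a curator needs around it: validation and
completeness scoring of experiment records, deterministic crosswalks
against external vocabularies, coverage statistics, and export to an
ISA-TAB-like tabular layout.

## The schema model

A `mit_schema` is a flat table of labeled fields. Each field carries a
stable `field_id` (snake-case slug of its name, module-prefixed on
collision), a module, an optional subdivision, synonyms (the schema
deliberately lists alternative names such as *zeta potential* /
*surface charge* to aid interoperability), an applicability branch
(`always`, `in_vitro_only`, `in_vivo_only`), a requirement level, a
value kind with optional unit hint, and a provenance tag naming the
standard the field was drawn from.

The bundled reference schema has six modules — general information,
material information, biological model information, exposure
information, endpoint read out information, and analysis and statistics
— with 33 grouping and 300 content-bearing fields, the content-bearing
fields distributed 22/32/69/48/98/31:

```{r stats}
schema_stats(build_reference_mit())
```

The complete published field inventory is distributed as a spreadsheet
supplement rather than in running text, so the bundled schema is a
reconstruction that is exact in structure: the module set, the grouping
and content-bearing cardinalities, the in vitro / in vivo branching of
the biological-model and exposure modules, and every field name that the
accompanying literature prints (experiment name, compound name, major
use, zeta potential with synonym surface charge, dispersion protocol,
passage number, seeding density, plate format, delivered dose,
statistic, and the three endpoint instrument groups: flow cytometry,
light and electron microscopy). Remaining fields are domain-standard
metadata names chosen to fill each subdivision to its printed
cardinality and are tagged `provenance = "reconstructed"` so they are
distinguishable from sourced fields. Subdivision depth is capped at one
level below the module, matching the published structure overview.

Grouping fields structure the schema but store no values; they carry no
value-kind constraint and never enter completeness denominators. The
published material does not state how the 33 grouping fields distribute
over modules, so no per-module grouping invariant is asserted anywhere;
here they are the 6 module headers plus 27 subdivision headers.

Serialization uses a canonical CSV dialect (one row per field, mirroring
the spreadsheet origin of such tables), with lossless JSON and XML
projections; `load(save(x))` is `identical()` to `x` in every dialect,
and the CSV dialect is byte-stable. To make that hold across dialects
the constructor canonicalizes row order (stable sort by module).

### Extension profiles

New approach methodologies need fields the base table does not carry.
`nam_profile()` bundles three profiles — `ali` (air–liquid interface
inhalation models: aerosol generation method, dilution, volume flow,
flow alignment, particle deposition, apical/basal culture conditions),
`intestine_advanced` (mucus layer, specialized cell types, peristalsis,
food-matrix and digestion simulation) and `skin_3d` (skin layer
coverage, UV damage, penetration and irritation/sensitization/corrosion
readouts). `merge_profile()` appends profile fields tagged with the
profile id; id collisions are an integrity error, which also makes
double-merging fail loudly rather than silently duplicating fields.
Profile field names were chosen to avoid token-subset overlap with base
fields so that merged schemas remain well-behaved under partial
matching.

## Records and completeness

A `mit_record` maps content-bearing field ids to values, with a model
context (`in_vitro`, `in_vivo`, `both`). Validation reports three kinds
of findings: unknown keys, value-kind violations (a quantity field with
no numeric content, a boolean field with a non-boolean literal), and
applicability violations (an in-vivo-only field in an in-vitro record).
An empty record is *valid* — emptiness is a completeness matter.

Completeness is the fraction of applicable content-bearing fields the
record fills, per module and overall. Design choices:

* **Presence** means at least one non-empty value. The sentinel
  `"not applicable"` counts as present (and passes value-kind checks):
  the experimenter addressed the field, which is what a completeness
  audit wants to know. Omission and inapplicability are different
  states.
* **Applicability**: `model_context = "both"` makes both branches
  applicable — a conservative denominator.
* **Unknown keys never count** toward the score; completeness measures
  schema coverage, not data volume.
* The published material does not designate which fields are strictly
  minimal versus contextual, noting instead that the required subset
  depends on the research question. The reference schema therefore
  defaults every field's requirement to `minimum` and leaves the level
  editable (profiles can override it); the `requirement_floor` argument
  of `completeness_score()` selects the denominator.

```{r completeness}
sch <- build_reference_mit()
rec <- generate_record(sch, p_present = 0.5, seed = 7)
completeness_score(rec, sch)
```

## Crosswalks: exact and partial matching

The published compatibility analysis mapped the MIT against two
external targets — the eNanoMapper ontology and the ISA-TAB-Nano
standard — by expert judgment in spreadsheets, one decision per labeled
field. That expert judgment is not reproducible algorithmically, and
this package does not pretend to replicate it. What it provides is a
*deterministic algorithmic proxy* plus a curated-override layer, so
published decision sets can be loaded as data and all the bookkeeping
recomputed:

* `normalize_label()` case-folds, strips punctuation and tokenizes.
* `match_exact()` declares a one-to-one match when the normalized field
  name **or any field synonym** equals a term label or term synonym.
  Ties break to the lexicographically lowest `term_id`.
* `match_partial()` implements "more generally labeled" targets: a term
  is a candidate when one token set is a non-empty *proper* subset of
  the other (e.g. *protocol* ⊂ *dispersion protocol*), scored by the
  Jaccard similarity of the token sets (0.5 in that example). Identical
  token sets are exact-matching territory and are never returned as
  partial. The token-subset rule is a declared proxy, not a claim about
  the original curators' procedure.
* `auto_crosswalk()` applies precedence curated > exact > partial >
  none and always returns a **total** crosswalk: exactly one decision
  per schema field, grouping fields included (they are matched like any
  other field but reported in their own stratum, since the two field
  categories are published separately).

The default `min_score = 0.25` admits the canonical
one-token-generalization (score 0.5) while rejecting single-token
overlap against long labels; it is exposed as an argument and a CLI
flag. The mapping is a function, not a relation: one target term per
source field, resolved by score then term id, which is what makes the
published counts sum exactly.

## Coverage statistics

`coverage_report()` counts matched fields per stratum — each module's
content-bearing fields, the grouping and content-bearing categories,
and overall — in `one_to_one` mode (exact only) or `partial` mode
(exact ∪ partial). Percentages are **rounded half-up** to integers;
this is the only rounding rule consistent with all published pairs
(55/333 = 16.52 → 17, 11/31 = 35.48 → 35, which half-even would round
differently). Zero-total strata report 0% with an `empty_stratum` flag
rather than erroring, since profiles may create empty strata.

`crosswalk_from_counts()` builds a deterministic crosswalk realizing
requested per-stratum exact/partial counts (fields filled in schema
order), which is how the worked examples and the acceptance checks
reproduce every published (matched, total, percent) pair:

```{r coverage}
cw <- crosswalk_from_counts(sch, rbind(
  data.frame(stratum = "grouping", exact = 8L),
  data.frame(stratum = mit_modules(),
             exact = c(14L, 29L, 16L, 13L, 22L, 11L))))
coverage_report(cw, "one_to_one")
```

One published inconsistency is deliberately left alone: the six
ISA-TAB-Nano per-module partial counts (13+26+58+45+15+26 = 183) do not
sum to the published overall partial count (257 of 300), whereas the six
eNanoMapper per-module counts sum exactly to the one-to-one total
(105). The test suite asserts each published pair individually and does
not assert cross-consistency for the ISA-TAB partial figures; where a
total is needed alongside per-module figures, the fixtures use an
internally consistent split and assert only the published numbers.

## Synthetic fixtures and what they do (not) show

`generate_vocabulary()` plants, per schema field with probabilities
(`p_exact`, `p_partial`, `p_none`), an exact label copy, a one-token
perturbation, or a fresh label drawn from a disjoint token alphabet,
returning the planted truth. Construction guarantees that
`auto_crosswalk()` recovers the plant *exactly*, which makes the ground
truth exact rather than probabilistic:

* "none" labels share no tokens with any field, precluding accidental
  matches;
* partial plants default to *adding* a unique qualifier token, whose
  interference analysis is tractable: a planted field's own term always
  dominates any cross-field candidate;
* `drop_qualifier_token` drops a token instead, but only when the
  result collides with no other field's token set, falling back to the
  add-perturbation otherwise;
* real schemas contain nested names ("density" ⊂ "effective density"),
  which could let a planted-none field partial-match a neighbour's
  term; a deterministic repair pass swaps such plants with unrelated
  fields, preserving the drawn type frequencies.

`generate_record()` fills each applicable content-bearing field
independently with probability `p_present`, with values conforming to
the field's value kind. Both generators take an explicit integer seed
as part of their public contract and restore the global RNG state.

These generators emulate the *bookkeeping* conditions of a
compatibility analysis — label identity, one-token generality, total
decision sets — not the linguistic reality of ontology labels. Real
vocabularies contain near-synonyms, morphological variants
("statistic"/"statistical") and cross-lingual labels that neither the
exact nor the token-subset rule captures; passing the planted-recovery
tests therefore demonstrates the engine's correctness on its own terms,
not that automatic matching approximates expert curation on real
ontologies. That gap is exactly why the curated-override layer exists.

## ISA-TAB export

`record_to_isatab()` routes record values into the four-table
Investigation/Study/Assay/Material layout using the published module
correspondence: general information → investigation, biological model
information → study, material information → material, endpoint read out
→ assay. The published correspondence is explicitly "rough" and names
no home for two modules; this package routes exposure information to
the study table and analysis/statistics to the assay table, following
the published observation that ISA-TAB holds statistical evaluation
only as the "Statistic" field of its Assay file. Values are emitted
under the generic `Parameter Value[...]` column convention. The export
partitions: every value lands in exactly one table, and the bundle
round-trips back to the same field→value set.

## Numerical and degenerate-input choices

* Percent rounding: half-up (see above); `percent_half_up(0, 0) = 0`.
* Matching is entirely deterministic; all tie-breaks are lexicographic.
* Empty schemas, empty records, and empty vocabularies are valid and
  yield zero counts, no findings, and all-`none` crosswalks
  respectively.
* Completeness with an empty denominator is 0, not NaN.
* Problem sizes: tests and the acceptance script run the full
  333-field reference schema against 333-term planted vocabularies and
  300-field records — the scale of the real analysis, chosen because
  the engines are exact at this size in well under a minute.

## Known limitations

* The reconstructed field inventory is faithful in structure and in
  every published name, but individual reconstructed field names are
  not the published supplement's names; analyses that depend on the
  identity of unpublished field names should load their own schema CSV.
* Automatic matching is lexical only — no embeddings, no edit
  distance, no multilingual normalization (by design; see above).
* The ISA-TAB export is a tabular convention, not a validating
  ISA-TAB(-Nano) implementation; the Investigation file's ontology
  source sections are limited to a static header.
* Vocabularies are flat term tables; OWL/OBO ingestion is out of scope
  and users are expected to flatten ontologies to TSV first.
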