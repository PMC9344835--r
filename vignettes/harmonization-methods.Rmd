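---
title: "Harmonizing cohort data against a clinical data model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing cohort data against a clinical data model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmsteward)
```

## The problem

Dementia cohort studies (ADNI-style designs, memory-clinic registries,
population cohorts) measure largely the same things — demographics,
clinical diagnosis, neuropsychological test scores, CSF biomarkers,
APOE genotype — but record them under different column names, units of
discretion, encodings and quality conventions. Pooling such datasets, or
validating a finding from one cohort in another, first requires *semantic
harmonization*: deciding, for every column of every study, which shared
concept it measures, and bringing its values into a single validated
representation.

`cdmsteward` implements the curation workflow around a **clinical data
model (CDM)**: a catalog of standardized variables carrying, for each
variable, a stable identifier, a human-readable label, a free-text
definition, a *modality* (demographics, diagnostics, neuropsychology,
biomarker, genetics, imaging, other), a *data type* (integer, float,
categorical, boolean, date, string), a *value range* (a numeric interval,
an enumeration of categories, or unconstrained) and optional ontology
cross-references as CURIEs. The catalog also accumulates **mappings** —
records of which study columns have already been linked to which variables
— which later act as aliases during matching, so the model gets better at
recognizing new studies as it is used.

## The matching model

Fuzzy matching of column names is deliberately simple and fully
reproducible. Labels are first normalized: lowercased, every run of
characters outside `a–z0–9` collapsed to a single space, trimmed
(`normalize_label()` is idempotent). The similarity of two normalized
labels is

$$\mathrm{sim}(a,b) \;=\; \max\!\Big(\,1-\tfrac{\mathrm{lev}(a,b)}{\max(|a|,|b|)},\;
 1-\tfrac{\mathrm{lev}(\tilde a,\tilde b)}{\max(|\tilde a|,|\tilde b|)}\Big)$$

where $\mathrm{lev}$ is the Levenshtein distance and $\tilde a$ is $a$ with
its whitespace tokens sorted alphabetically (the *token-sort ratio*, which
makes word order irrelevant). Two empty strings score 1; exactly one empty
string scores 0. The score is symmetric, lies in $[0,1]$, and equals 1
exactly when the normalized strings are equal or token-sort equal. The edit
distance itself is computed by `utils::adist()`; the test suite and the
acceptance script verify the whole contract against an independently
written dynamic-programming implementation.

Candidate decisions are controlled by two thresholds exposed in
`match_config()`:

| parameter | default | meaning |
|---|---|---|
| `auto_threshold` | 0.95 | at/above: mapping accepted automatically |
| `review_threshold` | 0.70 | at/above (but below auto): queued for review |
| `k` | 5 | candidates returned per source label |

The defaults are a design choice, not an empirical fit: 0.95 admits only
near-exact variants (case, punctuation, word order, one typo in a long
label) for unattended acceptance, while 0.70 is roughly where, for short
clinical variable names, shared-substring coincidences start outnumbering
true synonyms. Both are per-call configurable, and review-band columns are
*never* auto-resolved — they stay unmapped unless a manual override names
the target, which keeps the human in the loop exactly where the score is
ambiguous. When no variable fits at all, `lookup_terms()` ranks an offline
ontology-term catalog (CURIE, label, source ontology — a CSV snapshot
standing in for a live terminology service) by the same similarity score to
suggest a term a new variable could be anchored to.

Matching consults canonical labels *and* stored aliases, but not
definitions; free-text definitions are only scored by the catalog search
(`search_model()`), which adds a +0.25 exact-substring bonus so that a
single query word occurring inside one definition reliably surfaces that
variable.

## The standardization pipeline

Harmonization proceeds in four explicit steps, each a plain function:

1. `ingest_table()` — read the study CSV as strings, reject ragged rows
   and duplicate or missing subject columns up front (with row locators);
2. `resolve_columns()` — apply the matcher column-wise; manual overrides
   take precedence; subject/visit columns are never mapping targets;
3. `standardize()` — coerce and validate every (row, mapped column) cell
   into one typed entity–attribute–value record;
4. `repo_store()` / `repo_query()` — accumulate records in a repository
   queryable by study, subject, variable, modality and status.

Coercion rules: integers must parse as whole numbers; floats as finite
numerics; booleans accept `true/false`, `1/0`, `yes/no` case-insensitively;
dates must be ISO-8601 calendar dates; categorical values match the
enumeration case-insensitively and are stored in canonical case. The
missing-value vocabulary defaults to `"", NA, N/A, NaN, .` and is
configurable. Validation failures are *flagged, not dropped*: a record with
status `out_of_range` or `type_error` keeps its raw value and a null typed
value, so the validation report is a complete audit of the input
(`strict = TRUE` opts into fail-fast rejection instead). Counts are
conserved by construction — records emitted = rows × mapped columns — and
the suite asserts this on randomized inputs.

The long (EAV) record format was chosen over a wide table because
heterogeneous studies share few columns, and both FHIR and OMOP exports are
naturally row-wise. The repository persists as newline-delimited JSON: it
is diff-able, append-friendly, and needs no database.

## Serializations

**Catalog formats.** CSV (one row per variable; categories and ontology
references pipe-separated; mappings in a `_mappings.csv` companion; model
metadata on a `#meta` comment line) and a single JSON document. Numeric
range bounds are written with 17 significant digits so round-trips are
bit-exact.

**SKOS/RDF.** The model exports as a SKOS concept scheme: one
`skos:Concept` per variable with `skos:prefLabel`, `skos:definition`,
`skos:notation`, `skos:broader` to its modality concept, `skos:exactMatch`
to ontology terms (as identifiers.org IRIs), and data type/range carried by
small annotation properties under a stable base URI. This vocabulary was
chosen over full OWL because it round-trips without reasoning:
`import_model_rdf(export_model_rdf(m))` restores the model field by field,
a property tested on random models in both Turtle and RDF/XML. The Turtle
emitted is deliberately one-triple-per-line (an N-Triples-compatible
subset), and the suite additionally checks it with an independent RDF
parser.

**FHIR.** Bundles are R4, `type = "collection"`: one `Patient` per
subject, one `Observation` per valid record, values typed as
`valueQuantity` / `valueCodeableConcept` / `valueBoolean` /
`valueDateTime` / `valueString` according to the variable's data type, and
`Observation.code` carrying the variable id in a local code system.
Non-valid records are skipped and counted, never silently dropped.

**OMOP.** Export follows the OMOP CDM v5.4 core-table shapes with a
rule-based default domain assignment: sex/gender and birth-year variables
populate PERSON attributes (standard gender concept ids 8507/8532), numeric
biomarker and neuropsychology variables become MEASUREMENT rows
(`value_as_number`), everything else OBSERVATION rows (`value_as_string`).
`omop_concept_id` defaults to 0, the OMOP convention for "no matching
standard concept"; a caller-supplied concept map overrides both domain and
concept. The export partitions valid records exactly — every record lands
in one table or one person attribute — and the counts reconcile with the
validation report, which the suite asserts.

## The synthetic cohort generator

`generate_patients()` draws virtual patients against the built-in
12-variable schema. A baseline diagnosis (CN/MCI/AD with probabilities
0.35/0.40/0.25) is drawn first; every score and biomarker then comes from a
diagnosis-conditioned normal distribution clipped to the schema range —
e.g. MMSE centered at 29/27/21 (sd 1/2/4) for CN/MCI/AD, CSF amyloid-beta
1-42 at 1100/900/600 pg/ml, APOE ε4 allele counts drawn with
diagnosis-dependent weights. The location/scale choices reproduce the
direction and rough magnitude of the gradients familiar from published
dementia cohorts; they are the package's own parameterization, fixed here
once, not a fit to any real dataset. `expand_cohort()` then duplicates the
base patients (cycling, fresh subject ids) to a target size — the
deliberate default is duplication *without* perturbation, so the expanded
multiset is exactly the base multiset repeated; optional jitter adds seeded
Gaussian noise (sd = 2% of each numeric range) with clipping.

What the generator emulates: ADNI-style column names (via the schema's
stored aliases), realistic marginal locations, diagnosis-conditioned
shifts, seed-exact reproducibility. What it does *not* emulate: real
covariance structure between tests and biomarkers, longitudinal visits,
site effects, informative missingness. Passing tests therefore demonstrate
the *mechanics* of mapping, validation and export on realistic-shaped
input, not statistical fidelity to any real cohort.

`synthetic_dementia_cdm()` extends the core schema with templated variables
to a requested size (default 277) so that catalog loading, search and RDF
export are exercised at the scale of a full curated dementia CDM; it is a
synthetic stand-in, and says so in its documentation.

## Numerical and design choices

* **Determinism everywhere**: search and suggestion ties break
  lexicographically (by variable id, by CURIE); generators take explicit
  seeds and restore the caller's RNG state; repeated runs are
  byte-identical, which the suite asserts.
* **Degenerate inputs**: empty models, empty record sets, zero-row tables
  and header-only CSVs are all legal and round-trip; a numeric range may be
  a single point ($\min=\max$).
* **Case folding**: category uniqueness and categorical matching are
  case-insensitive, with canonical-case storage, because clinical exports
  disagree on casing far more often than they mean different categories.
* **Problem sizes**: the test suite and acceptance script run the oracle
  comparison at 10 000 string pairs, round-trips at 100 random models, and
  the cohort pipeline at 1 000 and 10 000 patients — sizes chosen to
  exercise every code path at the scale the workflow targets while keeping
  a full run in the order of a minute or two.
* **Errors are classed conditions** (`dst_*`), so callers and the CLI can
  distinguish user errors (exit 1) from internal failures (exit 2).

## Limitations

Matching is lexical only — no embeddings, no multilingual support — so
true synonyms with disjoint wording (e.g. `"ABETA"` vs a never-mapped
`"amyloid"`) are found only once recorded as aliases or via the ontology
catalog. Unit conversion and derived variables (e.g. height/weight to BMI)
are out of scope: values are validated, not transformed. The OMOP export
implements structural alignment with a rule-based default domain map, not a
vocabulary-complete ETL; the FHIR export produces bundles, not a server.
Visit identifiers are carried through verbatim without an encounter model.
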