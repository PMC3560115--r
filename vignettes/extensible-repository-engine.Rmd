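---
title: "An extensible metadata repository engine: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An extensible metadata repository engine: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrepo)
```

## The problem

Multidisciplinary clinical studies — a neurodegeneration study combining
clinical evaluations, neuropsychological batteries, candidate-gene
screening, brain imaging and frozen blood samples is the motivating case —
outgrow fixed database schemas quickly. Every new assay is a new record
structure, and a conventional design requires a schema migration, a rebuild
and a redeploy before the first record can be entered. `xrepo` implements
the alternative: data types are themselves data. A study member defines a
new type at runtime as a small XML schema; instances of it can be inserted,
validated, queried and displayed immediately, and the type can be extended
later without touching the records already stored.

## The meta data model

A data type is a **header** (name, version, description, whether instances
carry physical files, provenance) plus one or more **groups**, each an
ordered mix of **attributes** and **loops**.

An attribute is one piece of metadata with a value kind from
`{text, integer, decimal, date, boolean, enumeration}`, a required flag,
optional unit, optional default, optional ontology annotation, and — for
enumerations — the list of allowed values. The kind vocabulary is a design
choice: these six cover every field the motivating study records (scores,
dates, sex, gene names, smoking flags); bounds, patterns or cross-field
constraints are deliberately out of scope.

A loop is a repeatable block of attributes for information whose structure
is known but whose multiplicity is not: one iteration per reagent used, one
per risk factor assessed. Loops hold attributes only — they do not nest.
The flat form matches every repetition the use cases exhibit, and nesting
would complicate both the EAV projection and the query semantics with no
supporting need.

Names are unique case-insensitively within their namespace (groups in a
schema; attributes and loops together within a group; attributes within a
loop), with the original casing preserved for display. Case-folding the
uniqueness check prevents silent collisions once values are flattened to
entity-attribute-value rows.

Ontology support is a suggest-as-you-type prefix match over the `[Term]`
stanzas (`id:`/`name:` lines only) of an OBO flat file. Prefix matching —
not fuzzy search — is the minimal mechanism that makes standard annotation
labels easy to adopt; the reader is hand-written because only those two
lines per stanza are consumed.

### Evolution

`evolve_datatype()` applies a change list and bumps the version by one.
Additive changes (add attribute, loop, group or enumeration value; relax
required to optional) are always safe under one rule: an added attribute
must be optional or carry a default, so every instance recorded under the
old version still validates under the new one. Destructive changes
(removing a path, re-requiring a field) are applied only when the store
holds no instances of the type. Old versions are retained immutably;
instances pin the version they were written under, and validation always
uses the pinned version. Queries run against the latest version's paths,
through which older instances participate via the paths they share.

## Instances, validation and the dual representation

An instance supplies plain attribute values, loop instances (ordered
iterations of attribute values) and, for file-associated types, file URIs —
never payloads. Validation is total and deterministic: every
(instance, schema) pair yields a report tibble; an empty report means every
required attribute is present, every value satisfies its kind and
enumeration, no unknown paths occur and every loop iteration is complete.
Unknown paths are violations, not silently dropped — anything else would
corrupt the EAV projection. Dates are ISO-8601 calendar dates; decimals are
validated as exact decimal strings and stored canonically (no trailing
zeros), so validation never depends on floating-point parsing. A loop with
zero iterations is valid: the sources are silent on a minimum, and an empty
repetition is meaningful (no risk factors assessed yet).

Every saved instance is persisted twice, in one transaction:

* the canonical **XML document**, for fast integrated display, and
* its flattened **EAV rows** `(instance, group, loop, iteration, attribute,
  kind, value)`, for dynamic querying.

The canonical text encodings are injective per kind, which is what makes
the two representations checkable against each other: `consistency_check()`
re-derives the rows from each document and compares. `load_instance()`
reconstructs from either side and the results are structurally identical —
callers cannot tell which representation served them. When an event later
claims an instance, both representations are updated together. The engine
always maintains both representations; storing only one of them is a
deployment optimization elsewhere, not a semantic option here.

Iteration indices are 0-based in storage and 1-based in display; this is
stated once here and tested.

### The store

The storage contract is narrow: typed tables behind transactional
operations, one store per file. The reference backend keeps the tables as
tibbles in memory and persists the whole store as a single JSON document
(written atomically to a temporary file and renamed); mutations are
per-call transactions — tables are copied, modified and committed only on
success, so a failed save leaves no partial rows. `store_export()` writes a
directory of schema and instance XML documents plus a JSON manifest;
exports of equal-content stores are byte-identical (the append-only
operation log is excluded from exports as telemetry, not content).

## The process-event provenance taxonomy

Processes are ordered hierarchical containers of sub-processes and events;
events are atomic leaf operations (an acquisition, an analysis step, a
blood draw, an administrative action) owned by exactly one process and
optionally carrying data instances. The structure is a forest; children
order is insertion order and means sequence. `timeline()` reports the
depth-first structural order — the sequence in which operations were
performed — and carries each event's timestamp so callers wanting strict
chronology can sort on it; both orders are available because acquisition
timestamps and protocol order legitimately differ. No reorder operation is
provided: the sources describe sequential accumulation, nothing more.

The standard clinical-experiment exchange hierarchy maps onto the model via
`xcede_level_kind()`: visits and studies are processes (study under visit),
episodes and acquisitions collapse into events, project and subject are
context rather than tree nodes. Process types may restrict their permitted
child types; an empty restriction list means "any", the permissive default
matching free taxonomy building.

## Dynamic queries

A query is a conjunction of **subject conditions** (diagnosis, sex, birth
date) and **data conditions** (existence of a data type, or a comparison on
one attribute path). Composition — not execution — validates everything:
unknown types or paths and operator/kind mismatches are rejected when the
condition is built, so any composed query runs. Semantics, fixed and
documented because the sources leave them open:

* conjunction only — conditions accumulate with AND; OR and grouping are
  not modelled;
* each data condition is **independently existential** over the subject's
  instances: a subject matches if *some* instance satisfies it, and two
  conditions on the same data type may be satisfied by different instances;
* loop conditions are existential over iterations ("is a smoker" = some
  risk-factor iteration matches);
* text `eq` is case-insensitive exact and `contains` is case-insensitive
  substring — forgiving defaults for clinician-typed values;
* ordering operators apply to numbers and dates only (and, among subject
  fields, to birth date only).

Execution filters the EAV table. Its verification oracle,
`query_reference()`, is an independent implementation of the same
semantics that never reads the EAV table: it parses every instance from its
canonical XML and filters with plain R loops. The central property test of
the package holds the two routes equal over hundreds of random queries
against a seeded store. Note the worked "smoker" condition is composed as a
single field condition on the risk-factor label; tying `factor = "smoke"`
and `present = true` to the *same* iteration would need a conjunction
within one loop iteration, which the condition language deliberately does
not model.

`subject_overview()` renders the integrated per-subject view: all instances
grouped by data type with their values and file URIs, plus the provenance
timeline, as text or minimal HTML.

## Access control and anonymity

Subjects are structurally anonymous: the subject type has no field for a
personal name, so no rendering or serialization can leak one. Permissions
are default-deny and group-based; resources are data types, named engine
functions (pages being a UI notion, they collapse into functions), and the
special `subject_personal_data`. Which subject fields count as personal is
configurable and defaults to the birth date — sex and diagnosis are
clinical variables. Masking is applied at the data layer (`masked_view()`),
so it survives every rendering; overviews additionally omit data types the
user may not view. Authentication is out of scope: the engine trusts the
caller-supplied identity, and every mutating call appends one line to an
operation log (the minimal audit the design calls for).

## Samples

Freezer benches are -80C or -45C, hold named racks of numbered slots, and
every slot holds one sample box with a uniform x-y grid (per-slot variation
has no textual support). Coordinates are 1-based numeric columns and rows,
with A1-style rendering as a formatting option. The occupancy invariant —
at most one sample per coordinate — is enforced on placement and movement;
bounds are re-checked when a freezer is reconfigured so located samples can
never be stranded. Shipment is modelled as located-nowhere with a courier
number rather than a destination pre-assignment, matching a courier
workflow between sites with independent freezers; the history (registered,
placed, moved, shipped) is append-only with non-decreasing timestamps.

## Imaging

Modality profiles map DICOM header tags onto the attribute paths of a
file-associated data type and name the event type created on upload. The
default tag maps are intentionally minimal — study date, series
description, echo/repetition time for MR, radiopharmaceutical for PT/NM —
and user-extensible, since the authoritative tag set per modality is not
prescribed anywhere. DICOM has no functional-MRI modality code, so MR files
are classed as fMRI by a configurable series-description pattern
(default: contains "fmri" or "bold", case-insensitive). Registration is
atomic: one validated instance with the file URI attached plus one
modality event, or nothing. Patient-identifying tags (PatientName,
PatientID) are excluded from extraction unconditionally, consistent with
the anonymity model; image defacing is out of scope.

The DICOM layer itself is a minimal explicit-VR little-endian reader and
writer: the synthetic fixture writer is first-class engine functionality
(it is what makes the imaging path testable without downloads), and the
reader handles exactly what the writer emits plus required-tag lookup. One
test cross-checks the writer's output against an independent DICOM parser.

## The synthetic cohort

`generate_cohort()` emulates the motivating study: by default 20 subjects
(the study's initially inserted enrollment), diagnosis mix 35% controls,
40% amnestic MCI (split single-/multi-domain), 25% Alzheimer's disease —
proportions chosen once as a plausible memory-clinic case mix, not reported
values. Each subject gets a visit/study process pair; a clinical evaluation
with a three-iteration risk-factor loop (smoke/alchool/sedentary job — the
second label kept as the sources spell it); a neuropsychological battery
whose delayed-recall score (0-15) is drawn from diagnosis-dependent ranges
(controls 6-15, aMCI 2-10, AD 0-7) so that the "score below 6" query is
discriminative; zero to two candidate-gene variants (MAPT among the genes,
with static gene-page and variant-section URL patterns standing in for live
external integration); structural MRI with probability 0.85, FDG-PET 0.5,
resting-state fMRI 0.25, registered from synthetic DICOM files; and one
placed blood sample, every fourth shipped by courier.

Everything derives from the seed: timestamps come from fixed base dates
plus the subject index, imaging files get deterministic repository URIs
(`xr://images/...`) rather than temp paths, and bootstrap schemas carry a
fixed creation timestamp — two runs with the same specification export
byte-identically. What the generator does **not** emulate: missing and
contradictory clinical data, free-text noise, longitudinal visits,
realistic genetic allele frequencies, or image pixel content. Green tests
therefore demonstrate the engine's structural correctness on clean,
well-formed data, not robustness to the full messiness of real studies.

## Verification approach and problem sizes

The test suite is property-based where it matters, with independent
oracles: serialize/parse identity over 200 random schemas; validation over
200 random (schema, conforming instance) pairs with one targeted mutation
each, where the report must name exactly the mutated path; EAV-vs-XML
equivalence over whole cohorts; EAV query execution against the
XML-scanning reference over 500 random query specifications on a
200-subject store; forest and occupancy invariants under 1,000 random
operations each; 50-file imaging round trips. These sizes exercise the
engine well past the motivating study's scale (20 subjects, ~50/year
planned) while keeping the default `R CMD check`-style run in minutes on a
single CPU.

## Known limitations

* Conjunction-only queries; no OR, no grouping, no same-instance or
  same-iteration coupling across conditions.
* The JSON-file backend is single-writer, whole-store-in-memory; the
  storage contract would admit a server RDBMS backend, but none ships.
* No XSD generation or external schema-language validation; the XML
  dialects are validated structurally by the parser itself.
* Loops do not nest; groups do not repeat (only attribute-level loops are
  modelled).
* One instance links to at most one event (a single optional reference —
  multi-event linkage is not modelled).
* Ontology suggestion is prefix-only and reads `[Term]` id/name lines only.
* No workflow execution, no service association with events, no image
  viewing or defacing, no statistical analysis of stored cohorts.
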