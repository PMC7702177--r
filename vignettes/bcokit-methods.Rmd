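---
title: "bcokit: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bcokit: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcokit)
options(bcokit.now = "2020-06-01T12:00:00Z")
```

## What a BCO records, and what this package automates

A BioCompute Object (IEEE 2791-2020) documents a high-throughput sequencing
analysis across eight content domains plus three top-level fields. The key
observation behind this toolkit is that most of a BCO's content is already
machine-readable: the *description* domain's pipeline steps and the
prospective *input/output* entries live in the workflow's CWL definition, and
the realized files, parameter settings, and platform details live in the
execution record of the platform that ran it. Only provenance, usability, and
error expectations genuinely need an author. `bcokit` therefore offers three
composer paths of increasing automation — text-only, CWL, and platform task —
all converging on the same `compose()` core, and a validator that checks what
the composers emit.

## The CWL model

`parse_cwl()` normalizes a workflow document into ports, steps, and bindings:

- **Identifiers.** CWL ids can carry URI prefixes and fragments
  (`file:///wf.cwl#main/reads`). `normalize_id()` strips everything up to the
  fragment, the leading `#`, and the enclosing process's prefix; it is
  idempotent, which the test suite checks as a property over random id
  shapes.
- **Shorthand forms.** Map-form `inputs`/`outputs`/`steps` and string-typed
  ports are converted to the list-of-records form, so downstream code sees
  one shape.
- **Versions.** v1.0–v1.2 are accepted; any other `cwlVersion` produces a
  warning and a best-effort parse as v1.2. The upstream application never
  pinned a version, so refusing old documents would only lose information.
- **Subworkflows** are parsed to depth one: a step whose `run` is an embedded
  workflow stays a single step. The wiring diagram and the BCO description
  domain both describe the *top-level* pipeline; recursive flattening would
  invent steps the platform never scheduled. This is our choice — the
  upstream work does not specify nested-workflow handling.
- **Scatter, `when`, requirements** are preserved in `$raw` and ignored by
  the model: none of them feed a BCO field.

`build_graph()` turns the parsed model into a DAG with namespaced node ids
(`input:x`, `step:y`, `output:z`) so a step and a port may legally share a
name. Dangling source references fail fast with the offending reference in
the message, because a silently dropped edge would propagate into a wrong
description domain. Parallel bindings between the same two nodes collapse to
one edge for diagram clarity; multiplicity stays visible in the model's
bindings. The topological order uses Kahn's algorithm with the
lexicographically smallest ready node chosen each round, making the order —
and hence diagram text and pipeline-step numbering — unique and
byte-reproducible. Off-the-shelf graph libraries compute *a* topological
order but do not promise this tie-break, so the sort is implemented here and
tested against the brute-force all-edges-point-forward oracle.

## Canonical serialization and the etag

The standard says the integrity value is a SHA-256 over "all non-top-level
domains" without fixing the byte serialization. This package defines it as
canonical JSON — UTF-8, object keys sorted bytewise at every depth, no
insignificant whitespace, no trailing newline — of an object holding exactly
the eight content domains. Numbers use the shortest decimal string that
round-trips to the same double (integer-valued doubles print without a
decimal point); non-ASCII characters are emitted as raw UTF-8, not `\u`
escapes. The implementation is validated in the tests against frozen byte
strings and digests computed with an independent canonical-JSON
implementation (Python's `json` + `hashlib`).

Because the serialization dialect is ours, interoperability with etag values
produced by *other* 2791 implementations is not asserted; the validator
checks self-consistency of documents this package (or anything following the
same documented rules) produced.

One representational subtlety: R's JSON parsers return a bare empty `list()`
for both `{}` and `[]`. Serialization resolves the ambiguity with tagged
`json_obj()`/`json_arr()` values, and `read_bco()` repairs the three paths in
this dialect whose empty value must be an object (`empirical_error`,
`algorithmic_error`, `environment_variables`). An unknown, user-added field
holding an empty object will round-trip as `[]`; this is a documented
limitation, irrelevant to the digest because both writer and reader apply the
same convention.

`compose()` is deterministic under a frozen clock
(`options(bcokit.now = ...)`): timestamps come from an injectable clock, and
a caller-absent `object_id` is a *name-based* UUID derived from the
provenance name and creation time — fresh whenever the clock moves, but
reproducible in tests. A random UUID would have made "same inputs, same
object" untestable.

## Dialect choices in the domain schemas

`jsonvalidate` is unavailable in the supported environment and the normative
2791 schema files cannot be fetched offline, so the package vendors compact
per-domain schemas (in `inst/schemas/`, each marked with a `$comment`) and a
small JSON-Schema-subset checker (`type`, `required`, `properties`, `items`,
`enum`, `pattern`, `minItems`). Two deliberate deviations from the normative
schemas, both visible in the schema files:

- parametric entries use `step_number` (integer, referencing a
  description-domain step) rather than the standard's string-valued `step`;
- pipeline-step `input_list`/`output_list` entries are port-identifier
  strings rather than `{uri: ...}` records, since the CWL composer has no
  URIs for prospective ports.

Severity policy (the upstream work grades nothing): integrity mismatch and
schema violations are errors; a missing etag, unknown extra top-level
fields, and extension payloads whose external schema we do not hold are
warnings. Validation never raises on bad *content* — every finding goes into
the report; only an unreadable document or a missing schema bundle raises.

## Composer mapping rules

- **Array expansion.** Platform file parameters that are arrays expand to one
  io-domain entry per file, and duplicate URIs are kept. Nothing in the
  upstream description says whether its reported file counts deduplicate;
  expansion is the rule that makes "n input files" well-defined, and it is
  what the fixture-backed acceptance test pins down.
- **Parameters vs files.** Only scalar-representable values enter the
  parametric domain; file values live exclusively in the io domain, avoiding
  double-counting. Task parameter names follow a `step/param` convention;
  a name whose step is absent from the workflow warns and is skipped rather
  than failing the whole composition.
- **Step version** is taken from a trailing `/<digits>` revision suffix on
  the step's run name when present, else left empty.
- **No automatic usability text.** Which CWL fields (if any) the upstream app
  copied into the usability domain is unstated; guessing would put words in
  the author's mouth.

## What the synthetic generators emulate — and what they don't

`generate_cwl()` emits CWL v1.2 workflows with exact input/output/step
counts, `chain` or `random_dag` wiring (acyclic by construction: each step
draws sources only from earlier steps and workflow inputs), a configurable
File-typed port fraction (default 0.5 — realistic pipelines mix file and
scalar parameters), and a scalar `threads` default per step so the
parametric domain has material. `generate_task()` produces completed-status
task records whose *expanded* file counts equal its arguments exactly,
distributing files over the workflow's File ports as arrays. All randomness
flows through a locally scoped RNG seeded from the spec, so identical specs
give identical bytes and generation never perturbs the session RNG.

The bundled `rnaseq-de-pathway-synthetic.cwl.json` is a handwritten stand-in
emulating the structure of the publicly deposited four-step RNA-seq
differential-expression workflow (file-array inputs, per-step parameter
lists); it is labelled synthetic in its name and `doc`. The acceptance tests
that reference the deposited artifacts' headline numbers (4 steps, 102 input
files, 187 output files) run the full parse→compose→count pipeline against
these generators with those numbers as *generator inputs*. A green test
therefore establishes that the pipeline preserves counts through every
layer — not that this package reproduces the deposited bytes, which cannot
be fetched in the offline test environment. The generators also do not
imitate any platform's proprietary task JSON beyond the fields the
`task_record` contract needs, and they do not simulate workflow execution.

## Numerical and degenerate-input choices

- Tie-breaks everywhere are lexicographic (bytewise, `radix` order), chosen
  once so every emitted artifact is deterministic.
- Zero-step workflows are legal throughout: outputs may source directly from
  inputs, the description domain gets an empty `pipeline_steps`, and such
  objects still validate.
- `generate_cwl()` refuses specs whose `n_outputs` exceeds the reachable
  outputs rather than emitting dangling wiring.
- The HTML report prints every scalar leaf of the document (checked by
  string containment on fixtures); PDF is derived from HTML via an external
  converter and errors with advice when none is installed, rather than
  shipping a hand-rolled PDF writer.

## Known limitations

- Etag interoperability with other 2791 implementations is unverified (see
  above).
- CWL expressions (`$(...)`) are not evaluated and CWL documents are not
  themselves schema-validated; the parser is a normalizer, not a linter.
- Only the mock platform adapter ships; live platform clients (with
  authentication) are out of scope and belong behind the `fetch_task`
  adapter contract.
- Extension-domain payloads are not validated against their declared
  external schemas; the validator records a warning instead.
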