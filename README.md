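# bcokit

Compose, validate, and render **IEEE 2791-2020 BioCompute Objects (BCOs)** from
the command line or from R.

## The problem

A BioCompute Object is a JSON document that records how a high-throughput
sequencing analysis was actually run — the workflow's steps, software,
parameters, input and output files, contributors and review trail — across
nine standardized categories: the *provenance*, *usability*, *extension*,
*description*, *execution*, *parametric*, *input/output*, and *error* domains,
plus the top-level fields (`object_id`, `spec_version`, `etag`). The FDA
accepts BCOs for regulatory submission of HTS analyses, but writing one by
hand is tedious and error-prone. Most of its content already exists in two
machine-readable places: the workflow definition (Common Workflow Language)
and the execution record kept by the platform that ran it.

`bcokit` is a scriptable toolkit for that gap, aimed at bioinformaticians who
need to document NGS pipelines reproducibly. It:

- parses CWL v1.0–v1.2 workflows from JSON or YAML, including packed `$graph`
  documents, into a normalized model of inputs, outputs, steps, and wiring;
- builds the workflow's directed acyclic wiring graph and emits deterministic
  Graphviz DOT or mermaid diagram text;
- composes complete BCOs from plaintext author metadata (YAML config), from a
  parsed CWL workflow, or from a platform task-execution record (a bundled
  mock adapter emulates cloud-platform task exports; live clients plug in
  behind the same adapter contract);
- validates BCOs the two ways the standard recommends: a **content-integrity
  check** and per-domain **schema conformance**, reported with severities and
  JSON paths;
- renders printable HTML reports and textual domain-wise inspections;
- ships deterministic synthetic-fixture generators (workflows, task records,
  corrupted BCOs) so everything is testable offline.

## The integrity digest

The `etag` is defined here as

```
etag = SHA-256( canonical_json( { the eight content domains } ) )
```

where `canonical_json` is UTF-8 JSON with keys sorted bytewise at every
depth and no insignificant whitespace, over an object holding exactly the
eight non-top-level domains. Any content edit changes the digest; reordering
keys never does. (The standard prescribes SHA-256 over the non-top-level
domains but not the byte serialization; this canonical form is this package's
documented dialect — see the methods vignette.)

## Worked example

A four-step RNA-seq differential-expression workflow (a synthetic stand-in
bundled with the package) plus a mock platform task record:

```r
library(bcokit)
options(bcokit.now = "2020-06-01T12:00:00Z")  # freeze the clock for reproducibility

wf <- parse_cwl(paste(readLines(system.file(
  "extdata", "rnaseq-de-pathway-synthetic.cwl.json", package = "bcokit")),
  collapse = "\n"))
wf
#> <cwl_workflow> rnaseq_de_pathway_synthetic (v1.2)
#>   inputs:  5  outputs: 4  steps: 4

topological_order(build_graph(wf))
#> [1] "trim_and_qc"             "align_and_quantify"
#> [3] "differential_expression" "pathway_enrichment"

task <- fetch_task(mock_adapter(), "task-1")
task
#> <task_record> task-1 (completed) on mock-platform

meta <- author_metadata(provenance = list(name = "RNA-seq DE & pathway analysis"))
bco <- compose_from_task(task, wf, meta,
                         workflow_path = "rnaseq-de-pathway-synthetic.cwl.json")
bco
#> <bco> urn:uuid:01869682-e6c2-5e94-816c-6b2eeae76ed4/1.0
#>   etag: 229a3347e4f88ec02815685d99ba493df81362c3dc602b594b05d99b750e3822
#>   domains present: 8/8

validate(bco)
#> validation passed: no issues
```

The four workflow steps become the description domain's numbered
`pipeline_steps`, the task's file inputs/outputs become io-domain entries
(file arrays expand to one entry per file), scalar task parameters land in
the parametric domain keyed to their step, and the platform and app revision
are recorded in the description and execution domains. Editing any field
afterwards makes `validate()` fail the integrity check with both digests in
the message.

## Command line

```sh
exec/bcokit compose cwl --in wf.cwl.json --meta meta.yaml --out analysis.bco.json
exec/bcokit validate analysis.bco.json            # exit 0 = valid, 1 = issues
exec/bcokit diagram  wf.cwl.json --format mermaid
exec/bcokit render   analysis.bco.json --out report.html
exec/bcokit inspect  analysis.bco.json --domain provenance
exec/bcokit fixtures generate --out-dir fixtures/ --seed 7
```

Exit codes: 0 success, 1 validation failure, 2 usage/IO error.

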