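Package: bcokit
Title: Compose, Validate, and Render IEEE 2791-2020 BioCompute Objects
Version: 0.1.0
Authors@R:
    person("BCO", "Toolkit Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A scriptable toolkit for the IEEE 2791-2020 BioCompute Object
    (BCO) standard. Reads and normalizes Common Workflow Language (CWL)
    workflow documents from JSON or YAML (including packed '$graph' files),
    builds workflow wiring graphs and emits Graphviz DOT or mermaid diagram
    text, composes nine-domain BCO documents from plaintext author metadata,
    parsed CWL content, or platform task-execution records, validates BCOs by
    SHA-256 content-integrity digest and per-domain schema conformance,
    renders printable HTML reports and textual domain inspections, and ships
    deterministic synthetic-fixture generators plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    uuid,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
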