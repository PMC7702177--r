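test_that("normalize_id strips fragments, URIs, and parent prefixes; idempotent", {
  expect_identical(normalize_id("#main/reads", "main"), "reads")
  expect_identical(normalize_id("reads"), "reads")
  expect_identical(normalize_id("file:///wf.cwl#step1/out"), "step1/out")
  expect_error(normalize_id("#main/", "main"), "empty")
  # idempotence over random id shapes
  set.seed(42)
  frags <- c("", "#", "file:///a/b.cwl#", "https://x.org/wf.cwl#")
  parents <- c(NULL, "main", "wf")
  for (i in 1:50) {
    base <- paste(sample(letters, 5), collapse = "")
    parent <- sample(c("main", "wf", ""), 1)
    raw <- paste0(sample(frags, 1),
                  if (nzchar(parent) && runif(1) < 0.5) paste0(parent, "/"),
                  base)
    once <- normalize_id(raw, if (nzchar(parent)) parent)
    expect_identical(normalize_id(once, if (nzchar(parent)) parent), once)
  }
})

test_that("minimal degenerate workflow parses", {
  yaml_doc <- "
class: Workflow
cwlVersion: v1.2
inputs:
  reads: File
outputs:
  final:
    type: File
    outputSource: reads
steps: []
"
  wf <- parse_cwl(yaml_doc, format = "yaml")
  expect_length(wf$steps, 0)
  expect_length(wf$inputs, 1)
  expect_length(wf$outputs, 1)
  expect_true(wf$inputs[[1]]$is_file)
})

test_that("generated workflows are recovered with the generator's counts", {
  sp <- generator_spec(n_inputs = 2, n_outputs = 1, n_steps = 5, seed = 7)
  wf <- parse_cwl(generate_cwl(sp))
  expect_length(wf$steps, 5)
  expect_length(wf$inputs, 2)
  expect_length(wf$outputs, 1)
})

test_that("JSON and YAML representations parse to identical models", {
  grid <- expand.grid(n_steps = c(0L, 2L, 4L), wiring = c("chain", "random_dag"),
                      stringsAsFactors = FALSE)
  keep <- c("id", "label", "cwl_version", "inputs", "outputs", "steps")
  for (i in seq_len(nrow(grid))) {
    sp <- generator_spec(n_inputs = 2, n_outputs = 1,
                         n_steps = grid$n_steps[i],
                         wiring = grid$wiring[i], seed = 3L + i)
    wj <- parse_cwl(generate_cwl(sp, "json"), format = "json")
    wy <- parse_cwl(generate_cwl(sp, "yaml"), format = "yaml")
    expect_identical(wj[keep], wy[keep],
                     label = sprintf("steps=%d wiring=%s", grid$n_steps[i],
                                     grid$wiring[i]))
  }
})

test_that("map-form and list-form documents normalize identically", {
  map_doc <- '
class: Workflow
cwlVersion: v1.2
inputs:
  reads: File
  threads: int
steps:
  align:
    run: tools/align.cwl
    in:
      src: reads
      n: threads
    out: [bam]
outputs:
  bam_out:
    type: File
    outputSource: align/bam
'
  wf <- parse_cwl(map_doc, format = "yaml")
  expect_length(wf$steps, 1)
  st <- wf$steps[[1]]
  expect_identical(st$id, "align")
  expect_setequal(vapply(st$in_bindings, `[[`, character(1), "source"),
                  c("reads", "threads"))
  expect_identical(st$out_ports, "bam")
})

test_that("errors: malformed text, wrong class, unsupported version", {
  expect_error(parse_cwl("{not json", format = "json"),
               class = "bcokit_parse_error")
  expect_error(parse_cwl('{"class": "CommandLineTool", "cwlVersion": "v1.2"}'),
               class = "bcokit_not_workflow")
  old_doc <- '{"class": "Workflow", "cwlVersion": "draft-3",
               "inputs": [], "outputs": [], "steps": []}'
  expect_warning(wf <- parse_cwl(old_doc), "not a supported")
  expect_s3_class(wf, "cwl_workflow")
  expect_error(
    parse_cwl('{"class":"Workflow","cwlVersion":"v1.2","inputs":[],"outputs":[],
               "steps":[{"id":"a","run":"t.cwl","in":[],"out":["o"]},
                        {"id":"a","run":"t.cwl","in":[],"out":["o"]}]}'),
    "duplicate step ids")
})

test_that("packed $graph selection", {
  tool <- function(id) list(class = "CommandLineTool", id = id)
  wf_entry <- function(id) list(class = "Workflow", id = id,
                                cwlVersion = "v1.2",
                                inputs = list(), outputs = list(),
                                steps = list())
  packed1 <- list(cwlVersion = "v1.2",
                  `$graph` = list(tool("#t1"), wf_entry("#main"), tool("#t2")))
  sel <- select_from_graph(packed1)
  expect_identical(sel$id, "#main")
  packed2 <- list(`$graph` = list(wf_entry("#main"), wf_entry("#alt")))
  expect_error(select_from_graph(packed2), "multiple Workflows")
  expect_identical(select_from_graph(packed2, "#main")$id, "#main")
  packed3 <- list(`$graph` = list(tool("#t1")))
  expect_error(select_from_graph(packed3), "no Workflow")
  # end-to-end through parse_cwl
  wf <- parse_cwl(pretty_json(packed1))
  expect_s3_class(wf, "cwl_workflow")
  expect_identical(wf$id, "main")
})

test_that("output-source resolution is enforced", {
  bad <- '{"class":"Workflow","cwlVersion":"v1.2",
           "inputs":[{"id":"x","type":"File"}],
           "outputs":[{"id":"y","type":"File","outputSource":"ghost/out"}],
           "steps":[]}'
  expect_error(parse_cwl(bad), "unknown step")
})

test_that("port type descriptors normalize", {
  doc <- '{"class":"Workflow","cwlVersion":"v1.2",
           "inputs":[{"id":"a","type":"File"},
                     {"id":"b","type":{"type":"array","items":"File"}},
                     {"id":"c","type":["null","string"]},
                     {"id":"d","type":"int"}],
           "outputs":[],"steps":[]}'
  wf <- parse_cwl(doc)
  types <- vapply(wf$inputs, `[[`, character(1), "type_name")
  expect_identical(types, c("File", "File[]", "string?", "int"))
  expect_identical(vapply(wf$inputs, `[[`, logical(1), "is_file"),
                   c(TRUE, TRUE, FALSE, FALSE))
})
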