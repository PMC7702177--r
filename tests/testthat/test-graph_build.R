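chain_doc <- function() '
class: Workflow
cwlVersion: v1.2
inputs:
  reads: File
steps:
  align:
    run: tools/align.cwl
    in:
      src: reads
    out: [bam]
outputs:
  bam_out:
    type: File
    outputSource: align/bam
'

test_that("smallest chain gives 3 nodes and 2 edges", {
  g <- build_graph(parse_cwl(chain_doc(), format = "yaml"))
  expect_identical(nrow(g$nodes), 3L)
  expect_identical(nrow(g$edges), 2L)
  expect_setequal(g$nodes$kind, c("input", "step", "output"))
})

test_that("generated linear chain has |inputs|+|steps|+|outputs| nodes and n+1 edges", {
  sp <- generator_spec(n_inputs = 1, n_outputs = 1, n_steps = 4,
                       wiring = "chain", seed = 5)
  g <- build_graph(parse_cwl(generate_cwl(sp)))
  expect_identical(nrow(g$nodes), 6L)
  expect_identical(nrow(g$edges), 5L)
})

test_that("node count equals port/step totals across a generator grid", {
  grid <- expand.grid(n_steps = c(0L, 1L, 4L, 10L),
                      wiring = c("chain", "random_dag"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    sp <- generator_spec(n_inputs = 3, n_outputs = 1,
                         n_steps = grid$n_steps[i],
                         wiring = grid$wiring[i], seed = i)
    wf <- parse_cwl(generate_cwl(sp))
    g <- build_graph(wf)
    expect_identical(nrow(g$nodes),
                     length(wf$inputs) + length(wf$steps) + length(wf$outputs))
  }
})

test_that("dangling references are reported by name", {
  bad <- '
class: Workflow
cwlVersion: v1.2
inputs: {reads: File}
steps:
  align:
    run: t.cwl
    in: {src: {source: "ghost/out"}}
    out: [bam]
outputs: []
'
  expect_error(build_graph(parse_cwl(bad, format = "yaml")), "ghost/out")
})

test_that("topological order: forced chains, lexicographic ties, edge-forward property", {
  # forced chain A -> B -> C
  doc <- '
class: Workflow
cwlVersion: v1.2
inputs: {x: File}
steps:
  a: {run: t.cwl, in: {s: x}, out: [o]}
  b: {run: t.cwl, in: {s: a/o}, out: [o]}
  c: {run: t.cwl, in: {s: b/o}, out: [o]}
outputs: []
'
  g <- build_graph(parse_cwl(doc, format = "yaml"))
  expect_identical(topological_order(g), c("a", "b", "c"))

  # two independent steps listed out of order -> lexicographic
  doc2 <- '
class: Workflow
cwlVersion: v1.2
inputs: {x: File}
steps:
  zeta: {run: t.cwl, in: {s: x}, out: [o]}
  alpha: {run: t.cwl, in: {s: x}, out: [o]}
outputs: []
'
  g2 <- build_graph(parse_cwl(doc2, format = "yaml"))
  expect_identical(topological_order(g2), c("alpha", "zeta"))

  # brute-force oracle: all edges point forward on random DAGs
  for (s in 1:5) {
    sp <- generator_spec(n_inputs = 2, n_outputs = 2, n_steps = 8,
                         wiring = "random_dag", seed = s)
    gg <- build_graph(parse_cwl(generate_cwl(sp)))
    ord <- bcokit:::full_topological_order(gg)
    pos <- setNames(seq_along(ord), ord)
    for (k in seq_len(nrow(gg$edges))) {
      expect_lt(pos[[gg$edges$from[k]]], pos[[gg$edges$to[k]]])
    }
  }
})

test_that("cycles are detected", {
  g <- structure(list(
    nodes = data.frame(id = c("step:a", "step:b"),
                       kind = c("step", "step"),
                       label = c("a", "b"), stringsAsFactors = FALSE),
    edges = data.frame(from = c("step:a", "step:b"),
                       to = c("step:b", "step:a"), stringsAsFactors = FALSE)),
    class = "workflow_graph")
  expect_error(topological_order(g), "cycle")
})

test_that("emit_diagram is deterministic, counts match, dialects validated", {
  g <- build_graph(parse_cwl(chain_doc(), format = "yaml"))
  dot1 <- emit_diagram(g, "dot")
  expect_identical(dot1, emit_diagram(g, "dot"))
  expect_identical(length(grep(" -> ", strsplit(dot1, "\n")[[1]], fixed = TRUE)),
                   2L)
  mm <- emit_diagram(g, "mermaid")
  expect_identical(mm, emit_diagram(g, "mermaid"))
  expect_identical(length(grep(" --> ", strsplit(mm, "\n")[[1]], fixed = TRUE)),
                   2L)
  expect_error(emit_diagram(g, "svg"))

  # empty graph: header/footer only, zero node lines
  empty <- structure(list(
    nodes = data.frame(id = character(), kind = character(),
                       label = character(), stringsAsFactors = FALSE),
    edges = data.frame(from = character(), to = character(),
                       stringsAsFactors = FALSE)), class = "workflow_graph")
  lines <- strsplit(emit_diagram(empty, "dot"), "\n")[[1]]
  expect_false(any(grepl("label=", lines)))
})

test_that("parallel bindings collapse to one edge", {
  doc <- '
class: Workflow
cwlVersion: v1.2
inputs: {x: File}
steps:
  a: {run: t.cwl, in: {s: x}, out: [o1, o2]}
  b: {run: t.cwl, in: {p: a/o1, q: a/o2}, out: [o]}
outputs: []
'
  g <- build_graph(parse_cwl(doc, format = "yaml"))
  expect_identical(sum(g$edges$from == "step:a" & g$edges$to == "step:b"), 1L)
})
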