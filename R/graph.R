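#' Build the workflow wiring graph
#'
#' Translates a parsed CWL workflow into a directed acyclic graph with one
#' node per workflow input, per step, and per workflow output. Edges follow
#' the data flow: input to step for each step binding sourced from a workflow
#' input, step to step for bindings sourced from another step's output, and
#' step (or input) to output for each workflow output's source. Node ids are
#' namespaced (`input:`, `step:`, `output:`) so a step and a port may share a
#' raw name; labels keep the raw id. Parallel bindings between the same pair
#' collapse to a single edge.
#'
#' @param workflow a `cwl_workflow`.
#' @return A `workflow_graph`: `nodes` (data.frame id/kind/label) and `edges`
#'   (data.frame from/to).
#' @examples
#' wf <- parse_cwl(generate_cwl(generator_spec(n_steps = 2, seed = 1)))
#' g <- build_graph(wf)
#' nrow(g$nodes); nrow(g$edges)
#' @export
build_graph <- function(workflow) {
  stopifnot(inherits(workflow, "cwl_workflow"))
  input_ids  <- vapply(workflow$inputs,  `[[`, character(1), "id")
  output_ids <- vapply(workflow$outputs, `[[`, character(1), "id")
  step_ids   <- vapply(workflow$steps,   `[[`, character(1), "id")

  ns <- function(prefix, ids) {
    if (length(ids) == 0L) character() else paste0(prefix, ids)
  }
  nodes <- data.frame(
    id = c(ns("input:", input_ids),
           ns("step:", step_ids),
           ns("output:", output_ids)),
    kind = c(rep("input", length(input_ids)),
             rep("step", length(step_ids)),
             rep("output", length(output_ids))),
    label = c(input_ids, step_ids, output_ids),
    stringsAsFactors = FALSE
  )

  resolve_source <- function(src, where) {
    if (grepl("/", src, fixed = TRUE)) {
      s <- strsplit(src, "/", fixed = TRUE)[[1L]][1L]
      if (!s %in% step_ids) {
        stop("dangling source reference '", src, "' in ", where,
             ": no step '", s, "'", call. = FALSE)
      }
      paste0("step:", s)
    } else if (src %in% input_ids) {
      paste0("input:", src)
    } else {
      stop("dangling source reference '", src, "' in ", where, call. = FALSE)
    }
  }

  from <- character()
  to <- character()
  for (st in workflow$steps) {
    for (b in st$in_bindings) {
      from <- c(from, resolve_source(b$source, paste0("step '", st$id, "'")))
      to <- c(to, paste0("step:", st$id))
    }
  }
  for (o in workflow$outputs) {
    if (is.null(o$output_source)) next
    from <- c(from, resolve_source(o$output_source,
                                   paste0("output '", o$id, "'")))
    to <- c(to, paste0("output:", o$id))
  }
  edges <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  rownames(edges) <- NULL
  g <- structure(list(nodes = nodes, edges = edges), class = "workflow_graph")
  full_topological_order(g)  # errors on a cycle
  g
}

# Kahn's algorithm over all nodes; among ready nodes the lexicographically
# smallest id is taken, making the order unique.
full_topological_order <- function(graph) {
  ids <- graph$nodes$id
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (t in graph$edges$to) indeg[[t]] <- indeg[[t]] + 1L
  ready <- sort(ids[indeg == 0L], method = "radix")
  order <- character(0)
  indeg <- indeg
  while (length(ready) > 0L) {
    n <- ready[1L]
    ready <- ready[-1L]
    order <- c(order, n)
    outs <- graph$edges$to[graph$edges$from == n]
    for (m in outs) {
      indeg[[m]] <- indeg[[m]] - 1L
      if (indeg[[m]] == 0L) {
        ready <- sort(c(ready, m), method = "radix")
      }
    }
  }
  if (length(order) < length(ids)) {
    stop("workflow graph contains a cycle", call. = FALSE)
  }
  order
}

#' Topological order of workflow steps
#'
#' Unique topological order of the step nodes: every edge points forward and
#' ties are broken lexicographically by step id.
#'
#' @param graph a `workflow_graph`.
#' @return Character vector of step ids (raw, without the `step:` namespace).
#' @export
topological_order <- function(graph) {
  stopifnot(inherits(graph, "workflow_graph"))
  full <- full_topological_order(graph)
  sub("^step:", "", full[startsWith(full, "step:")])
}

diagram_node_order <- function(graph) {
  topo <- full_topological_order(graph)
  n <- graph$nodes
  c(sort(n$id[n$kind == "input"], method = "radix"),
    topo[startsWith(topo, "step:")],
    sort(n$id[n$kind == "output"], method = "radix"))
}

diagram_edge_order <- function(graph) {
  e <- graph$edges
  e[order(method = "radix", e$from, e$to), , drop = FALSE]
}

dot_quote <- function(x) paste0("\"", gsub("\"", "\\\"", x, fixed = TRUE), "\"")

# mermaid node ids must be bare words; map namespaced ids to safe tokens
mermaid_id <- function(id) gsub("[^A-Za-z0-9_]", "_", id)

#' Emit a wiring diagram as DOT or mermaid text
#'
#' Deterministic textual rendering of the wiring graph: nodes appear as
#' inputs (lexicographic), then steps in topological order, then outputs
#' (lexicographic); edges sorted by endpoints. Node kind is encoded by shape
#' (DOT: ellipse/box/note) or class (mermaid). Identical graphs yield
#' byte-identical text.
#'
#' @param graph a `workflow_graph`.
#' @param dialect `"dot"` or `"mermaid"`.
#' @return Diagram text (character scalar).
#' @export
emit_diagram <- function(graph, dialect = c("dot", "mermaid")) {
  stopifnot(inherits(graph, "workflow_graph"))
  dialect <- match.arg(dialect)
  ord <- diagram_node_order(graph)
  nodes <- graph$nodes[match(ord, graph$nodes$id), , drop = FALSE]
  edges <- diagram_edge_order(graph)
  if (dialect == "dot") {
    shape <- c(input = "ellipse", step = "box", output = "note")
    node_lines <- sprintf("  %s [label=%s, shape=%s];",
                          dot_quote(nodes$id), dot_quote(nodes$label),
                          shape[nodes$kind])
    edge_lines <- sprintf("  %s -> %s;",
                          dot_quote(edges$from), dot_quote(edges$to))
    paste(c("digraph workflow {", "  rankdir=LR;",
            node_lines, edge_lines, "}"), collapse = "\n")
  } else {
    bracket <- list(input = c("([", "])"), step = c("[", "]"),
                    output = c("[[", "]]"))
    node_lines <- vapply(seq_len(nrow(nodes)), function(i) {
      b <- bracket[[nodes$kind[i]]]
      sprintf("  %s%s\"%s\"%s:::%s", mermaid_id(nodes$id[i]), b[1],
              nodes$label[i], b[2], nodes$kind[i])
    }, character(1))
    edge_lines <- sprintf("  %s --> %s",
                          mermaid_id(edges$from), mermaid_id(edges$to))
    paste(c("flowchart TD", node_lines, edge_lines,
            "  classDef input fill:#e8f4e8",
            "  classDef step fill:#e8e8f4",
            "  classDef output fill:#f4e8e8"), collapse = "\n")
  }
}

#' @export
print.workflow_graph <- function(x, ...) {
  cat("<workflow_graph> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}
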