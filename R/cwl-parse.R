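#' Normalize a CWL identifier
#'
#' CWL identifiers may carry a file/URI prefix up to a `#` fragment and a
#' parent-process prefix (for example `#main/reads`). Normalization strips the
#' URI part, the leading `#`, and — when `parent_id` is given — the
#' `parent_id/` prefix. The operation is idempotent.
#'
#' @param raw_id identifier string, non-empty.
#' @param parent_id optional id of the enclosing process.
#' @return The normalized identifier.
#' @examples
#' normalize_id("#main/reads", "main")       # "reads"
#' normalize_id("file:///wf.cwl#step1/out")  # "step1/out"
#' @export
normalize_id <- function(raw_id, parent_id = NULL) {
  stopifnot(is.character(raw_id), length(raw_id) == 1L, nzchar(raw_id))
  id <- sub("^.*#", "", raw_id)
  if (!is.null(parent_id) && nzchar(parent_id)) {
    pre <- paste0(parent_id, "/")
    if (startsWith(id, pre)) id <- substring(id, nchar(pre) + 1L)
  }
  if (!nzchar(id)) {
    stop("identifier '", raw_id, "' is empty after normalization", call. = FALSE)
  }
  id
}

# CWL type descriptor -> compact string ("File", "File[]", "string?", ...)
cwl_type_name <- function(t) {
  if (is.null(t)) return("Any")
  if (is.character(t) && length(t) == 1L) return(t)
  if (is.list(t) && !is.null(names(t)) && identical(t[["type"]], "array")) {
    return(paste0(cwl_type_name(t[["items"]]), "[]"))
  }
  if (is.list(t) && is.null(names(t))) {  # union, usually ["null", X]
    parts <- vapply(t, cwl_type_name, character(1))
    non_null <- setdiff(parts, "null")
    if (length(non_null) == 1L && "null" %in% parts) {
      return(paste0(non_null, "?"))
    }
    return(paste(parts, collapse = "|"))
  }
  if (is.list(t) && !is.null(t[["type"]])) return(cwl_type_name(t[["type"]]))
  "Any"
}

cwl_type_is_file <- function(type_name) {
  grepl("^File(\\[\\])?\\??$", type_name)
}

# Accept both map-form (named list keyed by id) and list-form (unnamed list of
# records carrying `id`); return a list of records each with an `id` field.
as_record_list <- function(x, what) {
  if (is.null(x) || length(x) == 0L) return(list())
  if (!is.null(names(x)) && all(nzchar(names(x)))) {  # map form
    lapply(seq_along(x), function(i) {
      v <- x[[i]]
      rec <- if (is.list(v) && !is.null(names(v))) v else list(type = v)
      rec$id <- names(x)[i]
      rec
    })
  } else {
    lapply(x, function(rec) {
      if (!is.list(rec) || is.null(rec[["id"]])) {
        stop("list-form ", what, " entry lacks an 'id' field", call. = FALSE)
      }
      rec
    })
  }
}

parse_port <- function(rec, parent_id) {
  tn <- cwl_type_name(rec[["type"]])
  list(
    id = normalize_id(rec[["id"]], parent_id),
    type_name = tn,
    label = if (is.null(rec[["label"]])) "" else rec[["label"]],
    is_file = cwl_type_is_file(tn),
    output_source = if (is.null(rec[["outputSource"]])) NULL else
      normalize_id(first_scalar(rec[["outputSource"]]), parent_id),
    default = rec[["default"]]
  )
}

first_scalar <- function(x) if (is.list(x)) x[[1L]] else x

step_run_name <- function(run, parent_id) {
  if (is.null(run)) return("")
  if (is.character(run)) {
    # file path or fragment reference; keep the trailing name
    return(normalize_id(run))
  }
  if (is.list(run)) {
    if (!is.null(run[["id"]])) return(normalize_id(run[["id"]], parent_id))
    if (!is.null(run[["label"]])) return(run[["label"]])
  }
  ""
}

parse_step <- function(rec, parent_id) {
  sid <- normalize_id(rec[["id"]], parent_id)
  ins <- as_record_list(rec[["in"]], "step input")
  in_bindings <- list()
  defaults <- list()
  for (b in ins) {
    pid <- normalize_id(b[["id"]], paste0(parent_id, "/", sid))
    pid <- normalize_id(pid, sid)
    src <- b[["source"]]
    if (is.null(src) && is.character(b[["type"]])) {
      # map-form shorthand `port: source-string` arrives here as type = source
      src <- b[["type"]]
    }
    if (!is.null(b[["default"]])) defaults[[pid]] <- b[["default"]]
    if (!is.null(src)) {
      for (s in if (is.list(src)) src else list(src)) {
        in_bindings[[length(in_bindings) + 1L]] <- list(
          id = pid,
          source = normalize_id(s, parent_id)
        )
      }
    }
  }
  outs <- rec[["out"]]
  if (is.null(outs)) outs <- rec[["outputs"]]
  out_ports <- if (is.null(outs)) character() else unname(vapply(outs, function(o) {
    oid <- if (is.list(o)) o[["id"]] else o
    oid <- normalize_id(oid, paste0(parent_id, "/", sid))
    normalize_id(oid, sid)
  }, character(1)))
  list(
    id = sid,
    run_name = step_run_name(rec[["run"]], parent_id),
    doc = if (is.null(rec[["doc"]])) "" else rec[["doc"]],
    in_bindings = in_bindings,
    out_ports = out_ports,
    defaults = defaults
  )
}

#' Select a process from a packed `$graph` document
#'
#' Packed CWL documents hold several process objects under `$graph`. Returns
#' the entry whose id matches `entry_id`, or the unique `Workflow`-class entry
#' when `entry_id` is absent.
#'
#' @param tree parsed document containing `$graph`.
#' @param entry_id optional process id (with or without leading `#`).
#' @return The selected process subtree.
#' @export
select_from_graph <- function(tree, entry_id = NULL) {
  graph <- tree[["$graph"]]
  if (is.null(graph)) stop("document has no $graph member", call. = FALSE)
  if (!is.null(entry_id)) {
    want <- sub("^#", "", entry_id)
    for (p in graph) {
      if (!is.null(p[["id"]]) && sub("^#", "", p[["id"]]) == want) return(p)
    }
    stop("no $graph entry with id '", entry_id, "'", call. = FALSE)
  }
  wfs <- Filter(function(p) identical(p[["class"]], "Workflow"), graph)
  if (length(wfs) == 0L) {
    stop("packed document contains no Workflow entry", call. = FALSE)
  }
  if (length(wfs) > 1L) {
    ids <- vapply(wfs, function(p) p[["id"]] %||% "<unnamed>", character(1))
    stop("packed document contains multiple Workflows (",
         paste(ids, collapse = ", "), "); pass entry_id", call. = FALSE)
  }
  wfs[[1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

SUPPORTED_CWL_VERSIONS <- c("v1.0", "v1.1", "v1.2")

#' Parse a CWL workflow document
#'
#' Reads a CWL `Workflow` from JSON or YAML text (single-document or packed
#' `$graph`) and normalizes it to a uniform model: identifiers stripped of
#' fragment and parent prefixes, map-form `inputs`/`outputs`/`steps` converted
#' to list form, and string-typed port shorthands expanded. Subworkflows are
#' kept at depth one (an embedded `Workflow` run is a single step). Scatter,
#' `when`, and requirements are preserved in `$raw` but ignored by the model.
#'
#' @param text document text (character or raw bytes).
#' @param format one of `"auto"`, `"json"`, `"yaml"`.
#' @param entry_id packed-document process id to select, if any.
#' @return A `cwl_workflow` object: `id`, `label`, `doc`, `cwl_version`,
#'   `inputs` and `outputs` (lists of ports), `steps`, and `raw`.
#' @examples
#' wf <- parse_cwl(generate_cwl(generator_spec(n_steps = 2, seed = 1)))
#' length(wf$steps)
#' @export
parse_cwl <- function(text, format = c("auto", "json", "yaml"), entry_id = NULL) {
  format <- match.arg(format)
  if (is.raw(text)) text <- rawToChar(text)
  text <- paste(text, collapse = "\n")
  tree <- read_document_tree(text, format)
  if (!is.null(tree[["$graph"]])) tree <- select_from_graph(tree, entry_id)
  cls <- tree[["class"]]
  if (identical(cls, "CommandLineTool")) {
    stop_with_class("document is a CommandLineTool, not a Workflow",
                    "bcokit_not_workflow")
  }
  if (!identical(cls, "Workflow")) {
    stop_with_class(paste0("document class is '", cls %||% "<missing>",
                           "', expected 'Workflow'"), "bcokit_not_workflow")
  }
  ver <- tree[["cwlVersion"]]
  if (is.null(ver) || !ver %in% SUPPORTED_CWL_VERSIONS) {
    warning("cwlVersion '", ver %||% "<missing>",
            "' is not a supported v1.x version; parsing as v1.2", call. = FALSE)
    ver <- ver %||% "v1.2"
  }
  wf_id <- if (is.null(tree[["id"]])) "" else normalize_id(tree[["id"]])
  inputs  <- lapply(as_record_list(tree[["inputs"]], "input"),
                    parse_port, parent_id = wf_id)
  outputs <- lapply(as_record_list(tree[["outputs"]], "output"),
                    parse_port, parent_id = wf_id)
  steps   <- lapply(as_record_list(tree[["steps"]], "step"),
                    parse_step, parent_id = wf_id)
  step_ids <- vapply(steps, `[[`, character(1), "id")
  if (anyDuplicated(step_ids)) {
    stop("duplicate step ids after normalization: ",
         paste(unique(step_ids[duplicated(step_ids)]), collapse = ", "),
         call. = FALSE)
  }
  wf <- structure(list(
    id = wf_id,
    label = tree[["label"]] %||% "",
    doc = tree[["doc"]] %||% "",
    cwl_version = ver,
    inputs = inputs,
    outputs = outputs,
    steps = steps,
    raw = tree
  ), class = "cwl_workflow")
  check_output_sources(wf)
  wf
}

check_output_sources <- function(wf) {
  input_ids <- vapply(wf$inputs, `[[`, character(1), "id")
  step_ids  <- vapply(wf$steps, `[[`, character(1), "id")
  for (o in wf$outputs) {
    src <- o$output_source
    if (is.null(src)) next
    if (grepl("/", src, fixed = TRUE)) {
      s <- strsplit(src, "/", fixed = TRUE)[[1L]][1L]
      if (!s %in% step_ids) {
        stop("output '", o$id, "' references unknown step in source '",
             src, "'", call. = FALSE)
      }
    } else if (!src %in% input_ids) {
      stop("output '", o$id, "' references unknown source '", src, "'",
           call. = FALSE)
    }
  }
  invisible(wf)
}

read_document_tree <- function(text, format) {
  try_json <- function() {
    tryCatch(parse_json_text(text), error = function(e) {
      stop_with_class(paste0("JSON parse error: ", conditionMessage(e)),
                      "bcokit_parse_error")
    })
  }
  try_yaml <- function() {
    tryCatch(yaml::yaml.load(text), error = function(e) {
      stop_with_class(paste0("YAML parse error: ", conditionMessage(e)),
                      "bcokit_parse_error")
    })
  }
  if (format == "json") return(try_json())
  if (format == "yaml") return(try_yaml())
  # auto: JSON documents are a YAML subset, but jsonlite gives better
  # positions, so try JSON first when the text looks like JSON.
  if (grepl("^\\s*[{\\[]", text)) try_json() else try_yaml()
}

stop_with_class <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' @export
print.cwl_workflow <- function(x, ...) {
  cat("<cwl_workflow> ", if (nzchar(x$id)) x$id else "<unnamed>",
      " (", x$cwl_version, ")\n", sep = "")
  cat("  inputs:  ", length(x$inputs),
      "  outputs: ", length(x$outputs),
      "  steps: ", length(x$steps), "\n", sep = "")
  invisible(x)
}
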