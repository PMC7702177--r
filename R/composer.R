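#' Author-supplied metadata
#'
#' The config-file equivalent of the composer wizard forms: structured values
#' for the provenance, usability, error, and extension domains. Validated on
#' construction — provenance `name` must be non-empty.
#'
#' @param provenance named list; must carry `name`. May carry `version`,
#'   `license`, `contributors` (list of records with `name` and
#'   `contribution`), `review`, etc.
#' @param usability character vector of free-text statements.
#' @param extension list of extension records (each with `extension_schema`).
#' @param error list with `empirical_error` / `algorithmic_error` records.
#' @return An `author_metadata` object.
#' @export
author_metadata <- function(provenance, usability = character(),
                            extension = list(), error = NULL) {
  if (is.null(provenance[["name"]]) || !nzchar(provenance[["name"]])) {
    stop("author metadata must provide a provenance name", call. = FALSE)
  }
  structure(list(provenance = provenance,
                 usability = as.character(usability),
                 extension = extension,
                 error = error),
            class = "author_metadata")
}

#' Read author metadata from a YAML config file
#'
#' The file mirrors the wizard's domain-by-domain forms: top-level keys
#' `provenance` (mapping), `usability` (list of strings), `extension`
#' (list of mappings), `error` (mapping).
#'
#' @param path YAML file path.
#' @return An `author_metadata` object.
#' @export
read_author_metadata <- function(path) {
  cfg <- yaml::read_yaml(path)
  author_metadata(provenance = cfg$provenance %||% list(),
                  usability = unlist(cfg$usability) %||% character(),
                  extension = cfg$extension %||% list(),
                  error = cfg$error)
}

meta_domains <- function(meta) {
  usab <- if (length(meta$usability) == 0L) json_arr() else
    structure(as.list(meta$usability), class = "json_arr")
  ext <- if (length(meta$extension) == 0L) json_arr() else
    structure(meta$extension, class = "json_arr")
  d <- list(provenance_domain = meta$provenance,
            usability_domain = usab,
            extension_domain = ext)
  if (!is.null(meta$error)) {
    d$error_domain <- list(
      empirical_error = meta$error$empirical_error %||% json_obj(),
      algorithmic_error = meta$error$algorithmic_error %||% json_obj())
  }
  d
}

#' Compose a BCO from plaintext author metadata
#'
#' The Text-Composer path: author-supplied domains are carried over verbatim
#' and every machine-derivable domain is left empty but schema-valid.
#'
#' @param meta an [author_metadata()] object.
#' @param object_id,spec_version forwarded to [compose()].
#' @return A `bco`.
#' @export
compose_from_text <- function(meta, object_id = NULL,
                              spec_version = bco_spec_version()) {
  stopifnot(inherits(meta, "author_metadata"))
  compose(meta_domains(meta), object_id = object_id,
          spec_version = spec_version)
}

file_record <- function(uri, filename = NULL, access_time = NULL) {
  rec <- list(uri = uri)
  if (!is.null(filename)) rec$filename <- filename
  if (!is.null(access_time)) rec$access_time <- access_time
  list(uri = rec)
}

as_arr <- function(x) structure(x, class = "json_arr")

# revision suffix of a run name, e.g. "tools/star.cwl" -> "", "star/3" -> "3"
run_revision <- function(run_name) {
  m <- regmatches(run_name, regexec("/([0-9]+)$", run_name))[[1L]]
  if (length(m) == 2L) m[2L] else ""
}

cwl_description_domain <- function(workflow, platform = character()) {
  order <- topological_order(build_graph(workflow))
  steps <- workflow$steps[match(order, vapply(workflow$steps, `[[`,
                                              character(1), "id"))]
  pipeline_steps <- lapply(seq_along(steps), function(i) {
    st <- steps[[i]]
    list(step_number = i,
         name = st$id,
         description = st$doc,
         version = run_revision(st$run_name),
         input_list = as_arr(as.list(unique(c(
           vapply(st$in_bindings, `[[`, character(1), "id"),
           names(st$defaults))))),
         output_list = as_arr(as.list(st$out_ports)))
  })
  list(keywords = json_arr(),
       platform = if (length(platform)) as_arr(as.list(platform)) else json_arr(),
       pipeline_steps = as_arr(pipeline_steps))
}

cwl_parametric_domain <- function(workflow) {
  order <- topological_order(build_graph(workflow))
  out <- list()
  for (i in seq_along(order)) {
    st <- workflow$steps[[match(order[i], vapply(workflow$steps, `[[`,
                                                 character(1), "id"))]]
    for (p in names(st$defaults)) {
      v <- st$defaults[[p]]
      if (is.list(v)) next  # only scalar-representable defaults
      out[[length(out) + 1L]] <- list(step_number = i, param = p,
                                      value = as.character(v))
    }
  }
  as_arr(out)
}

cwl_io_domain <- function(workflow) {
  ins <- Filter(function(p) p$is_file, workflow$inputs)
  outs <- Filter(function(p) p$is_file, workflow$outputs)
  list(
    input_subdomain = as_arr(lapply(ins, function(p) {
      file_record(paste0("cwl://inputs/", p$id))
    })),
    output_subdomain = as_arr(lapply(outs, function(p) {
      file_record(paste0("cwl://outputs/", p$id))
    }))
  )
}

#' Compose a BCO from a parsed CWL workflow
#'
#' The CWL-Composer path: the description domain's pipeline steps are the
#' workflow's steps in topological order with their input/output port lists,
#' the parametric domain carries the steps' scalar default parameters keyed
#' to step numbers, the execution domain names the workflow document, and the
#' io domain lists File-typed workflow inputs/outputs as prospective entries.
#'
#' @param workflow a `cwl_workflow`.
#' @param meta an [author_metadata()] object.
#' @param workflow_path document name/path recorded in the execution domain.
#' @param object_id,spec_version forwarded to [compose()].
#' @return A `bco`.
#' @export
compose_from_cwl <- function(workflow, meta, workflow_path = NULL,
                             object_id = NULL,
                             spec_version = bco_spec_version()) {
  stopifnot(inherits(workflow, "cwl_workflow"),
            inherits(meta, "author_metadata"))
  script <- workflow_path %||%
    (if (nzchar(workflow$id)) workflow$id else "workflow.cwl")
  domains <- meta_domains(meta)
  domains$description_domain <- cwl_description_domain(workflow)
  domains$parametric_domain <- cwl_parametric_domain(workflow)
  domains$execution_domain <- list(
    script = as_arr(list(script)),
    script_driver = "cwl-runner",
    software_prerequisites = json_arr(),
    external_data_endpoints = json_arr(),
    environment_variables = json_obj())
  domains$io_domain <- cwl_io_domain(workflow)
  compose(domains, object_id = object_id, spec_version = spec_version)
}

# one io-domain entry per file; array-valued file params expand
expand_files <- function(value) {
  if (is.list(value) && is.null(value[["path"]]) && is.null(value[["uri"]])) {
    return(do.call(c, lapply(value, expand_files)))
  }
  list(value)
}

is_file_value <- function(v) {
  is.list(v) && (identical(v[["class"]], "File") ||
                 !is.null(v[["path"]]) || !is.null(v[["uri"]]))
}

task_file_entry <- function(f) {
  file_record(uri = f[["uri"]] %||% f[["path"]] %||% "",
              filename = f[["name"]] %||% f[["basename"]],
              access_time = f[["access_time"]])
}

#' Compose a BCO from a platform task-execution record
#'
#' The Platform-Composer path: everything [compose_from_cwl()] derives, plus
#' execution evidence from the task — input/output files expanded one
#' io-domain entry per file (array params expand; duplicate URIs are kept),
#' actual parameter settings in the parametric domain, the platform name in
#' the description domain, and the executed app's name/revision recorded as a
#' software prerequisite.
#'
#' Task parameter names of the form `step/param` are keyed to the matching
#' pipeline step; a name whose step is not in the workflow produces a warning
#' and is skipped (composition proceeds).
#'
#' @param task a `task_record` with status `completed`.
#' @param workflow a `cwl_workflow`.
#' @param meta an [author_metadata()] object.
#' @param workflow_path,object_id,spec_version as in [compose_from_cwl()].
#' @return A `bco`.
#' @export
compose_from_task <- function(task, workflow, meta, workflow_path = NULL,
                              object_id = NULL,
                              spec_version = bco_spec_version()) {
  stopifnot(inherits(task, "task_record"))
  if (!identical(task$status, "completed")) {
    stop("task '", task$task_id, "' has status '", task$status,
         "'; only completed tasks can be composed", call. = FALSE)
  }
  bco <- compose_from_cwl(workflow, meta, workflow_path = workflow_path,
                          object_id = object_id, spec_version = spec_version)
  order <- vapply(bco$description_domain$pipeline_steps, `[[`, integer(1),
                  "step_number")
  step_names <- vapply(bco$description_domain$pipeline_steps, `[[`,
                       character(1), "name")

  inputs <- list(); params <- list()
  for (inp in task$inputs) {
    v <- inp$value
    if (is_file_value(v) || (is.list(v) && length(v) > 0L &&
                             all(vapply(v, is_file_value, logical(1))))) {
      for (f in expand_files(v)) {
        inputs[[length(inputs) + 1L]] <- task_file_entry(f)
      }
    } else if (!is.list(v)) {
      parts <- strsplit(inp$name, "/", fixed = TRUE)[[1L]]
      if (length(parts) == 2L && parts[1L] %in% step_names) {
        params[[length(params) + 1L]] <- list(
          step_number = order[match(parts[1L], step_names)],
          param = parts[2L], value = as.character(v))
      } else {
        warning("task parameter '", inp$name,
                "' does not match a workflow step; skipped", call. = FALSE)
      }
    }
  }
  outputs <- lapply(task$outputs, task_file_entry)

  bco$io_domain <- list(input_subdomain = as_arr(inputs),
                        output_subdomain = as_arr(outputs))
  bco$parametric_domain <- as_arr(params)
  bco$description_domain$platform <- as_arr(as.list(
    unique(c(unlist(bco$description_domain$platform), task$platform_name))))
  bco$execution_domain$software_prerequisites <- as_arr(list(list(
    name = task$app_name, version = task$app_revision)))
  bco$execution_domain$external_data_endpoints <- as_arr(list(list(
    name = task$platform_name,
    url = paste0("platform://", task$platform_name, "/", task$project))))
  bco$etag <- compute_digest(bco)
  bco
}

#' Platform task records
#'
#' `as_task_record` normalizes a parsed platform task-export tree into a
#' `task_record`; `fetch_task` retrieves one through a platform adapter. The
#' bundled mock adapter ([mock_adapter()]) serves records from local JSON
#' fixture files named `<task_id>.json`, emulating the task shape of
#' cloud genomics platforms; live platform clients plug in behind the same
#' `fetch_task` generic.
#'
#' @param tree named list parsed from a task JSON export.
#' @return A `task_record`.
#' @export
as_task_record <- function(tree) {
  structure(list(
    task_id = tree$task_id %||% tree$id %||% "",
    task_name = tree$task_name %||% tree$name %||% "",
    app_name = tree$app_name %||% tree$app %||% "",
    app_revision = as.character(tree$app_revision %||% ""),
    platform_name = tree$platform_name %||% "unknown-platform",
    project = tree$project %||% "",
    inputs = lapply(seq_along(tree$inputs %||% list()), function(i) {
      x <- tree$inputs[[i]]
      if (!is.null(names(tree$inputs)) && nzchar(names(tree$inputs)[i])) {
        list(name = names(tree$inputs)[i], value = x)
      } else {
        list(name = x$name, value = x$value)
      }
    }),
    outputs = tree$outputs %||% list(),
    start = tree$start %||% tree$start_time %||% "",
    end = tree$end %||% tree$end_time %||% "",
    status = tree$status %||% "unknown"
  ), class = "task_record")
}

#' @rdname as_task_record
#' @param dir directory of JSON task fixtures.
#' @export
mock_adapter <- function(dir = system.file("extdata", "tasks",
                                           package = "bcokit")) {
  structure(list(kind = "mock", dir = dir), class = "platform_adapter")
}

#' @rdname as_task_record
#' @param adapter a `platform_adapter`.
#' @param task_id task identifier.
#' @export
fetch_task <- function(adapter, task_id) {
  stopifnot(inherits(adapter, "platform_adapter"))
  if (!identical(adapter$kind, "mock")) {
    stop_with_class(paste0("no client for adapter kind '", adapter$kind, "'"),
                    "bcokit_transport_error")
  }
  if (!dir.exists(adapter$dir)) {
    stop_with_class(paste0("adapter fixture directory unreachable: '",
                           adapter$dir, "'"), "bcokit_transport_error")
  }
  f <- file.path(adapter$dir, paste0(task_id, ".json"))
  if (!file.exists(f)) {
    stop_with_class(paste0("task '", task_id, "' not found"),
                    "bcokit_not_found_error")
  }
  as_task_record(parse_json_text(paste(readLines(f, warn = FALSE),
                                       collapse = "\n")))
}

#' @export
print.task_record <- function(x, ...) {
  cat("<task_record> ", x$task_id, " (", x$status, ") on ",
      x$platform_name, "\n", sep = "")
  invisible(x)
}
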