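# Deterministic generators: all randomness flows from spec$seed through a
# locally scoped RNG so generation never disturbs the session RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Synthetic CWL workflow generator spec
#'
#' Parameters of the deterministic workflow generator. `chain` wiring makes a
#' linear pipeline (step i consumes step i-1's output); `random_dag` wires
#' each step to a seed-chosen earlier step or workflow input, which is
#' acyclic by construction. `file_fraction` controls how many ports are
#' File-typed; `array_sizes` marks chosen input ports as File arrays.
#'
#' @param n_inputs,n_outputs,n_steps non-negative counts.
#' @param wiring `"chain"` or `"random_dag"`.
#' @param file_fraction proportion of workflow input ports typed `File`.
#' @param array_sizes optional named integer vector: input port -> array length.
#' @param seed integer seed; identical specs give identical bytes.
#' @return A `generator_spec`.
#' @export
generator_spec <- function(n_inputs = 1L, n_outputs = 1L, n_steps = 3L,
                           wiring = c("chain", "random_dag"),
                           file_fraction = 0.5, array_sizes = NULL,
                           seed = 1L) {
  wiring <- match.arg(wiring)
  stopifnot(n_inputs >= 0, n_outputs >= 0, n_steps >= 0,
            file_fraction >= 0, file_fraction <= 1)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_outputs = as.integer(n_outputs),
                 n_steps = as.integer(n_steps),
                 wiring = wiring, file_fraction = file_fraction,
                 array_sizes = array_sizes, seed = as.integer(seed)),
            class = "generator_spec")
}

gen_step_id <- function(i) sprintf("step_%02d", i)

#' Generate a synthetic CWL workflow document
#'
#' Emits a parseable CWL v1.2 `Workflow` with exactly the requested numbers
#' of inputs, outputs, and steps, wired per the spec. Every step has one
#' output port `out` and a scalar `threads` default (so the parametric
#' domain has material). Outputs are sourced from the last steps (or from
#' inputs when there are no steps). Identical specs yield identical bytes.
#'
#' @param spec a [generator_spec()].
#' @param format `"json"` or `"yaml"`.
#' @return Document text.
#' @examples
#' cat(substr(generate_cwl(generator_spec(n_steps = 1, seed = 1)), 1, 60))
#' @export
generate_cwl <- function(spec, format = c("json", "yaml")) {
  format <- match.arg(format)
  stopifnot(inherits(spec, "generator_spec"))
  n_avail <- if (spec$n_steps > 0L) spec$n_steps else spec$n_inputs
  if (spec$n_outputs > n_avail) {
    stop("n_outputs (", spec$n_outputs, ") exceeds reachable step outputs (",
         n_avail, ")", call. = FALSE)
  }
  with_local_seed(spec$seed, {
    input_ids <- if (spec$n_inputs > 0L) sprintf("in_%02d", seq_len(spec$n_inputs)) else character()
    n_file <- round(spec$file_fraction * spec$n_inputs)
    is_file_in <- seq_len(spec$n_inputs) <= n_file
    inputs <- lapply(seq_along(input_ids), function(i) {
      tp <- if (is_file_in[i]) "File" else "string"
      sz <- spec$array_sizes[[input_ids[i]]]
      if (!is.null(sz)) tp <- list(type = "array", items = tp)
      list(id = input_ids[i], type = tp,
           label = paste("workflow input", i))
    })
    steps <- lapply(seq_len(spec$n_steps), function(i) {
      sid <- gen_step_id(i)
      src <- if (spec$wiring == "chain") {
        if (i == 1L) {
          if (spec$n_inputs > 0L) input_ids[1L] else NULL
        } else {
          paste0(gen_step_id(i - 1L), "/out")
        }
      } else {  # random_dag: earlier step or a workflow input
        pool <- c(input_ids,
                  if (i > 1L) paste0(vapply(seq_len(i - 1L), gen_step_id,
                                            character(1)), "/out"))
        if (length(pool) > 0L) pool[sample.int(length(pool), 1L)] else NULL
      }
      ins <- list(list(id = "threads", default = sample.int(16L, 1L)))
      if (!is.null(src)) {
        ins <- c(list(list(id = "src", source = src)), ins)
      }
      list(id = sid,
           run = paste0("tools/", sid, ".cwl"),
           doc = paste("synthetic step", i),
           `in` = ins,
           out = list("out"))
    })
    # chain mode: spread surplus inputs over steps so they are consumed
    if (spec$wiring == "chain" && spec$n_inputs > 1L && spec$n_steps > 0L) {
      for (k in 2L:spec$n_inputs) {
        tgt <- ((k - 2L) %% spec$n_steps) + 1L
        steps[[tgt]]$`in` <- c(steps[[tgt]]$`in`,
                               list(list(id = paste0("aux_", input_ids[k]),
                                         source = input_ids[k])))
      }
    }
    outputs <- lapply(seq_len(spec$n_outputs), function(j) {
      src <- if (spec$n_steps > 0L) {
        paste0(gen_step_id(spec$n_steps - j + 1L), "/out")
      } else {
        input_ids[j]
      }
      list(id = sprintf("out_%02d", j), type = "File", outputSource = src)
    })
    tree <- list(
      class = "Workflow",
      cwlVersion = "v1.2",
      id = "synthetic_workflow",
      label = sprintf("synthetic %s workflow (%d steps)", spec$wiring,
                      spec$n_steps),
      inputs = inputs,
      outputs = outputs,
      steps = steps
    )
    if (format == "json") pretty_json(tree) else yaml::as.yaml(tree)
  })
}

#' Generate a synthetic platform task record
#'
#' Builds a completed-status `task_record` for a workflow whose expanded
#' input/output file counts equal the arguments exactly: input files are
#' distributed over the workflow's File-typed input ports as file arrays
#' (any surplus goes to a catch-all port), and per-step scalar parameters
#' are sampled deterministically from `seed`. Use [write_task_json()] for
#' the JSON fixture form served by the mock adapter.
#'
#' @param workflow a `cwl_workflow`.
#' @param n_input_files,n_output_files non-negative file counts.
#' @param seed integer seed.
#' @return A `task_record`.
#' @export
generate_task <- function(workflow, n_input_files, n_output_files, seed = 1L) {
  stopifnot(inherits(workflow, "cwl_workflow"),
            n_input_files >= 0, n_output_files >= 0)
  with_local_seed(seed, {
    file_ports <- vapply(Filter(function(p) p$is_file, workflow$inputs),
                         `[[`, character(1), "id")
    if (length(file_ports) == 0L) file_ports <- "input_files"
    # split n_input_files across ports; every port gets an array
    counts <- rep(n_input_files %/% length(file_ports), length(file_ports))
    if (length(counts) > 0L && n_input_files %% length(file_ports) > 0L) {
      counts[1L] <- counts[1L] + n_input_files %% length(file_ports)
    }
    mk_file <- function(prefix, k) {
      list(class = "File",
           path = sprintf("platform://files/%s_%03d.dat", prefix, k),
           name = sprintf("%s_%03d.dat", prefix, k))
    }
    inputs <- list()
    fi <- 0L
    for (i in seq_along(file_ports)) {
      if (counts[i] == 0L) next
      files <- lapply(seq_len(counts[i]), function(k) mk_file(file_ports[i],
                                                              fi + k))
      fi <- fi + counts[i]
      inputs[[length(inputs) + 1L]] <- list(name = file_ports[i],
                                            value = files)
    }
    for (st in workflow$steps) {
      inputs[[length(inputs) + 1L]] <- list(
        name = paste0(st$id, "/threads"),
        value = sample.int(16L, 1L))
    }
    outputs <- lapply(seq_len(n_output_files), function(k) mk_file("out", k))
    structure(list(
      task_id = sprintf("task-%d", seed),
      task_name = sprintf("synthetic run of %s", workflow$id),
      app_name = if (nzchar(workflow$id)) workflow$id else "synthetic-app",
      app_revision = as.character(sample.int(9L, 1L)),
      platform_name = "mock-platform",
      project = "demo/project",
      inputs = inputs,
      outputs = outputs,
      start = "2020-01-01T00:00:00Z",
      end = "2020-01-01T01:00:00Z",
      status = "completed"
    ), class = "task_record")
  })
}

#' @rdname generate_task
#' @param task a `task_record`.
#' @param path output JSON path; when `NULL` the text is returned.
#' @export
write_task_json <- function(task, path = NULL) {
  tree <- unclass(task)
  tree$inputs <- as_arr(tree$inputs)
  tree$outputs <- as_arr(tree$outputs)
  txt <- pretty_json(tree)
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path, useBytes = TRUE)
  invisible(txt)
}

CORRUPTION_MODES <- c("type_mismatch", "missing_required", "etag_tamper",
                      "domain_drop")

#' Inject a single defect into a valid BCO
#'
#' Produces a corrupted copy plus a descriptor of the injected defect
#' (`mode`, `path`, `description`) for assertion in tests. Schema-level modes
#' (`type_mismatch`, `missing_required`, `domain_drop`) recompute the etag
#' after mutation so only the schema check fails; `etag_tamper` leaves the
#' content intact so only the integrity check fails. The defect location is
#' chosen deterministically from `seed`.
#'
#' @param bco a valid `bco`.
#' @param mode one of `type_mismatch`, `missing_required`, `etag_tamper`,
#'   `domain_drop`.
#' @param seed integer seed.
#' @return List with `bco`, `mode`, `path`, `description`.
#' @export
corrupt_bco <- function(bco, mode = CORRUPTION_MODES, seed = 1L) {
  mode <- match.arg(mode)
  with_local_seed(seed, {
    out <- switch(mode,
      type_mismatch = {
        sites <- list(
          list(path = c("provenance_domain", "version"), value = 1.5),
          list(path = c("provenance_domain", "name"), value = 42),
          list(path = c("execution_domain", "script_driver"), value = TRUE))
        s <- sites[[sample.int(length(sites), 1L)]]
        bco[[s$path]] <- s$value
        list(bco = bco, path = paste(s$path, collapse = "/"),
             description = "field value replaced with a wrong-typed value")
      },
      missing_required = {
        sites <- list(c("provenance_domain", "name"),
                      c("provenance_domain", "created"),
                      c("execution_domain", "script_driver"))
        p <- sites[[sample.int(length(sites), 1L)]]
        bco[[p[1L]]][[p[2L]]] <- NULL
        list(bco = bco, path = paste(p, collapse = "/"),
             description = "required field removed")
      },
      etag_tamper = {
        if (is.null(bco$etag)) stop("no etag to tamper with", call. = FALSE)
        bco$etag <- sha256_hex(charToRaw(paste0("tampered-", seed)))
        list(bco = bco, path = "etag",
             description = "etag replaced, content untouched")
      },
      domain_drop = {
        present <- intersect(BCO_DOMAINS, names(bco))
        if (length(present) == 0L) stop("nothing to drop", call. = FALSE)
        d <- present[sample.int(length(present), 1L)]
        bco[[d]] <- NULL
        list(bco = bco, path = d, description = "entire domain removed")
      })
    if (mode != "etag_tamper") {
      out$bco$etag <- compute_digest(out$bco)
    }
    out$mode <- mode
    out$bco <- structure(out$bco, class = "bco")
    out
  })
}

#' Regenerate the synthetic fixture corpus on disk
#'
#' Writes a documented directory layout: `cwl/` (workflow documents over a
#' small parameter grid, JSON and YAML), `tasks/` (mock-adapter task
#' fixtures), and `bco/` (composed valid BCOs). Backs the `fixtures generate`
#' CLI subcommand.
#'
#' @param out_dir output directory (created if needed).
#' @param seed base seed.
#' @return Invisibly, the paths written.
#' @export
generate_fixture_corpus <- function(out_dir, seed = 1L) {
  for (d in c("cwl", "tasks", "bco")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  meta <- author_metadata(provenance = list(name = "synthetic fixture"))
  written <- character()
  grid <- expand.grid(n_steps = c(0L, 1L, 4L), wiring = c("chain", "random_dag"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    sp <- generator_spec(n_inputs = 2L, n_outputs = 1L,
                         n_steps = grid$n_steps[i], wiring = grid$wiring[i],
                         seed = seed + i)
    base <- sprintf("wf_%s_%d", grid$wiring[i], grid$n_steps[i])
    for (fmt in c("json", "yaml")) {
      f <- file.path(out_dir, "cwl", paste0(base, ".cwl.", fmt))
      writeLines(sub("\n$", "", generate_cwl(sp, fmt)), f, useBytes = TRUE)
      written <- c(written, f)
    }
    wf <- parse_cwl(generate_cwl(sp))
    task <- generate_task(wf, 3L, 2L, seed = seed + i)
    tf <- file.path(out_dir, "tasks", paste0("task-", seed + i, ".json"))
    write_task_json(task, tf)
    bf <- file.path(out_dir, "bco", paste0(base, ".bco.json"))
    write_bco(compose_from_task(task, wf, meta), bf)
    written <- c(written, tf, bf)
  }
  invisible(written)
}
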