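new_report <- function(issues = NULL) {
  if (is.null(issues) || nrow(issues) == 0L) {
    issues <- data.frame(severity = character(), category = character(),
                         path = character(), message = character(),
                         stringsAsFactors = FALSE)
  }
  structure(list(issues = issues,
                 passed = !any(issues$severity == "error")),
            class = "bco_validation_report")
}

issue_row <- function(severity, category, path, message) {
  data.frame(severity = severity, category = category, path = path,
             message = message, stringsAsFactors = FALSE)
}

merge_reports <- function(...) {
  new_report(do.call(rbind, lapply(list(...), function(r) r$issues)))
}

#' Load the vendored BCO schema bundle
#'
#' Reads the per-domain schema files shipped under `inst/schemas/`. The
#' bundle is local-only: no network `$ref` resolution ever happens.
#'
#' @param dir schema directory; defaults to the installed bundle.
#' @return Named list of parsed schemas (eight domains plus `top_level`).
#' @export
load_schema_bundle <- function(dir = system.file("schemas", package = "bcokit")) {
  if (!nzchar(dir) || !dir.exists(dir)) {
    stop("schema bundle directory not found: '", dir, "'", call. = FALSE)
  }
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  names(files) <- sub("\\.json$", "", basename(files))
  needed <- c(BCO_DOMAINS, "top_level")
  if (!all(needed %in% names(files))) {
    stop("schema bundle incomplete; missing: ",
         paste(setdiff(needed, names(files)), collapse = ", "), call. = FALSE)
  }
  lapply(files, function(f) parse_json_text(paste(readLines(f, warn = FALSE),
                                                  collapse = "\n")))
}

# JSON type of an R value under the package's tree conventions.
json_type_of <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) return(if (is_json_object(x)) "object" else "array")
  if (is.character(x)) return("string")
  if (is.logical(x)) return("boolean")
  if (is.numeric(x)) {
    return(if (x == trunc(x)) "integer" else "number")
  }
  "unknown"
}

type_matches <- function(actual, allowed) {
  allowed <- unlist(allowed)
  actual %in% allowed || (actual == "integer" && "number" %in% allowed)
}

# Minimal JSON-Schema checker: type, required, properties, items, enum,
# pattern, minItems. Returns an issues data.frame.
check_schema <- function(value, schema, path, category = "schema") {
  issues <- issue_row(character(), character(), character(), character())
  tn <- schema[["type"]]
  actual <- json_type_of(value)
  if (!is.null(tn) && !type_matches(actual, tn)) {
    return(issue_row("error", category, path,
                     sprintf("type mismatch: expected %s, found %s",
                             paste(unlist(tn), collapse = "|"), actual)))
  }
  if (actual == "object") {
    for (req in unlist(schema[["required"]])) {
      if (is.null(value[[req]])) {
        issues <- rbind(issues, issue_row(
          "error", category, paste0(path, "/", req),
          sprintf("required field '%s' is missing", req)))
      }
    }
    props <- schema[["properties"]]
    if (!is.null(props)) {
      for (key in names(value)) {
        if (!is.null(props[[key]]) && !is.null(value[[key]])) {
          issues <- rbind(issues, check_schema(
            value[[key]], props[[key]], paste0(path, "/", key), category))
        }
      }
    }
  }
  if (actual == "array") {
    mi <- schema[["minItems"]]
    if (!is.null(mi) && length(value) < mi) {
      issues <- rbind(issues, issue_row(
        "error", category, path,
        sprintf("array has %d items, minimum is %d", length(value), mi)))
    }
    it <- schema[["items"]]
    if (!is.null(it)) {
      for (i in seq_along(value)) {
        issues <- rbind(issues, check_schema(
          value[[i]], it, paste0(path, "/", i - 1L), category))
      }
    }
  }
  if (actual == "string") {
    en <- schema[["enum"]]
    if (!is.null(en) && !value %in% unlist(en)) {
      issues <- rbind(issues, issue_row(
        "error", category, path,
        sprintf("value '%s' is not one of the allowed values", value)))
    }
    pat <- schema[["pattern"]]
    if (!is.null(pat) && !grepl(pat, value)) {
      issues <- rbind(issues, issue_row(
        "error", category, path,
        sprintf("value does not match pattern '%s'", pat)))
    }
  }
  issues
}

#' Validate BCO content integrity
#'
#' Recomputes the SHA-256 digest of the non-top-level domains (see
#' [compute_digest()]) and compares it to the stored `etag`. A mismatch is
#' an error carrying both digests; a missing etag is a structure warning.
#' Findings go into the report; this never raises on bad content.
#'
#' @param bco a `bco` object.
#' @return A `bco_validation_report`.
#' @export
validate_integrity <- function(bco) {
  etag <- bco[["etag"]]
  if (is.null(etag) || !nzchar(etag)) {
    return(new_report(issue_row(
      "warning", "structure", "etag",
      "etag is absent; content integrity cannot be checked")))
  }
  recomputed <- compute_digest(bco)
  if (!identical(tolower(etag), recomputed)) {
    return(new_report(issue_row(
      "error", "integrity", "etag",
      sprintf("etag mismatch: stored %s, recomputed %s", etag, recomputed))))
  }
  new_report()
}

#' Validate a BCO against the domain schemas
#'
#' Checks each of the eight content domains against its vendored schema and
#' the top-level fields against the structural schema. A missing domain is a
#' schema error at the domain's path; unknown extra top-level keys are
#' structure warnings. An extension record that declares a schema this
#' package does not hold yields a warning, not an error.
#'
#' @param bco a `bco` object.
#' @param schemas schema bundle from [load_schema_bundle()].
#' @return A `bco_validation_report`.
#' @export
validate_schema <- function(bco, schemas = load_schema_bundle()) {
  issues <- issue_row(character(), character(), character(), character())
  for (d in BCO_DOMAINS) {
    if (is.null(bco[[d]])) {
      issues <- rbind(issues, issue_row(
        "error", "schema", d,
        sprintf("required domain '%s' is missing", d)))
    } else {
      issues <- rbind(issues, check_schema(bco[[d]], schemas[[d]], d))
    }
  }
  issues <- rbind(issues, check_schema(
    structure(bco[names(bco) %in% BCO_TOP_LEVEL], class = "json_obj"),
    schemas[["top_level"]], "", category = "structure"))
  extra <- setdiff(names(bco), c(BCO_TOP_LEVEL, BCO_DOMAINS))
  for (key in extra) {
    issues <- rbind(issues, issue_row(
      "warning", "structure", key,
      sprintf("unknown top-level field '%s'", key)))
  }
  ext <- bco[["extension_domain"]]
  if (is.list(ext)) {
    for (i in seq_along(ext)) {
      sch <- ext[[i]][["extension_schema"]]
      if (!is.null(sch)) {
        issues <- rbind(issues, issue_row(
          "warning", "schema", paste0("extension_domain/", i - 1L),
          sprintf("extension payload not validated (external schema '%s' not held)", sch)))
      }
    }
  }
  issues$path <- sub("^/", "", issues$path)
  new_report(issues)
}

#' Full BCO validation
#'
#' The two validation types the standard recommends: content-integrity
#' digest first, then per-domain schema conformance. The report concatenates
#' both; `passed` is true iff no error-severity issue was found.
#'
#' @inheritParams validate_schema
#' @return A `bco_validation_report`.
#' @examples
#' validate(compose(list(provenance_domain = list(name = "demo"))))$passed
#' @export
validate <- function(bco, schemas = load_schema_bundle()) {
  merge_reports(validate_integrity(bco), validate_schema(bco, schemas))
}

#' @export
print.bco_validation_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

format_report <- function(report) {
  if (nrow(report$issues) == 0L) return("validation passed: no issues")
  c(sprintf("validation %s: %d issue(s)",
            if (report$passed) "passed" else "FAILED",
            nrow(report$issues)),
    sprintf("  [%s/%s] %s: %s",
            report$issues$severity, report$issues$category,
            ifelse(nzchar(report$issues$path), report$issues$path, "<top>"),
            report$issues$message))
}

report_to_json <- function(report) {
  issues <- lapply(seq_len(nrow(report$issues)), function(i) {
    as.list(report$issues[i, , drop = FALSE])
  })
  pretty_json(list(passed = report$passed,
                   n_issues = nrow(report$issues),
                   issues = structure(issues, class = "json_arr")))
}
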