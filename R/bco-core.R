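BCO_DOMAINS <- c("provenance_domain", "usability_domain", "extension_domain",
                 "description_domain", "execution_domain", "parametric_domain",
                 "io_domain", "error_domain")
BCO_TOP_LEVEL <- c("object_id", "spec_version", "etag")

#' Default IEEE 2791-2020 schema URI used for `spec_version`
#' @export
bco_spec_version <- function() {
  "https://w3id.org/ieee/ieee-2791-schema/2791object.json"
}

# Clock injection point: tests freeze time with options(bcokit.now = ...).
bco_now <- function() {
  now <- getOption("bcokit.now", NULL)
  if (is.null(now)) now <- Sys.time()
  if (inherits(now, "POSIXt")) {
    now <- format(now, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  now
}

empty_domain <- function(domain) {
  switch(domain,
    provenance_domain = json_obj(),
    usability_domain = json_arr(),
    extension_domain = json_arr(),
    description_domain = list(
      keywords = json_arr(), platform = json_arr(),
      pipeline_steps = json_arr()),
    execution_domain = list(
      script = json_arr(), script_driver = "",
      software_prerequisites = json_arr(),
      external_data_endpoints = json_arr(),
      environment_variables = json_obj()),
    parametric_domain = json_arr(),
    io_domain = list(input_subdomain = json_arr(),
                     output_subdomain = json_arr()),
    error_domain = list(empirical_error = json_obj(),
                        algorithmic_error = json_obj())
  )
}

# Deterministic under a frozen clock: name-based UUID from provenance
# name + created stamp, with the standard's "/version" suffix.
default_object_id <- function(name, created, version) {
  ns <- "6ba7b811-9dad-11d1-80b4-00c04fd430c8"  # RFC 4122 URL namespace
  u <- uuid::UUIDfromName(ns, paste0(name, "|", created))
  paste0("urn:uuid:", u, "/", version)
}

#' Compose a BioCompute Object
#'
#' Assembles a complete nine-category BCO (eight content domains plus the
#' top-level fields) from a partial set of domain values. Missing domains are
#' filled with empty-but-schema-valid values, the provenance domain gets
#' `version`, `license`, `created`, and `modified` defaults, and the `etag`
#' content-integrity digest is computed over the finished domains. With a
#' frozen clock (`options(bcokit.now = ...)`) composition is deterministic.
#'
#' @param domains named list holding any of the eight content domains; the
#'   provenance domain must at least carry `name`.
#' @param object_id top-level object URI; a URN derived from the provenance
#'   name and creation time when absent.
#' @param spec_version schema URI; defaults to [bco_spec_version()].
#' @return A `bco` object (named list of top-level fields and domains).
#' @examples
#' bco <- compose(list(provenance_domain = list(name = "demo")))
#' names(bco)
#' @export
compose <- function(domains = list(), object_id = NULL,
                    spec_version = bco_spec_version()) {
  prov <- domains[["provenance_domain"]]
  if (is.null(prov[["name"]]) || !nzchar(prov[["name"]])) {
    stop("provenance name is required to compose a BCO", call. = FALSE)
  }
  now <- bco_now()
  prov$version  <- prov$version %||% "1.0"
  prov$license  <- prov$license %||%
    "https://spdx.org/licenses/CC-BY-4.0.html"
  prov$created  <- prov$created %||% now
  prov$modified <- prov$modified %||% now
  if (is.null(prov$contributors)) prov$contributors <- json_arr()
  body <- list()
  for (d in BCO_DOMAINS) {
    body[[d]] <- if (d == "provenance_domain") prov else
      domains[[d]] %||% empty_domain(d)
  }
  if (is.null(object_id)) {
    object_id <- default_object_id(prov$name, prov$created, prov$version)
  }
  bco <- c(list(object_id = object_id, spec_version = spec_version,
                etag = ""), body)
  bco$etag <- compute_digest(bco)
  structure(bco, class = "bco")
}

#' Content-integrity digest of a BCO
#'
#' SHA-256 hex digest of the canonical JSON bytes of an object holding
#' exactly the eight non-top-level domains (top-level `object_id`,
#' `spec_version`, and `etag` excluded), keys sorted at every depth. This is
#' the value stored in `etag` and recomputed by [validate_integrity()].
#'
#' @param bco a `bco` object or equivalent named list.
#' @return 64-character lowercase hex string.
#' @export
compute_digest <- function(bco) {
  body <- structure(lapply(BCO_DOMAINS, function(d) bco[[d]]),
                    names = BCO_DOMAINS)
  present <- !vapply(body, is.null, logical(1))
  sha256_hex(canonical_bytes(structure(body[present], class = "json_obj")))
}

# Paths that must deserialize as JSON objects even when empty; parse_json
# cannot tell {} from [] so they are repaired after reading.
OBJECT_VALUED_PATHS <- list(
  c("error_domain", "empirical_error"),
  c("error_domain", "algorithmic_error"),
  c("execution_domain", "environment_variables"),
  c("provenance_domain")
)

repair_bco_tree <- function(tree) {
  for (p in OBJECT_VALUED_PATHS) {
    if (length(p) > 1L && is.null(tree[[p[1L]]])) next
    v <- tryCatch(tree[[p]], error = function(e) NULL)
    if (!is.null(v) && is.list(v) && length(v) == 0L) {
      tree[[p]] <- json_obj()
    }
  }
  tree
}

#' Read / write BCO JSON
#'
#' `read_bco` parses a BCO JSON document (from text or a file path) into a
#' `bco` object; unknown fields are preserved, and missing top-level fields
#' are left for the validator to flag rather than failing the read.
#' `write_bco` serializes a BCO to pretty-printed (2-space) JSON; the
#' canonical form is used internally for digests only. The two are inverse up
#' to canonical form.
#'
#' @param text BCO JSON text, or a path to a `.json` file.
#' @param bco a `bco` object.
#' @param path optional output file; when `NULL` the JSON text is returned.
#' @return `read_bco`: a `bco`; `write_bco`: the JSON text (invisibly when
#'   written to a file).
#' @export
read_bco <- function(text) {
  if (length(text) == 1L && !grepl("[{\n]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  tree <- tryCatch(parse_json_text(text), error = function(e) {
    stop_with_class(paste0("BCO JSON parse error: ", conditionMessage(e)),
                    "bcokit_parse_error")
  })
  if (!is.list(tree) || is.null(names(tree))) {
    stop_with_class("BCO document is not a JSON object", "bcokit_parse_error")
  }
  structure(repair_bco_tree(tree), class = "bco")
}

#' @rdname read_bco
#' @export
write_bco <- function(bco, path = NULL) {
  txt <- pretty_json(unclass(bco))
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path, useBytes = TRUE)
  invisible(txt)
}

#' @export
print.bco <- function(x, ...) {
  cat("<bco> ", x$object_id %||% "<no object_id>", "\n", sep = "")
  cat("  etag: ", x$etag %||% "<unset>", "\n", sep = "")
  cat("  domains present: ",
      sum(BCO_DOMAINS %in% names(x)), "/8\n", sep = "")
  invisible(x)
}
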