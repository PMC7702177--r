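#' JSON tree helpers
#'
#' BCO and CWL documents are held as plain R lists in the shape produced by
#' [jsonlite::parse_json()]: JSON objects are named lists, JSON arrays are
#' unnamed lists, scalars are length-1 vectors. An empty R `list()` is
#' ambiguous between `{}` and `[]`; `json_obj()` and `json_arr()` tag the
#' empty cases so serialization is unambiguous.
#'
#' @param ... members of the object/array.
#' @return A list tagged as a JSON object or array.
#' @examples
#' canonical_bytes(list(a = json_arr(), b = json_obj()))
#' @export
json_obj <- function(...) {
  x <- list(...)
  if (is.null(names(x))) names(x) <- character(length(x))
  structure(x, class = "json_obj")
}

#' @rdname json_obj
#' @export
json_arr <- function(...) {
  structure(unname(list(...)), class = "json_arr")
}

is_json_object <- function(x) {
  if (inherits(x, "json_obj")) return(TRUE)
  if (inherits(x, "json_arr")) return(FALSE)
  is.list(x) && !is.null(names(x)) && length(x) > 0
}

is_json_array <- function(x) {
  is.list(x) && !is_json_object(x)
}

# Shortest decimal representation that round-trips to the same double.
# Integer-valued doubles within the exact range print without a decimal
# point, matching Python's json module on ints.
format_json_number <- function(x) {
  if (is.na(x)) stop("cannot serialize NA/NaN as JSON", call. = FALSE)
  if (is.infinite(x)) stop("cannot serialize Inf as JSON", call. = FALSE)
  if (x == trunc(x) && abs(x) < 2^53) {
    return(sprintf("%.0f", x))
  }
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g", width = -1)
    if (as.numeric(s) == x) return(s)
  }
  formatC(x, digits = 17, format = "g", width = -1)
}

escape_json_string <- function(s) {
  s <- enc2utf8(s)
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  s <- gsub("\b", "\\b", s, fixed = TRUE)
  s <- gsub("\f", "\\f", s, fixed = TRUE)
  # remaining C0 control characters -> \u00XX
  if (grepl("[\x01-\x1f]", s, useBytes = TRUE)) {
    for (code in 1:31) {
      ch <- rawToChar(as.raw(code))
      if (ch %in% c("\n", "\r", "\t", "\b", "\f")) next
      s <- gsub(ch, sprintf("\\u%04x", code), s, fixed = TRUE, useBytes = TRUE)
    }
  }
  s
}

serialize_scalar <- function(x) {
  if (is.null(x)) return("null")
  if (is.character(x)) return(paste0("\"", escape_json_string(x), "\""))
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) return(format_json_number(as.double(x)))
  stop("value of class '", paste(class(x), collapse = "/"),
       "' is not JSON-representable", call. = FALSE)
}

serialize_tree <- function(x, sort_keys, indent, depth = 0L) {
  pad  <- if (indent > 0L) strrep(" ", indent * (depth + 1L)) else ""
  padc <- if (indent > 0L) strrep(" ", indent * depth) else ""
  nl   <- if (indent > 0L) "\n" else ""
  sep  <- if (indent > 0L) ": " else ":"
  if (!is.list(x)) {
    if (length(x) > 1L) {  # atomic vector -> array
      x <- as.list(x)
    } else {
      return(serialize_scalar(if (length(x) == 0L) NULL else x))
    }
  }
  if (is_json_object(x) || inherits(x, "json_obj")) {
    if (length(x) == 0L) return("{}")
    keys <- names(x)
    if (anyNA(keys) || any(keys == "")) {
      stop("JSON object has unnamed members", call. = FALSE)
    }
    if (anyDuplicated(keys)) stop("duplicate JSON object keys", call. = FALSE)
    ord <- if (sort_keys) order(method = "radix", keys) else seq_along(keys)
    items <- vapply(ord, function(i) {
      paste0(pad, "\"", escape_json_string(keys[i]), "\"", sep,
             serialize_tree(x[[i]], sort_keys, indent, depth + 1L))
    }, character(1))
    paste0("{", nl, paste(items, collapse = paste0(",", nl)), nl, padc, "}")
  } else {
    if (length(x) == 0L) return("[]")
    items <- vapply(seq_along(x), function(i) {
      paste0(pad, serialize_tree(x[[i]], sort_keys, indent, depth + 1L))
    }, character(1))
    paste0("[", nl, paste(items, collapse = paste0(",", nl)), nl, padc, "]")
  }
}

#' Canonical JSON bytes
#'
#' Serializes a JSON-representable tree to its canonical form: UTF-8, keys
#' sorted lexicographically (bytewise) at every depth, no insignificant
#' whitespace, no trailing newline. Canonical bytes are the input to the BCO
#' content-integrity digest, so two trees that differ only in key order or
#' formatting hash identically.
#'
#' @param tree a JSON-representable R list (see [json_obj()]).
#' @return A `raw` vector of UTF-8 bytes.
#' @examples
#' rawToChar(canonical_bytes(list(b = 1, a = 2)))
#' @export
canonical_bytes <- function(tree) {
  charToRaw(enc2utf8(serialize_tree(tree, sort_keys = TRUE, indent = 0L)))
}

#' Pretty JSON text
#'
#' Human-facing 2-space-indented JSON preserving key insertion order.
#' Deterministic for a fixed tree.
#'
#' @param tree a JSON-representable R list.
#' @param indent spaces per level.
#' @return A character scalar (with trailing newline).
#' @export
pretty_json <- function(tree, indent = 2L) {
  paste0(serialize_tree(tree, sort_keys = FALSE, indent = as.integer(indent)), "\n")
}

sha256_hex <- function(bytes) {
  digest::digest(bytes, algo = "sha256", serialize = FALSE)
}

parse_json_text <- function(text) {
  jsonlite::parse_json(text, simplifyVector = FALSE)
}
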