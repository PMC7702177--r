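DOMAIN_ORDER <- c("top_level", "provenance", "usability", "extension",
                  "description", "execution", "parametric", "io", "error")

domain_key <- function(short) {
  if (short == "top_level") return(NA_character_)
  paste0(short, "_domain")
}

domain_title <- function(short) {
  c(top_level = "Top-level fields", provenance = "Provenance domain",
    usability = "Usability domain", extension = "Extension domain",
    description = "Description domain", execution = "Execution domain",
    parametric = "Parametric domain", io = "Input/Output domain",
    error = "Error domain")[[short]]
}

html_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

# Generic value rendering that prints every scalar leaf (the report must not
# silently omit fields).
render_value_html <- function(x) {
  if (is.null(x)) return("<em>null</em>")
  if (!is.list(x)) return(html_escape(paste(format(x), collapse = ", ")))
  if (length(x) == 0L) {
    return(if (is_json_object(x)) "<em>empty</em>" else "<em>none</em>")
  }
  if (is_json_object(x)) {
    rows <- vapply(names(x), function(k) {
      sprintf("<tr><th>%s</th><td>%s</td></tr>", html_escape(k),
              render_value_html(x[[k]]))
    }, character(1))
    paste0("<table class=\"kv\">", paste(rows, collapse = ""), "</table>")
  } else {
    items <- vapply(x, function(v) {
      paste0("<li>", render_value_html(v), "</li>")
    }, character(1))
    paste0("<ol>", paste(items, collapse = ""), "</ol>")
  }
}

top_level_tree <- function(bco) {
  keys <- intersect(BCO_TOP_LEVEL, names(bco))
  structure(lapply(keys, function(k) bco[[k]]), names = keys,
            class = "json_obj")
}

#' Render a BCO as a printable report
#'
#' Produces one section per domain category in the standard's fixed order
#' (top-level fields, provenance, usability, extension, description,
#' execution, parametric, input/output, error) — nine sections for a complete
#' object. HTML is the canonical rendering; PDF is derived from it via an
#' external `wkhtmltopdf`/`weasyprint` binary when one is on the PATH, and an
#' explicit error suggesting HTML otherwise. Deterministic given a frozen
#' clock (the generated-at stamp uses the injectable clock).
#'
#' @param bco a `bco`.
#' @param format `"html"` or `"pdf"`.
#' @param path optional output file.
#' @return HTML text (character) or PDF bytes (raw); written to `path` when
#'   given.
#' @export
render_report <- function(bco, format = c("html", "pdf"), path = NULL) {
  format <- match.arg(format)
  sections <- vapply(DOMAIN_ORDER, function(short) {
    key <- domain_key(short)
    value <- if (is.na(key)) top_level_tree(bco) else bco[[key]]
    if (is.na(key) || !is.null(value)) {
      sprintf("<section><h2>%s</h2>%s</section>",
              domain_title(short), render_value_html(value))
    } else {
      ""
    }
  }, character(1))
  title <- bco$provenance_domain$name %||% "BioCompute Object"
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
    "<title>", html_escape(title), "</title>",
    "<style>body{font-family:sans-serif;max-width:60em;margin:auto}",
    "table.kv{border-collapse:collapse;margin:0.3em 0}",
    "table.kv th{text-align:left;padding:2px 8px;vertical-align:top}",
    "table.kv td{padding:2px 8px}section{margin-bottom:1em}</style>",
    "</head><body>\n<h1>", html_escape(title), "</h1>\n",
    "<p class=\"stamp\">generated ", html_escape(bco_now()), "</p>\n",
    paste(sections[nzchar(sections)], collapse = "\n"),
    "\n</body></html>\n")
  if (format == "html") {
    if (!is.null(path)) {
      writeLines(sub("\n$", "", html), path, useBytes = TRUE)
      return(invisible(html))
    }
    return(html)
  }
  backend <- c(Sys.which("wkhtmltopdf"), Sys.which("weasyprint"))
  backend <- backend[nzchar(backend)][1]
  if (is.na(backend)) {
    stop("no PDF backend (wkhtmltopdf/weasyprint) available; ",
         "use format = \"html\" instead", call. = FALSE)
  }
  tmp <- tempfile(fileext = ".html")
  on.exit(unlink(tmp))
  writeLines(html, tmp, useBytes = TRUE)
  out <- path %||% tempfile(fileext = ".pdf")
  system2(backend, c(tmp, out), stdout = FALSE, stderr = FALSE)
  bytes <- readBin(out, "raw", file.info(out)$size)
  if (is.null(path)) unlink(out)
  bytes
}

inspect_lines <- function(x, indent = 0L) {
  pad <- strrep("  ", indent)
  if (is.null(x)) return(paste0(pad, "null"))
  if (!is.list(x)) {
    tp <- json_type_of(x)
    return(paste0(pad, format(x), "  <", tp, ">"))
  }
  if (length(x) == 0L) {
    return(paste0(pad, if (is_json_object(x)) "{}  <object>" else "[]  <array>"))
  }
  if (is_json_object(x)) {
    unlist(lapply(names(x), function(k) {
      v <- x[[k]]
      if (is.list(v) && length(v) > 0L) {
        c(paste0(pad, k, ":"), inspect_lines(v, indent + 1L))
      } else {
        paste0(pad, k, ": ", sub("^\\s*", "", inspect_lines(v, 0L)))
      }
    }))
  } else {
    unlist(lapply(seq_along(x), function(i) {
      v <- x[[i]]
      if (is.list(v) && length(v) > 0L) {
        c(paste0(pad, "- [", i, "]"), inspect_lines(v, indent + 1L))
      } else {
        paste0(pad, "- ", sub("^\\s*", "", inspect_lines(v, 0L)))
      }
    }))
  }
}

#' Textual domain-wise inspection of a BCO
#'
#' Pretty tree view of one domain category or (default) all nine in standard
#' order, with nested structures indented and scalar types annotated — the
#' static counterpart of the interactive browser.
#'
#' @param bco a `bco`.
#' @param domain optional category name: one of `top_level`, `provenance`,
#'   `usability`, `extension`, `description`, `execution`, `parametric`,
#'   `io`, `error`.
#' @return Character vector of lines (also printed invisibly usable).
#' @export
inspect <- function(bco, domain = NULL) {
  cats <- DOMAIN_ORDER
  if (!is.null(domain)) {
    if (!domain %in% cats) {
      stop("unknown domain '", domain, "'; valid names: ",
           paste(cats, collapse = ", "), call. = FALSE)
    }
    cats <- domain
  }
  out <- character()
  for (short in cats) {
    key <- domain_key(short)
    value <- if (is.na(key)) top_level_tree(bco) else bco[[key]]
    out <- c(out, paste0("== ", domain_title(short), " =="),
             if (is.null(value)) "  <absent>" else inspect_lines(value, 1L),
             "")
  }
  out
}
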