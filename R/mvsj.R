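# ---------------------------------------------------------------------------
# MVSJ: the JSON serialization of a state document.
#
# Key order is deterministic (document: metadata, root; node: kind, params,
# children; params in schema order) so that equal documents serialize to
# identical bytes for a fixed indent.
# ---------------------------------------------------------------------------

emit_string <- function(s) paste0('"', json_escape(s), '"')

emit_array <- function(items, level, pad) {
  if (!length(items)) return("[]")
  ind <- strrep(pad, level + 1L)
  paste0("[\n", paste0(ind, items, collapse = ",\n"), "\n",
         strrep(pad, level), "]")
}

emit_object <- function(keys, values, level, pad) {
  if (!length(keys)) return("{}")
  ind <- strrep(pad, level + 1L)
  paste0("{\n",
         paste0(ind, emit_string(keys), ": ", values, collapse = ",\n"),
         "\n", strrep(pad, level), "}")
}

emit_expression <- function(expr, level, pad) {
  nms <- intersect(expr_fields, names(expr))
  vals <- vapply(nms, function(nm) {
    if (nm %in% expr_int_fields) json_number(expr[[nm]])
    else emit_string(expr[[nm]])
  }, character(1))
  emit_object(nms, vals, level, pad)
}

emit_param <- function(type, value, level, pad) {
  switch(type,
    string = , enum = , color = emit_string(value),
    number = json_number(value),
    numvec = emit_array(json_number(value), level, pad),
    strvec = emit_array(emit_string(value), level, pad),
    selector = {
      if (is.character(value)) emit_string(value)
      else if (is_mvs_expression(value)) emit_expression(value, level, pad)
      else emit_array(vapply(value, emit_expression, character(1),
                             level + 1L, pad), level, pad)
    },
    mvs_stop("unhandled param type: ", type)
  )
}

emit_node <- function(node, level, pad) {
  schema <- mvs_param_schema[[node$kind]]
  keys <- character(0); vals <- character(0)
  for (f in schema) {
    v <- node$params[[f$name]]
    if (is.null(v)) next
    keys <- c(keys, f$name)
    vals <- c(vals, emit_param(f$type, v, level + 2L, pad))
  }
  children <- vapply(node$children, emit_node, character(1), level + 2L, pad)
  emit_object(
    c("kind", "params", "children"),
    c(emit_string(node$kind),
      emit_object(keys, vals, level + 1L, pad),
      emit_array(children, level + 1L, pad)),
    level, pad
  )
}

#' Serialize a state document to MVSJ text
#'
#' @param doc an `mvs_state` document.
#' @param indent number of spaces per nesting level (default 2).
#' @param check validate the document first and stop on violations.
#' @return a single string of UTF-8 JSON (with trailing newline).
#' @seealso [parse_mvsj()]
#' @export
serialize_mvsj <- function(doc, indent = 2L, check = TRUE) {
  stopifnot(inherits(doc, "mvs_state"))
  if (check) {
    v <- validate_tree(doc)
    v <- v[v$severity == "error", , drop = FALSE]
    if (nrow(v)) {
      mvs_stop("document is not valid:\n",
               paste0("  - ", v$path, ": ", v$message, collapse = "\n"),
               class = "mvs_validation_error")
    }
  }
  indent <- as.integer(indent %||% 2L)
  if (is.na(indent) || indent < 0L) mvs_stop("indent must be >= 0")
  pad <- strrep(" ", indent)
  meta <- doc$metadata
  meta_keys <- intersect(c("version", "timestamp", "title", "description",
                           "description_format"), names(meta))
  if (!("version" %in% meta_keys)) mvs_stop("metadata must carry a version")
  meta_json <- emit_object(meta_keys,
                           vapply(meta_keys,
                                  function(k) emit_string(meta[[k]]),
                                  character(1)),
                           1L, pad)
  paste0(emit_object(c("metadata", "root"),
                     c(meta_json, emit_node(doc$root, 1L, pad)), 0L, pad),
         "\n")
}

decode_expression <- function(x, where) {
  if (!is.list(x)) mvs_stop(where, ": expected an expression object")
  if (length(x) && is.null(names(x))) {
    mvs_stop(where, ": expected an expression object, got an array")
  }
  bad <- setdiff(names(x), expr_fields)
  if (length(bad)) {
    mvs_stop(where, ": unknown expression field(s): ",
             paste(bad, collapse = ", "))
  }
  do.call(mvs_expression, x)
}

decode_param <- function(type, value, where) {
  un <- function(v) unlist(v, use.names = FALSE)
  switch(type,
    string = , enum = , color = {
      if (!is.character(value) || length(value) != 1L) {
        mvs_stop(where, ": expected a string")
      }
      value
    },
    number = {
      if (!is.numeric(value) || length(value) != 1L) {
        mvs_stop(where, ": expected a number")
      }
      as.double(value)
    },
    numvec = {
      v <- un(value)
      if (!is.numeric(v)) mvs_stop(where, ": expected an array of numbers")
      as.double(v)
    },
    strvec = {
      v <- un(value)
      if (is.numeric(v)) v <- as.character(v)
      if (!is.character(v)) mvs_stop(where, ": expected strings")
      v
    },
    selector = {
      if (is.character(value) && length(value) == 1L) value
      else if (is.list(value) && (length(value) == 0L || !is.null(names(value)))) {
        decode_expression(value, where)
      } else if (is.list(value)) {
        lapply(value, decode_expression, where = where)
      } else {
        mvs_stop(where, ": invalid selector encoding")
      }
    },
    mvs_stop("unhandled param type: ", type)
  )
}

decode_node <- function(x, where, version) {
  if (!is.list(x)) mvs_stop(where, ": node must be a JSON object")
  bad <- setdiff(names(x), c("kind", "params", "children"))
  if (length(bad)) {
    mvs_stop(where, ": unknown node key(s): ", paste(bad, collapse = ", "))
  }
  kind <- x$kind
  if (!is_string(kind)) mvs_stop(where, ": node is missing its kind")
  if (!(kind %in% mvs_node_kinds)) {
    mvs_stop(where, ": unknown node kind '", kind,
             "' (document format version ", version, ")",
             class = "mvs_unknown_kind_error")
  }
  schema <- mvs_param_schema[[kind]]
  declared <- vapply(schema, `[[`, character(1), "name")
  raw_params <- x$params %||% list()
  if (length(raw_params) && is.null(names(raw_params))) {
    mvs_stop(where, ": params must be a JSON object")
  }
  unknown <- setdiff(names(raw_params), declared)
  if (length(unknown)) {
    mvs_stop(where, ": unknown param(s) for '", kind, "': ",
             paste(unknown, collapse = ", "), class = "mvs_params_error")
  }
  params <- list()
  for (f in schema) {
    v <- raw_params[[f$name]]
    if (is.null(v)) next
    params[[f$name]] <- decode_param(f$type, v,
                                     paste0(where, " param '", f$name, "'"))
  }
  children <- lapply(seq_along(x$children %||% list()), function(i) {
    decode_node(x$children[[i]],
                paste0(where, "/children[", i, "]"), version)
  })
  mvs_node(kind, params, children, check = "collect")
}

#' Parse MVSJ text into a state document
#'
#' Structural problems (malformed JSON, unknown node kinds, unknown
#' parameter keys, a format version newer than supported) raise errors;
#' value-level problems (e.g. an out-of-enum format string) are kept and
#' reported by [validate_tree()].
#'
#' @param text MVSJ JSON text (or a connection/path accepted by
#'   [jsonlite::fromJSON()] is *not* supported; pass text).
#' @return an `mvs_state` document.
#' @export
parse_mvsj <- function(text) {
  x <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                error = function(e) {
                  mvs_stop("malformed MVSJ JSON: ", conditionMessage(e),
                           class = "mvs_parse_error")
                })
  if (!is.list(x)) mvs_stop("MVSJ document must be a JSON object")
  bad <- setdiff(names(x), c("metadata", "root"))
  if (length(bad)) {
    mvs_stop("unknown document key(s): ", paste(bad, collapse = ", "))
  }
  meta <- x$metadata %||% list()
  version <- meta$version
  if (!is_string(version)) {
    version <- if (is.numeric(version) && length(version) == 1L) {
      as.character(version)
    } else {
      mvs_stop("MVSJ metadata must declare a version")
    }
  }
  vnum <- suppressWarnings(as.numeric(version))
  if (!is.na(vnum) && vnum > as.numeric(MVS_VERSION)) {
    mvs_stop("Newer format version: this document declares version '",
             version, "' but only versions up to '", MVS_VERSION,
             "' are supported; update the toolkit.",
             class = "mvs_version_error")
  }
  known_meta <- c("version", "timestamp", "title", "description",
                  "description_format")
  bad_meta <- setdiff(names(meta), known_meta)
  if (length(bad_meta)) {
    mvs_stop("unknown metadata key(s): ", paste(bad_meta, collapse = ", "))
  }
  meta <- meta[intersect(known_meta, names(meta))]
  meta <- lapply(meta, as.character)
  if (is.null(x$root)) mvs_stop("MVSJ document has no root node")
  root <- decode_node(x$root, "root", version)
  if (!identical(root$kind, "root")) {
    mvs_stop("document root must have kind 'root', found '", root$kind, "'")
  }
  structure(list(metadata = meta, root = root), class = "mvs_state")
}
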