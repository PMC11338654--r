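# ---------------------------------------------------------------------------
# Node-tree data model: kinds, parameter schemas, grammar, validation.
#
# A state document is a metadata header plus a tree of typed nodes
# (download -> parse -> structure -> component -> representation -> color,
# plus camera/canvas/labels/tooltips).  Nodes are plain lists
# list(kind, params, children); documents are list(metadata, root).
# ---------------------------------------------------------------------------

MVS_VERSION <- "1"

parse_formats <- c("mmcif", "bcif", "pdb")
annotation_formats <- c("cif", "bcif", "json")
representation_types <- c("cartoon", "surface", "ball_and_stick")
named_selectors <- c("all", "polymer", "protein", "nucleic", "branched",
                     "ligand", "ion", "water")
annotation_schemas <- c("entity", "chain", "residue", "residue_range", "atom",
                        "auth_chain", "auth_residue", "auth_residue_range",
                        "auth_atom", "all_atomic")

# independent-variable columns of annotation tables; group_id added there
expr_int_fields <- c("label_seq_id", "beg_label_seq_id", "end_label_seq_id",
                     "auth_seq_id", "beg_auth_seq_id", "end_auth_seq_id",
                     "atom_id", "atom_index")
expr_str_fields <- c("label_entity_id", "label_asym_id", "label_atom_id",
                     "auth_asym_id", "pdbx_PDB_ins_code", "auth_atom_id",
                     "type_symbol")
expr_fields <- c("label_entity_id", "label_asym_id", "label_seq_id",
                 "beg_label_seq_id", "end_label_seq_id", "label_atom_id",
                 "auth_asym_id", "auth_seq_id", "pdbx_PDB_ins_code",
                 "beg_auth_seq_id", "end_auth_seq_id", "auth_atom_id",
                 "type_symbol", "atom_id", "atom_index")

# Allowed child kinds per parent kind.
mvs_grammar <- local({
  under_structure <- c("transform", "component", "component_from_uri",
                       "component_from_source", "label_from_uri",
                       "label_from_source", "tooltip_from_uri",
                       "tooltip_from_source")
  under_component <- c("representation", "label", "tooltip", "focus")
  under_representation <- c("color", "color_from_uri", "color_from_source")
  list(
    root = c("download", "camera", "canvas"),
    download = "parse",
    parse = "structure",
    structure = under_structure,
    component = under_component,
    component_from_uri = under_component,
    component_from_source = under_component,
    representation = under_representation,
    transform = character(0),
    color = character(0), color_from_uri = character(0),
    color_from_source = character(0),
    label = character(0), label_from_uri = character(0),
    label_from_source = character(0),
    tooltip = character(0), tooltip_from_uri = character(0),
    tooltip_from_source = character(0),
    focus = character(0), camera = character(0), canvas = character(0)
  )
})

mvs_node_kinds <- names(mvs_grammar)

fld <- function(name, type, required = FALSE, enum = NULL, len = NULL) {
  list(name = name, type = type, required = required, enum = enum, len = len)
}

mvs_param_schema <- local({
  ann_ref <- function(with_uri, with_values) {
    out <- list()
    if (with_uri) {
      out <- c(out, list(fld("uri", "string", required = TRUE),
                         fld("format", "enum", required = TRUE,
                             enum = annotation_formats)))
    }
    out <- c(out, list(fld("block_header", "string"),
                       fld("category_name", "string"),
                       fld("field_name", "string")))
    if (with_values) out <- c(out, list(fld("field_values", "strvec")))
    c(out, list(fld("schema", "enum", required = TRUE,
                    enum = annotation_schemas)))
  }
  list(
    root = list(),
    download = list(fld("url", "string", required = TRUE)),
    parse = list(fld("format", "enum", required = TRUE, enum = parse_formats)),
    structure = list(
      fld("type", "enum", required = TRUE, enum = c("model", "assembly")),
      fld("assembly_id", "string"),
      fld("block_index", "number"),
      fld("model_index", "number")
    ),
    transform = list(fld("rotation", "numvec", len = 9L),
                     fld("translation", "numvec", len = 3L)),
    component = list(fld("selector", "selector", required = TRUE)),
    component_from_uri = ann_ref(TRUE, TRUE),
    component_from_source = ann_ref(FALSE, TRUE),
    representation = list(fld("type", "enum", required = TRUE,
                              enum = representation_types)),
    color = list(fld("color", "color", required = TRUE),
                 fld("selector", "selector")),
    color_from_uri = ann_ref(TRUE, FALSE),
    color_from_source = ann_ref(FALSE, FALSE),
    label = list(fld("text", "string", required = TRUE)),
    label_from_uri = ann_ref(TRUE, FALSE),
    label_from_source = ann_ref(FALSE, FALSE),
    tooltip = list(fld("text", "string", required = TRUE)),
    tooltip_from_uri = ann_ref(TRUE, FALSE),
    tooltip_from_source = ann_ref(FALSE, FALSE),
    focus = list(),
    camera = list(fld("target", "numvec", required = TRUE, len = 3L),
                  fld("position", "numvec", required = TRUE, len = 3L),
                  fld("up", "numvec", len = 3L)),
    canvas = list(fld("background_color", "color", required = TRUE))
  )
})

#' Atom-addressing selection expression
#'
#' A partial atom address: any subset of the `label_*` / `auth_*` namespace
#' fields may be given and an atom matches when every set field matches
#' (ranges `beg_* <= x <= end_*` inclusive).  An empty expression matches all
#' atoms.
#'
#' @param label_entity_id,label_asym_id,label_atom_id,auth_asym_id,auth_atom_id,pdbx_PDB_ins_code,type_symbol
#'   text-valued address fields.
#' @param label_seq_id,beg_label_seq_id,end_label_seq_id,auth_seq_id,beg_auth_seq_id,end_auth_seq_id,atom_id,atom_index
#'   integer-valued address fields (`atom_index` is 0-based; seq ids 1-based).
#' @return an object of class `mvs_component_expression`.
#' @examples
#' mvs_expression(label_asym_id = "E", label_atom_id = "FE")
#' @export
mvs_expression <- function(label_entity_id = NULL, label_asym_id = NULL,
                           label_seq_id = NULL, beg_label_seq_id = NULL,
                           end_label_seq_id = NULL, label_atom_id = NULL,
                           auth_asym_id = NULL, auth_seq_id = NULL,
                           pdbx_PDB_ins_code = NULL, beg_auth_seq_id = NULL,
                           end_auth_seq_id = NULL, auth_atom_id = NULL,
                           type_symbol = NULL, atom_id = NULL,
                           atom_index = NULL) {
  vals <- list(
    label_entity_id = label_entity_id, label_asym_id = label_asym_id,
    label_seq_id = label_seq_id, beg_label_seq_id = beg_label_seq_id,
    end_label_seq_id = end_label_seq_id, label_atom_id = label_atom_id,
    auth_asym_id = auth_asym_id, auth_seq_id = auth_seq_id,
    pdbx_PDB_ins_code = pdbx_PDB_ins_code, beg_auth_seq_id = beg_auth_seq_id,
    end_auth_seq_id = end_auth_seq_id, auth_atom_id = auth_atom_id,
    type_symbol = type_symbol, atom_id = atom_id, atom_index = atom_index
  )
  vals <- vals[!vapply(vals, is.null, logical(1))]
  for (nm in intersect(names(vals), expr_int_fields)) {
    vals[[nm]] <- as.double(vals[[nm]])
  }
  for (nm in intersect(names(vals), expr_str_fields)) {
    vals[[nm]] <- as.character(vals[[nm]])
  }
  structure(vals, class = "mvs_component_expression")
}

is_mvs_expression <- function(x) inherits(x, "mvs_component_expression")

check_expression <- function(x) {
  probs <- character(0)
  bad <- setdiff(names(x), expr_fields)
  if (length(bad)) {
    probs <- c(probs, paste0("unknown expression field(s): ",
                             paste(bad, collapse = ", ")))
  }
  for (nm in intersect(names(x), expr_int_fields)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != floor(v)) {
      probs <- c(probs, paste0("expression field '", nm,
                               "' must be a single integer"))
    }
  }
  for (pair in list(c("beg_label_seq_id", "end_label_seq_id"),
                    c("beg_auth_seq_id", "end_auth_seq_id"))) {
    b <- x[[pair[1]]]; e <- x[[pair[2]]]
    if (!is.null(b) && !is.null(e) && is.numeric(b) && is.numeric(e) &&
        b > e) {
      probs <- c(probs, paste0(pair[1], " > ", pair[2]))
    }
  }
  probs
}

check_selector <- function(sel) {
  if (is.character(sel)) {
    if (!is_string(sel) || !(sel %in% named_selectors)) {
      return(paste0("named selector must be one of: ",
                    paste(named_selectors, collapse = ", ")))
    }
    return(character(0))
  }
  if (is_mvs_expression(sel)) return(check_expression(sel))
  if (is.list(sel)) {
    probs <- character(0)
    for (e in sel) {
      if (!is_mvs_expression(e)) {
        probs <- c(probs, "selector list elements must be component expressions")
      } else {
        probs <- c(probs, check_expression(e))
      }
    }
    return(probs)
  }
  "selector must be a named selector, a component expression, or a list of expressions"
}

coerce_param <- function(f, value) {
  switch(f$type,
    string = , enum = , color = {
      if (is.character(value) && length(value) == 1L) as.character(value)
      else value
    },
    number = if (is.numeric(value)) as.double(value) else value,
    numvec = if (is.numeric(value)) as.double(value) else value,
    strvec = {
      if (is.list(value)) value <- unlist(value, use.names = FALSE)
      if (is.character(value) || is.numeric(value)) as.character(value)
      else value
    },
    selector = {
      if (is.character(value) && length(value) == 1L) {
        as.character(value)
      } else if (is_mvs_expression(value)) {
        value
      } else if (is.list(value) && all(vapply(value, is_mvs_expression, logical(1)))) {
        value
      } else {
        value
      }
    },
    value
  )
}

check_param_value <- function(kind, f, value) {
  probs <- character(0)
  p <- function(msg) paste0("param '", f$name, "' of '", kind, "': ", msg)
  switch(f$type,
    string = {
      if (!is_string(value) || !nzchar(value)) {
        probs <- c(probs, p("must be a non-empty string"))
      }
    },
    enum = {
      if (!is_string(value) || !(value %in% f$enum)) {
        probs <- c(probs, p(paste0("must be one of: ",
                                   paste(f$enum, collapse = ", "))))
      }
    },
    color = {
      if (!is_string(value) || !is_mvs_color(value)) {
        probs <- c(probs, p("must be '#RRGGBB' hex or an SVG 1.1 color keyword"))
      }
    },
    number = {
      if (!is_number_vec(value, 1L)) probs <- c(probs, p("must be a single number"))
    },
    numvec = {
      if (!is_number_vec(value, f$len)) {
        probs <- c(probs, p(paste0("must be ", f$len, " finite numbers")))
      }
    },
    strvec = {
      if (!is.character(value) || length(value) == 0L || anyNA(value)) {
        probs <- c(probs, p("must be a string or list of strings"))
      }
    },
    selector = {
      probs <- c(probs, vapply(check_selector(value), function(m) p(m),
                               character(1)))
    }
  )
  probs
}

# kind-level invariants beyond per-field types; returns list of
# list(message, severity)
check_node_invariants <- function(kind, params) {
  out <- list()
  add <- function(msg, severity = "error") {
    out[[length(out) + 1L]] <<- list(message = msg, severity = severity)
    invisible(NULL)
  }
  if (kind == "structure" && is_string(params$type)) {
    has_id <- is_string(params$assembly_id)
    if (params$type == "assembly" && !has_id) {
      add("structure type 'assembly' requires assembly_id")
    }
    if (params$type == "model" && has_id) {
      add("assembly_id is only allowed when type is 'assembly'")
    }
  }
  if (kind == "transform" && is_number_vec(params$rotation %||% NA, 9L)) {
    defect <- rotation_orthonormality_defect(params$rotation)
    if (defect > 1e-1) {
      add(sprintf("rotation is not orthonormal (defect %.3g > 0.1)", defect))
    } else if (defect > 1e-3) {
      add(sprintf("rotation deviates from orthonormality (defect %.3g)", defect),
          severity = "warning")
    }
  }
  if (kind == "camera" &&
      is_number_vec(params$target %||% NA, 3L) &&
      is_number_vec(params$position %||% NA, 3L)) {
    dir <- params$position - params$target
    if (all(dir == 0)) add("camera position must differ from target")
    up <- params$up %||% c(0, 1, 0)
    if (is_number_vec(up, 3L) && any(dir != 0)) {
      cr <- c(dir[2] * up[3] - dir[3] * up[2],
              dir[3] * up[1] - dir[1] * up[3],
              dir[1] * up[2] - dir[2] * up[1])
      if (max(abs(cr)) < 1e-12) add("camera up vector is parallel to the view direction")
    }
  }
  out
}

# Validates keys/types for one node's params. Unknown keys are always an
# error (strict format). Returns list(params = coerced, problems = list).
check_params <- function(kind, params) {
  schema <- mvs_param_schema[[kind]]
  declared <- vapply(schema, `[[`, character(1), "name")
  problems <- list()
  add <- function(msg, severity = "error") {
    problems[[length(problems) + 1L]] <<- list(message = msg, severity = severity)
  }
  unknown <- setdiff(names(params), declared)
  if (length(unknown)) {
    add(paste0("unknown param(s) for '", kind, "': ",
               paste(unknown, collapse = ", ")))
  }
  out <- list()
  for (f in schema) {
    if (!is.null(params[[f$name]])) {
      v <- coerce_param(f, params[[f$name]])
      for (m in check_param_value(kind, f, v)) add(m)
      out[[f$name]] <- v
    } else if (f$required) {
      add(paste0("param '", f$name, "' of '", kind, "' is required"))
    }
  }
  for (inv in check_node_invariants(kind, out)) {
    add(inv$message, inv$severity)
  }
  list(params = out, problems = problems)
}

#' Construct a state-tree node
#'
#' Low-level constructor; the fluent builder (see [mvs_builder()]) is the
#' usual way to create nodes. Unknown kinds and unknown parameter keys are
#' always rejected; with `check = "error"` any parameter-level problem stops.
#'
#' @param kind node kind (e.g. `"download"`, `"component"`).
#' @param params named list of kind-specific parameters.
#' @param children list of child nodes.
#' @param check `"error"` to stop on invalid parameter values, `"collect"` to
#'   defer them to [validate_tree()].
#' @return a node: `list(kind, params, children)` of class `mvs_node`.
#' @export
mvs_node <- function(kind, params = list(), children = list(),
                     check = c("error", "collect")) {
  check <- match.arg(check)
  if (!is_string(kind) || !(kind %in% mvs_node_kinds)) {
    mvs_stop("unknown node kind: ",
             if (is_string(kind)) paste0("'", kind, "'") else "<non-string>",
             class = "mvs_unknown_kind_error")
  }
  res <- check_params(kind, params)
  msgs <- vapply(res$problems, `[[`, character(1), "message")
  sev <- vapply(res$problems, `[[`, character(1), "severity")
  unknown_key <- any(grepl("^unknown param", msgs))
  if (any(sev == "error") && (check == "error" || unknown_key)) {
    mvs_stop(paste(msgs[sev == "error"], collapse = "; "),
             class = "mvs_params_error")
  }
  if (check == "error") for (m in msgs[sev == "warning"]) mvs_warn(m)
  structure(list(kind = kind, params = res$params, children = children),
            class = "mvs_node")
}

#' Create an empty state document
#'
#' @param title,description,description_format optional metadata fields.
#' @param timestamp ISO-8601 creation time; defaults to the current UTC time.
#' @return an object of class `mvs_state`, `list(metadata, root)`.
#' @export
mvs_state_document <- function(title = NULL, description = NULL,
                               description_format = NULL, timestamp = NULL) {
  meta <- list(version = MVS_VERSION,
               timestamp = timestamp %||%
                 format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  if (!is.null(title)) meta$title <- as.character(title)
  if (!is.null(description)) meta$description <- as.character(description)
  if (!is.null(description_format)) {
    if (!description_format %in% c("markdown", "plaintext")) {
      mvs_stop("description_format must be 'markdown' or 'plaintext'")
    }
    meta$description_format <- description_format
  }
  structure(list(metadata = meta, root = mvs_node("root")), class = "mvs_state")
}

node_path_label <- function(kinds, ordinals) {
  paste(paste0(kinds, "#", ordinals), collapse = "/")
}

#' Validate a state document against the node grammar
#'
#' Walks the tree and reports every violation (disallowed child kinds,
#' missing or invalid parameters, broken kind-level invariants) as data.
#' An empty result means the document is valid. Rows with
#' `severity == "warning"` (e.g. a mildly non-orthonormal rotation) do not
#' make the document invalid.
#'
#' @param doc an `mvs_state` document.
#' @return data.frame with columns `path`, `kind`, `message`, `severity`.
#' @export
validate_tree <- function(doc) {
  stopifnot(inherits(doc, "mvs_state"))
  rows <- list()
  add <- function(path, kind, message, severity = "error") {
    rows[[length(rows) + 1L]] <<- data.frame(path = path, kind = kind,
                                             message = message,
                                             severity = severity,
                                             stringsAsFactors = FALSE)
  }
  walk <- function(node, kinds, ordinals) {
    path <- node_path_label(kinds, ordinals)
    res <- check_params(node$kind, node$params)
    for (p in res$problems) add(path, node$kind, p$message, p$severity)
    allowed <- mvs_grammar[[node$kind]]
    for (i in seq_along(node$children)) {
      child <- node$children[[i]]
      if (!(child$kind %in% allowed)) {
        add(node_path_label(c(kinds, child$kind), c(ordinals, i)), child$kind,
            paste0("kind '", child$kind, "' not allowed under '", node$kind,
                   "' (allowed: ",
                   if (length(allowed)) paste(allowed, collapse = ", ")
                   else "none", ")"))
      }
      walk(child, c(kinds, child$kind), c(ordinals, i))
    }
  }
  if (!identical(doc$root$kind, "root")) {
    add("root#1", doc$root$kind, "document root must have kind 'root'")
  }
  walk(doc$root, "root", 1L)
  if (!length(rows)) {
    return(data.frame(path = character(0), kind = character(0),
                      message = character(0), severity = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Tally node kinds in a document
#'
#' Convenience used to compare a built document against an expected node
#' multiset (e.g. two `download`, two `parse` nodes).
#'
#' @param doc an `mvs_state` document.
#' @return named integer vector, counts per node kind present.
#' @export
count_node_kinds <- function(doc) {
  kinds <- character(0)
  walk <- function(node) {
    kinds <<- c(kinds, node$kind)
    lapply(node$children, walk)
  }
  walk(doc$root)
  tab <- table(kinds[kinds != "root"])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
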