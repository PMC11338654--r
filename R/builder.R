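# ---------------------------------------------------------------------------
# Fluent, grammar-aware construction of state documents.
#
# A builder reference is a lightweight handle: a shared environment holding
# the document plus a cursor path into the tree.  Every verb appends a node
# under the cursor and returns a reference whose cursor is the new node;
# leaf verbs (color, label, tooltip, focus) return the parent reference so
# calls can be chained, e.g. rep |> mvs_color(...) |> mvs_color(...).
# ---------------------------------------------------------------------------

node_get <- function(root, path) {
  node <- root
  for (i in path) node <- node$children[[i]]
  node
}

node_append <- function(root, path, child) {
  if (!length(path)) {
    root$children[[length(root$children) + 1L]] <- child
    return(root)
  }
  i <- path[1]
  root$children[[i]] <- node_append(root$children[[i]], path[-1], child)
  root
}

new_ref <- function(env, path) {
  structure(list(env = env, path = path), class = "mvs_ref")
}

#' Start building a view state
#'
#' @param timestamp optional fixed ISO-8601 timestamp for the document
#'   metadata (useful for reproducible output); defaults to the current
#'   UTC time.
#' @return a builder reference positioned at the root node.
#' @examples
#' b <- mvs_builder(timestamp = "2024-01-01T00:00:00Z")
#' s <- b |> mvs_download("https://files.wwpdb.org/download/1oj6.cif") |>
#'   mvs_parse("mmcif") |> mvs_model_structure()
#' s |> mvs_component("polymer") |> mvs_representation("cartoon") |>
#'   mvs_color("#e19039")
#' cat(mvs_get_state(b))
#' @export
mvs_builder <- function(timestamp = NULL) {
  env <- new.env(parent = emptyenv())
  env$doc <- mvs_state_document(timestamp = timestamp)
  new_ref(env, integer(0))
}

# kinds whose verb returns the parent reference (chaining); includes
# transform so that s <- mvs_transform(s, ...) keeps s usable as the
# structure for components
leaf_return_kinds <- c("transform",
                       "color", "color_from_uri", "color_from_source",
                       "label", "label_from_uri", "label_from_source",
                       "tooltip", "tooltip_from_uri", "tooltip_from_source",
                       "focus")

#' Append a node under a builder reference
#'
#' The generic verb behind all builder methods. Fails when the grammar does
#' not allow `kind` under the cursor's node or when `params` are invalid, so
#' builder-made documents always pass [validate_tree()].
#'
#' @param ref a builder reference.
#' @param kind node kind to append.
#' @param params named list of parameters for the node.
#' @return a reference to the new node (or to `ref`'s node for leaf verbs).
#' @export
mvs_extend <- function(ref, kind, params = list()) {
  stopifnot(inherits(ref, "mvs_ref"))
  parent <- node_get(ref$env$doc$root, ref$path)
  allowed <- mvs_grammar[[parent$kind]]
  if (!(kind %in% allowed)) {
    mvs_stop("node kind '", kind, "' is not allowed under '", parent$kind,
             "'; allowed here: ",
             if (length(allowed)) paste(allowed, collapse = ", ") else "none",
             class = "mvs_grammar_error")
  }
  node <- mvs_node(kind, params, check = "error")
  ref$env$doc$root <- node_append(ref$env$doc$root, ref$path, node)
  if (kind %in% leaf_return_kinds) return(ref)
  n_children <- length(node_get(ref$env$doc$root, ref$path)$children)
  new_ref(ref$env, c(ref$path, n_children))
}

drop_nulls <- function(x) x[!vapply(x, is.null, logical(1))]

#' Builder verbs
#'
#' Each verb mirrors one node kind of the view grammar: structural data
#' acquisition (`mvs_download`, `mvs_parse`), structure instantiation
#' (`mvs_model_structure` for the deposited asymmetric unit,
#' `mvs_assembly_structure` for a biological assembly), rigid-body
#' `mvs_transform`, selections (`mvs_component` with a named selector,
#' expression or list of expressions; `mvs_component_from_uri` /
#' `mvs_component_from_source` driven by annotation tables), rendering
#' styles (`mvs_representation`), coloring (`mvs_color` and annotation
#' variants), text (`mvs_label`, `mvs_tooltip` and annotation variants),
#' camera control (`mvs_camera`, `mvs_focus`) and canvas background
#' (`mvs_canvas`).
#'
#' Defaults follow the format: a representation defaults to `"cartoon"`, a
#' component without selector selects the whole structure (`"all"`).
#'
#' @param ref a builder reference.
#' @param url,uri resource locations (absolute, or relative to the state
#'   file / bundle).
#' @param format coordinate format (`mmcif`, `bcif`, `pdb`) for
#'   [mvs_parse()]; annotation format (`cif`, `bcif`, `json`) for the
#'   `_from_uri` verbs.
#' @param assembly_id,block_index,model_index structure addressing.
#' @param rotation 9 reals, a 3x3 rotation matrix in column-major order.
#' @param translation 3 reals (Angstrom).
#' @param selector named selector, [mvs_expression()], or list of
#'   expressions.
#' @param type representation type (`cartoon`, `surface`, `ball_and_stick`).
#' @param color `#RRGGBB` hex or SVG 1.1 color keyword.
#' @param text label/tooltip text.
#' @param block_header,category_name annotation table address in a CIF file.
#' @param field_name,field_values annotation row filter (see
#'   [filter_rows()]).
#' @param schema annotation granularity (`entity`, `chain`, `residue`,
#'   `residue_range`, `atom`, `auth_*` variants, `all_atomic`).
#' @param target,position,up camera vectors.
#' @param background_color canvas background.
#' @return a builder reference (see [mvs_extend()] for cursor semantics).
#' @name builder-verbs
NULL

#' @rdname builder-verbs
#' @export
mvs_download <- function(ref, url) mvs_extend(ref, "download", list(url = url))

#' @rdname builder-verbs
#' @export
mvs_parse <- function(ref, format) mvs_extend(ref, "parse", list(format = format))

#' @rdname builder-verbs
#' @export
mvs_model_structure <- function(ref, block_index = NULL, model_index = NULL) {
  mvs_extend(ref, "structure", drop_nulls(list(
    type = "model", block_index = block_index, model_index = model_index)))
}

#' @rdname builder-verbs
#' @export
mvs_assembly_structure <- function(ref, assembly_id = "1", block_index = NULL,
                                   model_index = NULL) {
  mvs_extend(ref, "structure", drop_nulls(list(
    type = "assembly", assembly_id = assembly_id,
    block_index = block_index, model_index = model_index)))
}

#' @rdname builder-verbs
#' @export
mvs_transform <- function(ref, rotation = NULL, translation = NULL) {
  mvs_extend(ref, "transform",
             drop_nulls(list(rotation = rotation, translation = translation)))
}

#' @rdname builder-verbs
#' @export
mvs_component <- function(ref, selector = "all") {
  mvs_extend(ref, "component", list(selector = selector))
}

ann_params <- function(uri = NULL, format = NULL, block_header = NULL,
                       category_name = NULL, field_name = NULL,
                       field_values = NULL, schema = NULL) {
  drop_nulls(list(uri = uri, format = format, block_header = block_header,
                  category_name = category_name, field_name = field_name,
                  field_values = field_values, schema = schema))
}

#' @rdname builder-verbs
#' @export
mvs_component_from_uri <- function(ref, uri, format, schema,
                                   block_header = NULL, category_name = NULL,
                                   field_name = NULL, field_values = NULL) {
  mvs_extend(ref, "component_from_uri",
             ann_params(uri, format, block_header, category_name, field_name,
                        field_values, schema))
}

#' @rdname builder-verbs
#' @export
mvs_component_from_source <- function(ref, schema, block_header = NULL,
                                      category_name = NULL, field_name = NULL,
                                      field_values = NULL) {
  mvs_extend(ref, "component_from_source",
             ann_params(NULL, NULL, block_header, category_name, field_name,
                        field_values, schema))
}

#' @rdname builder-verbs
#' @export
mvs_representation <- function(ref, type = "cartoon") {
  mvs_extend(ref, "representation", list(type = type))
}

#' @rdname builder-verbs
#' @export
mvs_color <- function(ref, color, selector = NULL) {
  mvs_extend(ref, "color",
             drop_nulls(list(color = color, selector = selector %||% "all")))
}

#' @rdname builder-verbs
#' @export
mvs_color_from_uri <- function(ref, uri, format, schema, block_header = NULL,
                               category_name = NULL, field_name = NULL) {
  mvs_extend(ref, "color_from_uri",
             ann_params(uri, format, block_header, category_name, field_name,
                        NULL, schema))
}

#' @rdname builder-verbs
#' @export
mvs_color_from_source <- function(ref, schema, block_header = NULL,
                                  category_name = NULL, field_name = NULL) {
  mvs_extend(ref, "color_from_source",
             ann_params(NULL, NULL, block_header, category_name, field_name,
                        NULL, schema))
}

#' @rdname builder-verbs
#' @export
mvs_label <- function(ref, text) mvs_extend(ref, "label", list(text = text))

#' @rdname builder-verbs
#' @export
mvs_tooltip <- function(ref, text) mvs_extend(ref, "tooltip", list(text = text))

#' @rdname builder-verbs
#' @export
mvs_label_from_uri <- function(ref, uri, format, schema, block_header = NULL,
                               category_name = NULL, field_name = NULL) {
  mvs_extend(ref, "label_from_uri",
             ann_params(uri, format, block_header, category_name, field_name,
                        NULL, schema))
}

#' @rdname builder-verbs
#' @export
mvs_label_from_source <- function(ref, schema, block_header = NULL,
                                  category_name = NULL, field_name = NULL) {
  mvs_extend(ref, "label_from_source",
             ann_params(NULL, NULL, block_header, category_name, field_name,
                        NULL, schema))
}

#' @rdname builder-verbs
#' @export
mvs_tooltip_from_uri <- function(ref, uri, format, schema, block_header = NULL,
                                 category_name = NULL, field_name = NULL) {
  mvs_extend(ref, "tooltip_from_uri",
             ann_params(uri, format, block_header, category_name, field_name,
                        NULL, schema))
}

#' @rdname builder-verbs
#' @export
mvs_tooltip_from_source <- function(ref, schema, block_header = NULL,
                                    category_name = NULL, field_name = NULL) {
  mvs_extend(ref, "tooltip_from_source",
             ann_params(NULL, NULL, block_header, category_name, field_name,
                        NULL, schema))
}

#' @rdname builder-verbs
#' @export
mvs_focus <- function(ref) mvs_extend(ref, "focus")

#' @rdname builder-verbs
#' @export
mvs_camera <- function(ref, target, position, up = NULL) {
  mvs_extend(ref, "camera", drop_nulls(list(
    target = as.double(target), position = as.double(position),
    up = if (!is.null(up)) as.double(up))))
}

#' @rdname builder-verbs
#' @export
mvs_canvas <- function(ref, background_color) {
  mvs_extend(ref, "canvas", list(background_color = background_color))
}

#' Extract the current state document from a builder
#'
#' @param ref any reference into the builder.
#' @return the `mvs_state` document (a copy; further builder calls do not
#'   affect it).
#' @export
mvs_document <- function(ref) {
  stopifnot(inherits(ref, "mvs_ref"))
  ref$env$doc
}

apply_state_metadata <- function(doc, title, description, description_format) {
  if (!is.null(title)) doc$metadata$title <- as.character(title)
  if (!is.null(description)) doc$metadata$description <- as.character(description)
  if (!is.null(description_format)) {
    if (!description_format %in% c("markdown", "plaintext")) {
      mvs_stop("description_format must be 'markdown' or 'plaintext'")
    }
    doc$metadata$description_format <- description_format
  }
  doc
}

#' Export the builder state as MVSJ
#'
#' @param ref any reference into the builder.
#' @param title,description,description_format optional metadata to stamp
#'   into the exported state.
#' @param indent spaces per nesting level (default 2).
#' @return `mvs_get_state()` returns the MVSJ text; `mvs_save_state()`
#'   writes it to `destination` and returns the path invisibly.
#' @export
mvs_get_state <- function(ref, title = NULL, description = NULL,
                          description_format = NULL, indent = 2L) {
  doc <- apply_state_metadata(mvs_document(ref), title, description,
                              description_format)
  serialize_mvsj(doc, indent = indent)
}

#' @rdname mvs_get_state
#' @param destination file path for the `.mvsj` output.
#' @export
mvs_save_state <- function(ref, destination, title = NULL, description = NULL,
                           description_format = NULL, indent = 2L) {
  txt <- mvs_get_state(ref, title, description, description_format, indent)
  writeLines(sub("\n$", "", txt), destination, useBytes = TRUE)
  invisible(destination)
}

#' Convert an alignment 4x4 matrix to rotation and translation vectors
#'
#' Pairwise-superposition services report a 4x4 homogeneous transformation
#' acting on row vectors (`[x 1] \%*\% M`). The first three values of each of
#' the first three rows carry the rotation (which, flattened in that order,
#' is exactly the column-major 3x3 rotation the transform node expects) and
#' the first three values of the fourth row carry the translation. Fourth
#' column values are ignored.
#'
#' @param m 16 numbers in row-major order (values 1-16 as printed), or a
#'   4x4 matrix in the row-vector convention.
#' @return `list(rotation = <9 reals>, translation = <3 reals>)`.
#' @examples
#' convert_alignment_matrix(c(1,0,0,0, 0,1,0,0, 0,0,1,0, 0,0,0,1))
#' @export
convert_alignment_matrix <- function(m) {
  if (is.matrix(m)) {
    if (!all(dim(m) == c(4L, 4L))) mvs_stop("alignment matrix must be 4x4")
    m <- as.double(t(m))  # row-major flattening
  }
  if (!is.numeric(m) || length(m) != 16L) {
    mvs_stop("alignment matrix must have 16 values")
  }
  m <- as.double(m)
  if (max(abs(m[c(4L, 8L, 12L)])) > 1e-9 || abs(m[16L] - 1) > 1e-9) {
    mvs_warn("fourth column of the alignment matrix is expected to be ",
             "(0, 0, 0, 1); ignoring it")
  }
  list(rotation = m[c(1L, 2L, 3L, 5L, 6L, 7L, 9L, 10L, 11L)],
       translation = m[13:15])
}
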