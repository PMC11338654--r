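# ---------------------------------------------------------------------------
# Materializing a state document against structure coordinates: selection
# resolution, rigid-body transforms, assembly expansion, color layering,
# label/tooltip instantiation, and the flat per-atom scene export.
# ---------------------------------------------------------------------------

#' Resolve a selector to an atom index set
#'
#' Named selectors go through [classify_atoms()]; a component expression
#' matches an atom iff every set field matches (`beg_*`/`end_*` ranges are
#' inclusive; unset fields are wildcards); a list of expressions is the
#' union of its members. An empty selection is legal (the caller may attach
#' a diagnostic).
#'
#' @param model a structure model.
#' @param selector named selector string, [mvs_expression()], or list of
#'   expressions.
#' @param classes optional precomputed [classify_atoms()] table.
#' @return sorted integer vector of row indices into `model$atoms`.
#' @export
resolve_selection <- function(model, selector, classes = NULL) {
  stopifnot(inherits(model, "mvs_structure"))
  atoms <- model$atoms
  if (is.character(selector)) {
    if (!is_string(selector) || !(selector %in% named_selectors)) {
      mvs_stop("unknown named selector: ", paste(selector, collapse = ", "))
    }
    if (selector == "all") return(seq_len(nrow(atoms)))
    if (is.null(classes)) classes <- classify_atoms(model)
    return(which(classes[[selector]]))
  }
  if (is_mvs_expression(selector)) {
    return(which(match_expression(atoms, selector)))
  }
  if (is.list(selector)) {
    hits <- lapply(selector, function(e) {
      which(match_expression(atoms, e))
    })
    return(sort(unique(unlist(hits))))
  }
  mvs_stop("invalid selector")
}

match_expression <- function(atoms, expr) {
  if (!is_mvs_expression(expr)) mvs_stop("expected a component expression")
  keep <- rep(TRUE, nrow(atoms))
  eq <- function(colv, value) !is.na(colv) & colv == value
  for (nm in names(expr)) {
    v <- expr[[nm]]
    keep <- keep & switch(nm,
      label_entity_id = eq(atoms$label_entity_id, v),
      label_asym_id = eq(atoms$label_asym_id, v),
      label_seq_id = eq(atoms$label_seq_id, v),
      beg_label_seq_id = !is.na(atoms$label_seq_id) & atoms$label_seq_id >= v,
      end_label_seq_id = !is.na(atoms$label_seq_id) & atoms$label_seq_id <= v,
      label_atom_id = eq(atoms$label_atom_id, v),
      auth_asym_id = eq(atoms$auth_asym_id, v),
      auth_seq_id = eq(atoms$auth_seq_id, v),
      pdbx_PDB_ins_code = eq(atoms$pdbx_PDB_ins_code, v),
      beg_auth_seq_id = !is.na(atoms$auth_seq_id) & atoms$auth_seq_id >= v,
      end_auth_seq_id = !is.na(atoms$auth_seq_id) & atoms$auth_seq_id <= v,
      auth_atom_id = eq(atoms$auth_atom_id, v),
      type_symbol = eq(toupper(atoms$type_symbol), toupper(v)),
      atom_id = eq(atoms$atom_id, v),
      atom_index = eq(atoms$atom_index, v),
      mvs_stop("unknown expression field: ", nm)
    )
  }
  keep
}

#' Apply a rigid-body transform to coordinates
#'
#' `x' = R x + t` per atom, with the rotation decoded column-major
#' (`R[i, j] = rotation[3 (j - 1) + i]`).
#'
#' @param coords n x 3 numeric matrix (Angstrom).
#' @param rotation 9 reals (column-major 3x3); default identity.
#' @param translation 3 reals; default zero.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, rotation = NULL, translation = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) mvs_stop("coords must have 3 columns")
  rotation <- rotation %||% c(1, 0, 0, 0, 1, 0, 0, 0, 1)
  translation <- translation %||% c(0, 0, 0)
  if (!is_number_vec(as.double(rotation), 9L)) {
    mvs_stop("rotation must be 9 finite numbers")
  }
  if (!is_number_vec(as.double(translation), 3L)) {
    mvs_stop("translation must be 3 finite numbers")
  }
  R <- matrix(as.double(rotation), 3L, 3L)
  out <- coords %*% t(R)
  out[, 1] <- out[, 1] + translation[1]
  out[, 2] <- out[, 2] + translation[2]
  out[, 3] <- out[, 3] + translation[3]
  dimnames(out) <- dimnames(coords)
  out
}

# "1,2", "1-60", "(1-60)" -> character operator ids; composed products
# like "(1-60)(61-88)" are not supported
parse_oper_expression <- function(expr, known_ids) {
  if (is.null(expr) || is.na(expr) || !nzchar(expr)) return(known_ids)
  e <- gsub("[[:space:]]", "", expr)
  if (grepl("\\)\\(", e)) {
    mvs_stop("composed assembly operator products are not supported: '",
             expr, "'", class = "mvs_unsupported_error")
  }
  e <- sub("^\\(", "", e)
  e <- sub("\\)$", "", e)
  if (grepl("[()]", e)) {
    mvs_stop("cannot parse assembly operator expression: '", expr, "'",
             class = "mvs_unsupported_error")
  }
  parts <- strsplit(e, ",", fixed = TRUE)[[1]]
  ids <- character(0)
  for (p in parts) {
    if (grepl("^[0-9]+-[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      ids <- c(ids, as.character(seq(ab[1], ab[2])))
    } else {
      ids <- c(ids, p)
    }
  }
  ids
}

#' Expand a biological assembly
#'
#' Replicates the targeted chains under each assembly operator. Copy
#' ordinals and operator ids are recorded in extra atom columns (`copy`,
#' `oper_id`); `atom_index` is re-densified over the expanded set.
#'
#' @param model a structure model.
#' @param assembly_id assembly identifier (usually `"1"`, `"2"`, ...).
#' @return a new structure model containing the expanded atoms.
#' @export
expand_assembly <- function(model, assembly_id) {
  stopifnot(inherits(model, "mvs_structure"))
  gens <- model$assemblies[[assembly_id]]
  if (is.null(gens)) {
    mvs_stop("unknown assembly id '", assembly_id, "'; known: ",
             if (length(model$assemblies)) {
               paste(names(model$assemblies), collapse = ", ")
             } else "none (file defines no assemblies)",
             class = "mvs_lookup_error")
  }
  pieces <- list()
  copy_ord <- 0L
  for (gen in gens) {
    op_ids <- parse_oper_expression(gen$oper_expression, names(model$opers))
    for (oid in op_ids) {
      M <- model$opers[[oid]]
      if (is.null(M)) {
        mvs_stop("assembly references unknown operator '", oid, "'; known: ",
                 paste(names(model$opers), collapse = ", "),
                 class = "mvs_lookup_error")
      }
      sel <- model$atoms$label_asym_id %in% gen$asym_ids
      if (!any(sel)) next
      copy_ord <- copy_ord + 1L
      part <- model$atoms[sel, , drop = FALSE]
      xyz <- apply_transform(as.matrix(part[, c("x", "y", "z")]),
                             rotation = as.vector(M[1:3, 1:3]),
                             translation = M[1:3, 4])
      part$x <- xyz[, 1]; part$y <- xyz[, 2]; part$z <- xyz[, 3]
      part$oper_id <- oid
      part$copy <- copy_ord
      pieces[[length(pieces) + 1L]] <- part
    }
  }
  atoms <- if (length(pieces)) do.call(rbind, pieces) else {
    cbind(empty_atom_table(), oper_id = character(0), copy = integer(0))
  }
  rownames(atoms) <- NULL
  if (nrow(atoms)) {
    atoms$atom_index <- stats::ave(seq_len(nrow(atoms)), atoms$model_num,
                                   FUN = seq_along) - 1L
  }
  new_structure_model(atoms, model$entities, model$assemblies, model$opers,
                      source_text = model$source_text)
}

# consulted independent columns per annotation schema
schema_columns <- list(
  entity = "label_entity_id",
  chain = c("label_entity_id", "label_asym_id"),
  residue = c("label_entity_id", "label_asym_id", "label_seq_id"),
  residue_range = c("label_entity_id", "label_asym_id", "beg_label_seq_id",
                    "end_label_seq_id"),
  atom = c("label_entity_id", "label_asym_id", "label_seq_id",
           "label_atom_id"),
  auth_chain = "auth_asym_id",
  auth_residue = c("auth_asym_id", "auth_seq_id", "pdbx_PDB_ins_code"),
  auth_residue_range = c("auth_asym_id", "beg_auth_seq_id",
                         "end_auth_seq_id"),
  auth_atom = c("auth_asym_id", "auth_seq_id", "pdbx_PDB_ins_code",
                "auth_atom_id"),
  all_atomic = expr_fields
)

#' Turn annotation rows into selection expressions
#'
#' Each row yields one expression consulting only the columns of the given
#' schema; null cells in consulted columns become wildcards (e.g. a
#' chain-schema row with only `label_asym_id` set selects the whole chain).
#'
#' @param rows data.frame of annotation rows (from [filter_rows()]).
#' @param schema one of the annotation schemas (`chain`, `residue_range`,
#'   `auth_atom`, `all_atomic`, ...).
#' @return list of [mvs_expression()] objects, one per row.
#' @export
rows_to_expressions <- function(rows, schema) {
  if (!is_string(schema) || !(schema %in% annotation_schemas)) {
    mvs_stop("unknown annotation schema: ", schema, "; expected one of: ",
             paste(annotation_schemas, collapse = ", "))
  }
  consult <- intersect(schema_columns[[schema]], names(rows))
  lapply(seq_len(nrow(rows)), function(i) {
    vals <- list()
    for (cn in consult) {
      cell <- rows[[cn]][i]
      if (is.na(cell)) next
      if (cn %in% expr_int_fields) {
        iv <- suppressWarnings(as.integer(cell))
        if (is.na(iv)) {
          mvs_stop("row ", i, ": column '", cn, "' value '", cell,
                   "' is not an integer", class = "mvs_parse_error")
        }
        vals[[cn]] <- iv
      } else {
        vals[[cn]] <- cell
      }
    }
    do.call(mvs_expression, vals)
  })
}

#' Layer colors over a component
#'
#' Applies ordered color layers (inline `.color()` calls and annotation
#' rows, in document/file order): each atom ends up with the color of the
#' last layer containing it; atoms covered by no layer stay unset (`NA`).
#' Colors only stick to atoms inside the owning representation's component.
#'
#' @param model a structure model.
#' @param component_atoms integer atom indices of the component.
#' @param layers list of `list(atoms = <indices>, color = <value>)` in
#'   application order.
#' @return character vector over all atoms: assigned color or `NA`.
#' @export
resolve_colors <- function(model, component_atoms, layers) {
  colors <- rep(NA_character_, nrow(model$atoms))
  for (layer in layers) {
    colors[layer$atoms] <- layer$color
  }
  outside <- setdiff(which(!is.na(colors)), component_atoms)
  colors[outside] <- NA_character_
  colors
}

# ---------------------------------------------------------------------------
# Scene flattening
# ---------------------------------------------------------------------------

# read + locate the annotation table addressed by a *_from_* node
load_annotation_table <- function(params, kind, fetcher, source_text) {
  from_source <- grepl("_from_source$", kind)
  if (from_source) {
    if (is.null(source_text)) {
      mvs_stop("cannot read annotations from source: structure text ",
               "unavailable")
    }
    parsed <- parse_annotation_cif(source_text)
  } else {
    bytes <- fetch_resource(fetcher, params$uri)
    parsed <- switch(params$format,
      cif = parse_annotation_cif(ensure_text(bytes)),
      json = parse_annotation_json(ensure_text(bytes)),
      bcif = mvs_stop("BinaryCIF annotations require the delegated codec, ",
                      "which is not available; convert '", params$uri,
                      "' to CIF or JSON", class = "mvs_unsupported_error"),
      mvs_stop("unknown annotation format: ", params$format)
    )
  }
  locate_table(parsed, params$block_header, params$category_name)
}

value_column <- function(table, field_name, default_field) {
  col <- field_name %||% default_field
  if (col %in% independent_columns) {
    mvs_stop("'", col, "' is an independent (selector) column and cannot ",
             "supply values", class = "mvs_lookup_error")
  }
  if (!col %in% names(table$columns)) {
    mvs_stop("value column '", col, "' not present; table columns: ",
             paste(names(table$columns), collapse = ", "),
             class = "mvs_lookup_error")
  }
  col
}

#' Instantiate labels (or tooltips) from annotation rows
#'
#' One instance per row group (see [group_rows()]); the instance's atom set
#' is the union of the group's row selections; groups that select nothing
#' are dropped with a diagnostic.
#'
#' @param model a structure model.
#' @param table an annotation table.
#' @param schema annotation schema for the row selections.
#' @param field_name column holding the text; defaults to `default_field`.
#' @param default_field `"label"` or `"tooltip"`.
#' @return `list(instances = list(list(text, atoms)), diagnostics = chr)`.
#' @export
resolve_labels <- function(model, table, schema, field_name = NULL,
                           default_field = "label") {
  rows <- annotation_rows_df(table)
  col <- value_column(table, field_name, default_field)
  exprs <- rows_to_expressions(rows, schema)
  groups <- group_rows(rows)
  instances <- list()
  diagnostics <- character(0)
  for (g in groups) {
    texts <- unique(stats::na.omit(rows[[col]][g$rows]))
    if (!length(texts)) next
    atoms <- sort(unique(unlist(lapply(g$rows, function(i) {
      resolve_selection(model, exprs[[i]])
    }))))
    if (!length(atoms)) {
      diagnostics <- c(diagnostics, paste0(
        "label group ", if (is.na(g$group_id)) paste0("(row ", g$rows[1], ")")
        else paste0("'", g$group_id, "'"),
        " ('", texts[1], "') selects no atoms; dropped"))
      next
    }
    instances[[length(instances) + 1L]] <- list(text = texts[1],
                                                atoms = atoms)
  }
  list(instances = instances, diagnostics = diagnostics)
}

focus_camera <- function(coords, k = 2.5, axis = c(0, 0, 1)) {
  target <- colMeans(coords)
  radius <- max(sqrt(rowSums(sweep(coords, 2, target)^2)), 1)
  list(target = as.double(target),
       position = as.double(target + k * radius * axis),
       up = c(0, 1, 0))
}

#' Materialize a state document into a resolved scene
#'
#' Walks the tree: downloads are fetched through `fetcher`, coordinates
#' parsed per the parse node, the model or assembly instantiated, transform
#' children applied in document order, components resolved to atom sets,
#' colors layered in document/file order, labels and tooltips instantiated,
#' and the last camera/canvas nodes recorded.
#'
#' @param doc an `mvs_state` document (must validate).
#' @param fetcher a [mvs_fetcher()].
#' @return a `mvs_scene`: structures (atom tables with transformed
#'   coordinates, components, representations with per-atom colors), label
#'   and tooltip instances, camera/canvas settings, and a diagnostics
#'   vector. See [scene_table()] and [scene_summary()] for exports.
#' @export
flatten_scene <- function(doc, fetcher) {
  stopifnot(inherits(doc, "mvs_state"))
  v <- validate_tree(doc)
  verr <- v[v$severity == "error", , drop = FALSE]
  if (nrow(verr)) {
    mvs_stop("document is not valid:\n",
             paste0("  - ", verr$path, ": ", verr$message, collapse = "\n"),
             class = "mvs_validation_error")
  }
  scene <- list(structures = list(), labels = list(), tooltips = list(),
                camera = NULL, canvas = NULL, focus_camera = NULL,
                diagnostics = character(0))
  diag <- function(msg) {
    scene$diagnostics <<- c(scene$diagnostics, msg)
  }
  root_children <- doc$root$children
  for (ci in seq_along(root_children)) {
    node <- root_children[[ci]]
    path <- node_path_label(c("root", node$kind), c(1L, ci))
    if (node$kind == "camera") {
      scene$camera <- node$params
    } else if (node$kind == "canvas") {
      scene$canvas <- node$params
    } else if (node$kind == "download") {
      for (pi in seq_along(node$children)) {
        parse_node <- node$children[[pi]]
        bytes <- fetch_resource(fetcher, node$params$url)
        model0 <- switch(parse_node$params$format,
          mmcif = parse_structure_mmcif(bytes),
          pdb = parse_structure_pdb(bytes),
          bcif = mvs_stop("BinaryCIF structures require the delegated ",
                          "codec, which is not available",
                          class = "mvs_unsupported_error"))
        for (si in seq_along(parse_node$children)) {
          snode <- parse_node$children[[si]]
          spath <- node_path_label(
            c("root", "download", "parse", "structure"),
            c(1L, ci, pi, si))
          st <- resolve_structure_node(snode, model0, spath, fetcher, diag)
          scene$structures[[length(scene$structures) + 1L]] <- st$structure
          for (lb in st$labels) {
            scene$labels[[length(scene$labels) + 1L]] <-
              c(lb, list(structure = length(scene$structures)))
          }
          for (tt in st$tooltips) {
            scene$tooltips[[length(scene$tooltips) + 1L]] <-
              c(tt, list(structure = length(scene$structures)))
          }
          if (!is.null(st$focus_camera)) scene$focus_camera <- st$focus_camera
        }
      }
    }
  }
  structure(scene, class = "mvs_scene")
}

# resolve one structure node and its subtree; returns structure record plus
# collected labels/tooltips
resolve_structure_node <- function(snode, model0, spath, fetcher, diag) {
  # first model only; multi-model selection is out of scope
  first_model <- min(model0$atoms$model_num)
  model <- model0
  model$atoms <- model0$atoms[model0$atoms$model_num == first_model, ,
                              drop = FALSE]
  rownames(model$atoms) <- NULL
  model$atoms$atom_index <- seq_len(nrow(model$atoms)) - 1L
  if (identical(snode$params$type, "assembly")) {
    model <- expand_assembly(model, snode$params$assembly_id)
  }
  # transform children compose in document order
  for (ch in snode$children) {
    if (ch$kind != "transform") next
    xyz <- apply_transform(as.matrix(model$atoms[, c("x", "y", "z")]),
                           rotation = ch$params$rotation,
                           translation = ch$params$translation)
    model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
    model$atoms$z <- xyz[, 3]
  }
  classes <- classify_atoms(model)
  components <- list()
  representations <- list()
  labels <- list()
  tooltips <- list()
  focus_cam <- NULL
  for (ki in seq_along(snode$children)) {
    ch <- snode$children[[ki]]
    cpath <- paste0(spath, "/", ch$kind, "#", ki)
    if (ch$kind == "component") {
      atoms <- resolve_selection(model, ch$params$selector, classes)
      if (!length(atoms)) diag(paste0(cpath, ": component selects no atoms"))
      comp <- list(path = cpath, atoms = atoms)
      components[[length(components) + 1L]] <- comp
      out <- resolve_component_children(ch, comp, model, cpath, fetcher,
                                        diag)
      representations <- c(representations, out$representations)
      labels <- c(labels, out$labels)
      tooltips <- c(tooltips, out$tooltips)
      focus_cam <- out$focus_camera %||% focus_cam
    } else if (ch$kind %in% c("component_from_uri", "component_from_source")) {
      table <- load_annotation_table(ch$params, ch$kind, fetcher,
                                     model$source_text)
      rows <- filter_rows(table, ch$params$field_name,
                          ch$params$field_values,
                          default_field = "component")
      exprs <- rows_to_expressions(rows, ch$params$schema)
      atoms <- sort(unique(unlist(lapply(exprs, function(e) {
        resolve_selection(model, e)
      }))))
      if (!length(atoms)) diag(paste0(cpath, ": component selects no atoms"))
      comp <- list(path = cpath, atoms = atoms)
      components[[length(components) + 1L]] <- comp
      out <- resolve_component_children(ch, comp, model, cpath, fetcher,
                                        diag)
      representations <- c(representations, out$representations)
      labels <- c(labels, out$labels)
      tooltips <- c(tooltips, out$tooltips)
      focus_cam <- out$focus_camera %||% focus_cam
    } else if (ch$kind %in% c("label_from_uri", "label_from_source",
                              "tooltip_from_uri", "tooltip_from_source")) {
      is_label <- startsWith(ch$kind, "label")
      table <- load_annotation_table(ch$params, ch$kind, fetcher,
                                     model$source_text)
      res <- resolve_labels(model, table, ch$params$schema,
                            ch$params$field_name,
                            default_field = if (is_label) "label"
                                            else "tooltip")
      for (d in res$diagnostics) diag(paste0(cpath, ": ", d))
      if (is_label) labels <- c(labels, res$instances)
      else tooltips <- c(tooltips, res$instances)
    }
  }
  list(structure = list(path = spath, model = model, classes = classes,
                        components = components,
                        representations = representations),
       labels = labels, tooltips = tooltips, focus_camera = focus_cam)
}

resolve_component_children <- function(cnode, comp, model, cpath, fetcher,
                                       diag) {
  representations <- list()
  labels <- list()
  tooltips <- list()
  focus_cam <- NULL
  for (ri in seq_along(cnode$children)) {
    ch <- cnode$children[[ri]]
    rpath <- paste0(cpath, "/", ch$kind, "#", ri)
    if (ch$kind == "representation") {
      layers <- list()
      for (li in seq_along(ch$children)) {
        cn <- ch$children[[li]]
        lpath <- paste0(rpath, "/", cn$kind, "#", li)
        if (cn$kind == "color") {
          atoms <- resolve_selection(model, cn$params$selector %||% "all")
          extra <- setdiff(atoms, comp$atoms)
          if (length(extra)) {
            diag(paste0(lpath, ": color selector addresses ", length(extra),
                        " atom(s) outside the component; intersected"))
            atoms <- intersect(atoms, comp$atoms)
          }
          layers[[length(layers) + 1L]] <- list(atoms = atoms,
                                                color = cn$params$color)
        } else if (cn$kind %in% c("color_from_uri", "color_from_source")) {
          table <- load_annotation_table(cn$params, cn$kind, fetcher,
                                         model$source_text)
          col <- value_column(table, cn$params$field_name, "color")
          rows <- annotation_rows_df(table)
          exprs <- rows_to_expressions(rows, cn$params$schema)
          for (i in seq_len(nrow(rows))) {
            val <- rows[[col]][i]
            if (is.na(val)) next
            layers[[length(layers) + 1L]] <- list(
              atoms = intersect(resolve_selection(model, exprs[[i]]),
                                comp$atoms),
              color = val)
          }
        }
      }
      colors <- resolve_colors(model, comp$atoms, layers)
      representations[[length(representations) + 1L]] <-
        list(path = rpath, type = ch$params$type,
             component_path = comp$path, atoms = comp$atoms,
             colors = colors)
    } else if (ch$kind == "label" || ch$kind == "tooltip") {
      if (!length(comp$atoms)) {
        diag(paste0(rpath, ": ", ch$kind, " on empty component; dropped"))
        next
      }
      inst <- list(text = ch$params$text, atoms = comp$atoms)
      if (ch$kind == "label") labels[[length(labels) + 1L]] <- inst
      else tooltips[[length(tooltips) + 1L]] <- inst
    } else if (ch$kind == "focus") {
      if (length(comp$atoms)) {
        coords <- as.matrix(model$atoms[comp$atoms, c("x", "y", "z"),
                                        drop = FALSE])
        focus_cam <- focus_camera(coords)
      } else {
        diag(paste0(rpath, ": focus on empty component; ignored"))
      }
    }
  }
  list(representations = representations, labels = labels,
       tooltips = tooltips, focus_camera = focus_cam)
}

#' Flat per-atom table of a resolved scene
#'
#' @param scene an `mvs_scene` from [flatten_scene()].
#' @return data.frame, one row per atom over all structures: structure
#'   ordinal, identifiers, transformed coordinates, semicolon-joined
#'   component paths, final color (last covering representation layer) and
#'   joined tooltip texts.
#' @export
scene_table <- function(scene) {
  stopifnot(inherits(scene, "mvs_scene"))
  out <- list()
  for (si in seq_along(scene$structures)) {
    st <- scene$structures[[si]]
    atoms <- st$model$atoms
    n <- nrow(atoms)
    comp_paths <- rep("", n)
    for (comp in st$components) {
      comp_paths[comp$atoms] <- ifelse(
        nzchar(comp_paths[comp$atoms]),
        paste0(comp_paths[comp$atoms], ";", comp$path), comp$path)
    }
    color <- rep(NA_character_, n)
    for (rep_ in st$representations) {
      set <- !is.na(rep_$colors)
      color[set] <- rep_$colors[set]
    }
    tooltip <- rep(NA_character_, n)
    for (tt in scene$tooltips) {
      if (!identical(tt$structure, si)) next
      tooltip[tt$atoms] <- ifelse(is.na(tooltip[tt$atoms]), tt$text,
                                  paste0(tooltip[tt$atoms], "; ", tt$text))
    }
    out[[si]] <- data.frame(
      structure = si,
      atom_index = atoms$atom_index, atom_id = atoms$atom_id,
      label_asym_id = atoms$label_asym_id, comp_id = atoms$comp_id,
      label_seq_id = atoms$label_seq_id,
      label_atom_id = atoms$label_atom_id,
      auth_asym_id = atoms$auth_asym_id, auth_seq_id = atoms$auth_seq_id,
      x = atoms$x, y = atoms$y, z = atoms$z,
      components = comp_paths, color = color, tooltip = tooltip,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(structure = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' JSON-ready summary of a resolved scene
#'
#' @param scene an `mvs_scene`.
#' @return list with structure/component/representation counts, label and
#'   tooltip instance counts, camera/canvas settings and diagnostics.
#' @export
scene_summary <- function(scene) {
  stopifnot(inherits(scene, "mvs_scene"))
  list(
    n_structures = length(scene$structures),
    n_atoms = sum(vapply(scene$structures,
                         function(s) nrow(s$model$atoms), integer(1))),
    n_components = sum(vapply(scene$structures,
                              function(s) length(s$components), integer(1))),
    n_representations = sum(vapply(scene$structures,
                                   function(s) length(s$representations),
                                   integer(1))),
    n_labels = length(scene$labels),
    n_tooltips = length(scene$tooltips),
    camera = scene$camera,
    canvas = scene$canvas,
    diagnostics = scene$diagnostics
  )
}
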