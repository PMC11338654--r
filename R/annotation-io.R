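# ---------------------------------------------------------------------------
# Annotation tables: named column stores whose independent-variable columns
# select substructures and whose dependent-variable columns assign values
# (component names, colors, labels, tooltips).
# ---------------------------------------------------------------------------

# predefined independent-variable columns of an annotation row
independent_columns <- c(expr_fields, "group_id")

#' Read annotation tables from CIF text
#'
#' Parses the CIF subset used for annotations: `data_` blocks, `loop_`
#' categories, quoted values (quotes keep internal spaces), `.` / `?`
#' nulls and `#` comments. Row order is preserved; category names must be
#' unique within a block.
#'
#' @param text CIF text (a single string).
#' @return a list of blocks, each `list(block_header, tables)` where
#'   `tables` is a named list of annotation tables
#'   (`list(block_header, category_name, columns, n_rows)`; columns are
#'   character vectors with `NA` for null cells).
#' @seealso [locate_table()], [write_annotation_cif()]
#' @export
parse_annotation_cif <- function(text) {
  blocks <- cif_read_blocks(text)
  if (!length(blocks)) mvs_stop("no data_ block found",
                                class = "mvs_cif_error")
  blocks
}

#' Read an annotation table from JSON text
#'
#' Accepts either an array of row objects (missing keys become null cells)
#' or an object of equal-length column arrays. JSON can carry a single
#' table only, so the result has no block or category address.
#'
#' @param text JSON text.
#' @return an annotation table (as in [parse_annotation_cif()]).
#' @export
parse_annotation_json <- function(text) {
  x <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                error = function(e) {
                  mvs_stop("malformed annotation JSON: ",
                           conditionMessage(e), class = "mvs_parse_error")
                })
  as_cell <- function(v, where) {
    if (is.null(v)) return(NA_character_)
    if (is.list(v) || length(v) != 1L) {
      mvs_stop(where, ": cell values must be scalars",
               class = "mvs_parse_error")
    }
    if (is.logical(v)) return(tolower(as.character(v)))
    if (is.numeric(v)) return(json_number(v))
    as.character(v)
  }
  if (is.list(x) && is.null(names(x))) {
    # array of row objects
    cols <- character(0)
    for (i in seq_along(x)) {
      row <- x[[i]]
      if (!is.list(row) || (length(row) && is.null(names(row)))) {
        mvs_stop("row ", i, ": expected a JSON object per row",
                 class = "mvs_parse_error")
      }
      cols <- union(cols, names(row))
    }
    columns <- stats::setNames(lapply(cols, function(cn) {
      vapply(seq_along(x), function(i) {
        as_cell(x[[i]][[cn]], paste0("row ", i, ", column '", cn, "'"))
      }, character(1))
    }), cols)
    return(new_annotation_table(NULL, columns))
  }
  if (is.list(x)) {
    # object of column arrays
    columns <- lapply(names(x), function(cn) {
      col <- x[[cn]]
      if (!is.list(col)) col <- as.list(col)
      vapply(seq_along(col), function(i) {
        as_cell(col[[i]], paste0("column '", cn, "', row ", i))
      }, character(1))
    })
    names(columns) <- names(x)
    lens <- lengths(columns)
    if (length(unique(lens)) > 1L) {
      mvs_stop("column arrays have differing lengths: ",
               paste(paste0(names(columns), "=", lens), collapse = ", "),
               class = "mvs_parse_error")
    }
    return(new_annotation_table(NULL, columns))
  }
  mvs_stop("annotation JSON must be an array of rows or an object of columns",
           class = "mvs_parse_error")
}

#' Pick one annotation table out of parsed CIF blocks
#'
#' @param parsed result of [parse_annotation_cif()], or a single annotation
#'   table (returned unchanged; JSON files hold one table only).
#' @param block_header,category_name exact-match address; when omitted the
#'   first category of the first block is used.
#' @return an annotation table.
#' @export
locate_table <- function(parsed, block_header = NULL, category_name = NULL) {
  if (inherits(parsed, "mvs_annotation_table")) return(parsed)
  stopifnot(is.list(parsed), length(parsed) >= 1L)
  headers <- vapply(parsed, function(b) b$block_header %||% "", character(1))
  if (is.null(block_header)) {
    block <- parsed[[1]]
  } else {
    hit <- which(headers == block_header)
    if (!length(hit)) {
      mvs_stop("block '", block_header, "' not found; available blocks: ",
               paste(headers, collapse = ", "), class = "mvs_lookup_error")
    }
    block <- parsed[[hit[1]]]
  }
  if (!length(block$tables)) {
    mvs_stop("block '", block$block_header %||% "", "' holds no categories",
             class = "mvs_lookup_error")
  }
  if (is.null(category_name)) return(block$tables[[1]])
  if (!category_name %in% names(block$tables)) {
    mvs_stop("category '", category_name, "' not found; available: ",
             paste(names(block$tables), collapse = ", "),
             class = "mvs_lookup_error")
  }
  block$tables[[category_name]]
}

annotation_rows_df <- function(table) {
  cols <- table$columns
  if (!length(cols)) {
    return(data.frame(row.names = seq_len(table$n_rows)))
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE,
                      optional = TRUE)
  names(df) <- names(cols)
  df
}

#' Select annotation rows by a column filter
#'
#' Keeps the rows whose cell in `field_name` (or `default_field` when
#' `field_name` is omitted) is one of `field_values`. With `field_values`
#' omitted all rows are kept. Row order is preserved.
#'
#' @param table an annotation table.
#' @param field_name filter column; defaults to `default_field`.
#' @param field_values character vector (a scalar is a singleton set).
#' @param default_field column assumed when `field_name` is missing
#'   (`"component"` for component annotations).
#' @return data.frame of the kept rows (character columns, `NA` = null).
#' @export
filter_rows <- function(table, field_name = NULL, field_values = NULL,
                        default_field = "component") {
  stopifnot(inherits(table, "mvs_annotation_table"))
  df <- annotation_rows_df(table)
  if (is.null(field_values)) return(df)
  col <- field_name %||% default_field
  if (!col %in% names(df)) {
    mvs_stop("filter column '", col, "' not present; table columns: ",
             paste(names(df), collapse = ", "), class = "mvs_lookup_error")
  }
  keep <- !is.na(df[[col]]) & df[[col]] %in% as.character(field_values)
  df[keep, , drop = FALSE]
}

#' Group annotation rows by group_id
#'
#' Rows sharing a non-null `group_id` merge into one group (one label
#' instance); rows with a null `group_id` — or all rows when the column is
#' absent — each form their own group. Values compare as text (`"1"` and
#' `"01"` differ). Group order is first-appearance order.
#'
#' @param rows data.frame of annotation rows (as from [filter_rows()]).
#' @return list of groups: `list(group_id = <chr or NA>, rows = <integer
#'   indices into `rows`>)`.
#' @export
group_rows <- function(rows) {
  stopifnot(is.data.frame(rows))
  n <- nrow(rows)
  if (!n) return(list())
  gid <- if ("group_id" %in% names(rows)) rows$group_id
         else rep(NA_character_, n)
  groups <- list()
  index_of <- character(0)  # group_id -> position, for non-null ids
  for (i in seq_len(n)) {
    g <- gid[i]
    if (!is.na(g) && g %in% names(index_of)) {
      at <- as.integer(index_of[[g]])
      groups[[at]]$rows <- c(groups[[at]]$rows, i)
    } else {
      groups[[length(groups) + 1L]] <- list(group_id = g, rows = i)
      if (!is.na(g)) index_of[[g]] <- length(groups)
    }
  }
  groups
}

#' Write annotation tables as CIF text
#'
#' Inverse of [parse_annotation_cif()]: null cells become `.`, values with
#' spaces or special characters are quoted, block headers must be unique.
#'
#' @param blocks list of blocks as returned by [parse_annotation_cif()]
#'   (a single annotation table is also accepted and wrapped in one block).
#' @return CIF text.
#' @export
write_annotation_cif <- function(blocks) {
  if (inherits(blocks, "mvs_annotation_table")) {
    blocks <- list(list(block_header = blocks$block_header %||% "annotations",
                        tables = stats::setNames(list(blocks),
                                                 blocks$category_name %||%
                                                   "annotations")))
  }
  headers <- vapply(blocks, function(b) b$block_header %||% "", character(1))
  if (anyDuplicated(headers)) {
    mvs_stop("duplicate block header(s): ",
             paste(unique(headers[duplicated(headers)]), collapse = ", "),
             class = "mvs_cif_error")
  }
  out <- character(0)
  for (b in blocks) {
    out <- c(out, paste0("data_", b$block_header %||% ""))
    for (nm in names(b$tables)) {
      tab <- b$tables[[nm]]
      cat_name <- tab$category_name %||% nm
      out <- c(out, "#", "loop_",
               paste0("_", cat_name, ".", names(tab$columns)))
      if (tab$n_rows > 0L) {
        cells <- vapply(names(tab$columns), function(cn) {
          vapply(tab$columns[[cn]], cif_format_cell, character(1),
                 USE.NAMES = FALSE)
        }, character(tab$n_rows))
        if (tab$n_rows == 1L) cells <- matrix(cells, nrow = 1L)
        out <- c(out, apply(cells, 1L, paste, collapse = " "))
      }
    }
    out <- c(out, "#")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Write an annotation table as JSON text
#'
#' Emits an array of row objects; null cells become JSON `null`.
#'
#' @param table an annotation table.
#' @param indent spaces per nesting level.
#' @return JSON text.
#' @export
write_annotation_json <- function(table, indent = 2L) {
  stopifnot(inherits(table, "mvs_annotation_table"))
  df <- annotation_rows_df(table)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, , drop = FALSE])
    lapply(row, function(v) if (is.na(v)) NULL else v)
  })
  paste0(jsonlite::toJSON(rows, auto_unbox = TRUE, null = "null",
                          pretty = indent), "\n")
}
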