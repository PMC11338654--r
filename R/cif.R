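# ---------------------------------------------------------------------------
# Tokenizer and block/category reader for the CIF subset used by annotation
# files and by the mmCIF structure reader: data_ blocks, loop_ categories,
# key-value pairs, single-/double-quoted values, "." / "?" nulls, # comments.
# Multi-line semicolon text fields are not part of the subset.
# ---------------------------------------------------------------------------

cif_tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  values <- character(0); quoted <- logical(0); linenos <- integer(0)
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (startsWith(line, ";")) {
      mvs_stop("line ", ln, ": multi-line semicolon text fields are not ",
               "supported by this reader; see the CIF specification ",
               "(https://www.iucr.org/resources/cif) for their syntax",
               class = "mvs_cif_error")
    }
    pos <- 1L
    n <- nchar(line)
    while (pos <= n) {
      rest <- substr(line, pos, n)
      ws <- regmatches(rest, regexpr("^[ \t\r]+", rest))
      if (length(ws)) {
        pos <- pos + nchar(ws)
        next
      }
      rest <- substr(line, pos, n)
      if (!nzchar(rest)) break
      first <- substr(rest, 1L, 1L)
      if (first == "#") break  # comment to end of line
      if (first == "'" || first == '"') {
        pat <- if (first == "'") "^'([^']*)'([ \t\r]|$)" else
          '^"([^"]*)"([ \t\r]|$)'
        m <- regexec(pat, rest)[[1]]
        if (m[1] == -1L) {
          mvs_stop("line ", ln, ": unterminated quoted value",
                   class = "mvs_cif_error")
        }
        len <- attr(m, "match.length")[2]
        tok <- substr(rest, 2L, 1L + len)
        values <- c(values, tok); quoted <- c(quoted, TRUE)
        linenos <- c(linenos, ln)
        pos <- pos + len + 2L
      } else {
        m <- regexpr("^[^ \t\r]+", rest)
        len <- attr(m, "match.length")
        tok <- substr(rest, 1L, len)
        values <- c(values, tok); quoted <- c(quoted, FALSE)
        linenos <- c(linenos, ln)
        pos <- pos + len
      }
    }
  }
  list(value = values, quoted = quoted, line = linenos)
}

new_annotation_table <- function(category_name, columns, block_header = NULL) {
  n <- if (length(columns)) length(columns[[1]]) else 0L
  structure(list(block_header = block_header, category_name = category_name,
                 columns = columns, n_rows = n),
            class = "mvs_annotation_table")
}

# Reads the full block/category structure. Returns
# list of list(block_header = chr, tables = named list of tables).
cif_read_blocks <- function(text) {
  tk <- cif_tokenize(text)
  n <- length(tk$value)
  blocks <- list()
  cur_header <- NULL
  cur_cats <- list()       # name -> list(cols = chr vec, cells = list of chr vec)
  cat_order <- character(0)
  flush_block <- function() {
    if (is.null(cur_header) && !length(cat_order)) return()
    tables <- list()
    for (nm in cat_order) {
      cc <- cur_cats[[nm]]
      cols <- stats::setNames(cc$cells, cc$cols)
      tables[[nm]] <- new_annotation_table(nm, cols, cur_header)
    }
    blocks[[length(blocks) + 1L]] <<- list(block_header = cur_header,
                                           tables = tables)
  }
  split_tag <- function(tag, ln) {
    m <- regmatches(tag, regexec("^_([^.]+)\\.(.+)$", tag))[[1]]
    if (length(m) != 3L) {
      mvs_stop("line ", ln, ": malformed data name '", tag,
               "' (expected _category.column)", class = "mvs_cif_error")
    }
    m[2:3]
  }
  decode_cell <- function(value, quoted) {
    if (!quoted && (value == "." || value == "?")) NA_character_ else value
  }
  add_category <- function(cat, cols, cells, ln) {
    if (cat %in% names(cur_cats)) {
      mvs_stop("line ", ln, ": duplicate category '", cat, "' in block",
               if (!is.null(cur_header)) paste0(" '", cur_header, "'"),
               class = "mvs_cif_error")
    }
    cur_cats[[cat]] <<- list(cols = cols, cells = cells)
    cat_order <<- c(cat_order, cat)
  }
  i <- 1L
  while (i <= n) {
    v <- tk$value[i]; q <- tk$quoted[i]; ln <- tk$line[i]
    if (!q && grepl("^data_", v, ignore.case = TRUE)) {
      flush_block()
      cur_header <- substring(v, 6L)
      cur_cats <- list(); cat_order <- character(0)
      i <- i + 1L
    } else if (!q && tolower(v) == "loop_") {
      i <- i + 1L
      cols <- character(0); cats <- character(0)
      while (i <= n && !tk$quoted[i] && startsWith(tk$value[i], "_")) {
        parts <- split_tag(tk$value[i], tk$line[i])
        cats <- c(cats, parts[1]); cols <- c(cols, parts[2])
        i <- i + 1L
      }
      if (!length(cols)) {
        mvs_stop("line ", ln, ": loop_ without column definitions",
                 class = "mvs_cif_error")
      }
      if (length(unique(cats)) != 1L) {
        mvs_stop("line ", ln, ": loop_ mixes categories: ",
                 paste(unique(cats), collapse = ", "),
                 class = "mvs_cif_error")
      }
      vals <- character(0)
      last_ln <- ln
      while (i <= n && (tk$quoted[i] ||
                        !grepl("^(_|data_|loop_)", tk$value[i],
                               ignore.case = TRUE))) {
        vals <- c(vals, decode_cell(tk$value[i], tk$quoted[i]))
        last_ln <- tk$line[i]
        i <- i + 1L
      }
      k <- length(cols)
      if (length(vals) %% k != 0L) {
        mvs_stop("line ", last_ln, ": ragged loop for category '", cats[1],
                 "': ", length(vals), " cells do not fill rows of ", k,
                 " columns", class = "mvs_cif_error")
      }
      nr <- length(vals) %/% k
      cells <- lapply(seq_len(k), function(j) vals[seq(j, by = k,
                                                       length.out = nr)])
      add_category(cats[1], cols, cells, ln)
    } else if (!q && startsWith(v, "_")) {
      # key-value pair outside a loop: one-row category, possibly built up
      # over several consecutive tags
      parts <- split_tag(v, ln)
      if (i + 1L > n) {
        mvs_stop("line ", ln, ": data name '", v, "' without a value",
                 class = "mvs_cif_error")
      }
      cell <- decode_cell(tk$value[i + 1L], tk$quoted[i + 1L])
      cat <- parts[1]
      if (cat %in% names(cur_cats) && cat != cat_order[length(cat_order)]) {
        mvs_stop("line ", ln, ": duplicate category '", cat, "' in block",
                 class = "mvs_cif_error")
      }
      if (cat %in% names(cur_cats)) {
        cur_cats[[cat]]$cols <- c(cur_cats[[cat]]$cols, parts[2])
        cur_cats[[cat]]$cells <- c(cur_cats[[cat]]$cells, list(cell))
      } else {
        cur_cats[[cat]] <- list(cols = parts[2], cells = list(cell))
        cat_order <- c(cat_order, cat)
      }
      i <- i + 2L
    } else {
      mvs_stop("line ", ln, ": unexpected value '", v,
               "' outside any category", class = "mvs_cif_error")
    }
  }
  flush_block()
  blocks
}

cif_needs_quoting <- function(v) {
  grepl("[ \t']", v) | v %in% c(".", "?", "") |
    grepl("^(_|#|\\$|'|\"|;|\\[|\\])", v) |
    grepl("^(data_|loop_|save_|stop_|global_)", v, ignore.case = TRUE)
}

cif_format_cell <- function(v) {
  if (is.na(v)) return(".")
  if (!cif_needs_quoting(v)) return(v)
  if (!grepl("'", v, fixed = TRUE)) return(paste0("'", v, "'"))
  if (!grepl('"', v, fixed = TRUE)) return(paste0('"', v, '"'))
  mvs_stop("cannot write value containing both quote characters: ", v,
           class = "mvs_cif_error")
}
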