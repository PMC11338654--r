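test_that("the worked-example components category parses as printed", {
  blocks <- sp2_blocks()
  expect_length(blocks, 1L)
  expect_identical(blocks[[1]]$block_header, "1h9t_annotations")
  comp <- locate_table(blocks, "1h9t_annotations", "components")
  expect_identical(comp$n_rows, 9L)
  expect_length(comp$columns, 2L)
  expect_identical(names(comp$columns), c("label_asym_id", "component"))
  expect_identical(length(unique(comp$columns$component)), 4L)
})

test_that("quoting keeps internal spaces and '.' cells become null", {
  ann <- locate_table(sp2_blocks(), category_name = "annotations")
  expect_identical(ann$n_rows, 22L)
  expect_length(ann$columns, 6L)
  rowC <- which(ann$columns$label_asym_id == "C")
  expect_identical(ann$columns$label[rowC], "DNA X")
  expect_true(is.na(ann$columns$beg_label_seq_id[rowC]))
  expect_identical(sum(ann$columns$label == "Ligand binding site"), 11L)
})

test_that("a minimal one-value file parses to one block/table/row", {
  blocks <- parse_annotation_cif("data_x\nloop_\n_t.a\n1\n")
  expect_length(blocks, 1L)
  tab <- locate_table(blocks)
  expect_identical(tab$category_name, "t")
  expect_identical(tab$n_rows, 1L)
  expect_identical(tab$columns$a, "1")
})

test_that("ragged loops and duplicate categories are parse errors", {
  ragged <- "data_x\nloop_\n_t.a\n_t.b\n1 2\n3\n"
  expect_error(parse_annotation_cif(ragged), "line 6.*ragged")
  dup <- "data_x\nloop_\n_t.a\n1\nloop_\n_t.a\n2\n"
  expect_error(parse_annotation_cif(dup), "duplicate category")
  expect_error(parse_annotation_cif("data_x\n;multi\n;\n"), "semicolon")
})

test_that("whitespace amount between cells is irrelevant", {
  a <- parse_annotation_cif("data_x\nloop_\n_t.a\n_t.b\n1 2\n")
  b <- parse_annotation_cif("data_x\nloop_\n_t.a\n_t.b\n  1\t   2  \n")
  expect_identical(locate_table(a)$columns, locate_table(b)$columns)
})

test_that("JSON rows, JSON columns and CIF parse to cell-identical tables", {
  comp_cif <- locate_table(sp2_blocks(), category_name = "components")
  path <- system.file("extdata", "annotations-1h9t-components.json",
                      package = "mvspec")
  comp_rows <- parse_annotation_json(paste(readLines(path), collapse = "\n"))
  expect_identical(comp_rows$columns, comp_cif$columns)
  comp_cols <- parse_annotation_json(jsonlite::toJSON(
    lapply(comp_cif$columns, as.list), auto_unbox = TRUE))
  expect_identical(comp_cols$columns, comp_cif$columns)
})

test_that("JSON edge cases: empty array, missing keys, bad shapes", {
  expect_identical(parse_annotation_json("[]")$n_rows, 0L)
  tab <- parse_annotation_json('[{"a": "1", "b": "x"}, {"a": "2"}]')
  expect_identical(tab$columns$b, c("x", NA_character_))
  expect_error(parse_annotation_json('[{"a": 1}, ["not", "object"]]'),
               "object")
  expect_error(parse_annotation_json('{"a": ["1"], "b": ["1", "2"]}'),
               "differing lengths")
})

test_that("locate_table defaults to first category and errors list names", {
  blocks <- sp2_blocks()
  expect_identical(locate_table(blocks)$category_name, "components")
  expect_error(locate_table(blocks, category_name = "nope"),
               "components, annotations")
  expect_error(locate_table(blocks, block_header = "missing"),
               "1h9t_annotations")
})

test_that("filter_rows selects by value set, defaulting to 'component'", {
  comp <- locate_table(sp2_blocks(), category_name = "components")
  expect_identical(filter_rows(comp, "component", "Protein")$label_asym_id,
                   c("A", "B"))
  # field_name omitted: the 'component' column is assumed
  ions <- filter_rows(comp, field_values = c("Gold", "Chloride"))
  expect_identical(ions$label_asym_id, c("E", "H", "F", "G", "I"))
  expect_identical(nrow(filter_rows(comp)), 9L)
  expect_error(filter_rows(comp, "shade", "x"), "not present")
})

test_that("group_rows merges by group_id and keeps null rows separate", {
  ann <- locate_table(sp2_blocks(), category_name = "annotations")
  rows <- filter_rows(ann, "label", "Ligand binding site")
  groups <- group_rows(rows)
  expect_length(groups, 4L)
  expect_identical(vapply(groups, function(g) length(g$rows), integer(1)),
                   c(2L, 4L, 1L, 4L))
  chl <- group_rows(filter_rows(ann, "label", "Chloride"))
  expect_length(chl, 3L)
  expect_length(group_rows(filter_rows(ann, "label", character(0))), 0L)
})

test_that("group_rows partitions its input", {
  ann <- locate_table(sp2_blocks(), category_name = "annotations")
  rows <- filter_rows(ann)
  groups <- group_rows(rows)
  expect_length(groups, 15L)  # 11 null-group singletons + groups 1-4
  all_rows <- sort(unlist(lapply(groups, `[[`, "rows")))
  expect_identical(all_rows, seq_len(nrow(rows)))
})

test_that("CIF writing round-trips the worked-example tables", {
  blocks <- sp2_blocks()
  txt <- write_annotation_cif(blocks)
  expect_match(txt, "'Ligand binding site'", fixed = TRUE)
  reparsed <- parse_annotation_cif(txt)
  for (cat_name in c("components", "annotations")) {
    expect_identical(locate_table(reparsed, category_name = cat_name),
                     locate_table(blocks, category_name = cat_name))
  }
})

test_that("CIF writer quotes spaced values and emits '.' for null", {
  tab <- mvspec:::new_annotation_table(
    "t", list(a = c("plain", "has space", NA)), "blk")
  txt <- write_annotation_cif(list(list(block_header = "blk",
                                        tables = list(t = tab))))
  lines <- strsplit(txt, "\n")[[1]]
  expect_true("'has space'" %in% lines)
  expect_true("." %in% lines)
  dup <- list(list(block_header = "b", tables = list()),
              list(block_header = "b", tables = list()))
  expect_error(write_annotation_cif(dup), "duplicate block header")
})

test_that("JSON writing round-trips cell-wise", {
  comp <- locate_table(sp2_blocks(), category_name = "components")
  again <- parse_annotation_json(write_annotation_json(comp))
  expect_identical(again$columns, comp$columns)
  ann <- locate_table(sp2_blocks(), category_name = "annotations")
  again2 <- parse_annotation_json(write_annotation_json(ann))
  expect_identical(again2$columns, ann$columns)
})
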