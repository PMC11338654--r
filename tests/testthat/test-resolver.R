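test_that("named selectors and AND-expressions resolve as defined", {
  model <- toy_mixed_model()
  n <- nrow(model$atoms)
  expect_identical(resolve_selection(model, "all"), seq_len(n))
  expect_identical(resolve_selection(model, "water"),
                   which(model$atoms$comp_id == "HOH"))
  fe <- resolve_selection(model, mvs_expression(label_asym_id = "E",
                                                label_atom_id = "FE"))
  expect_length(fe, 1L)
  expect_identical(model$atoms$label_atom_id[fe], "FE")
  # list = union; "all" contains everything
  lst <- resolve_selection(model, list(
    mvs_expression(label_asym_id = "A"), mvs_expression(label_asym_id = "B")))
  expect_identical(lst, which(model$atoms$label_asym_id %in% c("A", "B")))
  expect_true(all(lst %in% resolve_selection(model, "all")))
  # empty selection is legal
  expect_length(resolve_selection(model, mvs_expression(label_asym_id = "Z")),
                0L)
})

test_that("expression resolution equals an exhaustive per-atom scan", {
  set.seed(31)
  model <- toy_mixed_model()
  for (i in seq_len(300L)) {
    expr <- random_expression()
    expect_identical(resolve_selection(model, expr),
                     which(oracle_match_expression(model$atoms, expr)))
  }
})

test_that("apply_transform is x' = R x + t with column-major rotation", {
  pts <- matrix(c(0, 0, 0, 1, 2, 3), ncol = 3, byrow = TRUE)
  expect_equal(apply_transform(pts), pts)
  expect_equal(apply_transform(pts, translation = c(1, 2, 3))[1, ],
               c(1, 2, 3))
  # 90-degree rotation about z, column-major: columns (0,1,0),(-1,0,0),(0,0,1)
  rot_z <- c(0, 1, 0, -1, 0, 0, 0, 0, 1)
  expect_equal(apply_transform(matrix(c(1, 0, 0), 1), rot_z),
               matrix(c(0, 1, 0), 1))
  expect_error(apply_transform(pts, rotation = 1:4), "9 finite")
})

test_that("the printed superposition vectors match homogeneous multiplication", {
  set.seed(5)
  m <- alignment_matrix_1oj6_5mjd()
  conv <- convert_alignment_matrix(m)
  M <- matrix(m, 4, 4, byrow = TRUE)
  pts <- matrix(stats::rnorm(60, sd = 20), ncol = 3)
  expect_equal(apply_transform(pts, conv$rotation, conv$translation),
               (cbind(pts, 1) %*% M)[, 1:3], tolerance = 1e-12)
})

test_that("the printed rotation is orthonormal with determinant one", {
  conv <- convert_alignment_matrix(alignment_matrix_1oj6_5mjd())
  R <- matrix(conv$rotation, 3, 3)
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-3)
  expect_lt(abs(det(R) - 1), 1e-3)
})

test_that("transforms preserve pairwise distances for orthonormal rotations", {
  set.seed(13)
  pts <- matrix(stats::rnorm(45), ncol = 3)
  for (i in 1:10) {
    R <- random_proper_rotation()
    out <- apply_transform(pts, as.vector(R), stats::rnorm(3))
    expect_equal(as.vector(dist(out)), as.vector(dist(pts)),
                 tolerance = 1e-9)
  }
})

test_that("assembly expansion replicates chains per operator", {
  ident <- list(rotation = c(diag(3)), translation = c(0, 0, 0))
  shift <- list(rotation = c(diag(3)), translation = c(0, 0, 25))
  spec <- toy_spec(
    list(list(label_asym_id = "A", kind = "protein", n_residues = 4L)),
    assemblies = list("1" = list(operators = list(ident)),
                      "2" = list(operators = list(ident, shift))))
  model <- parse_structure_mmcif(make_toy_structure(spec)$mmcif)
  a1 <- expand_assembly(model, "1")
  expect_identical(nrow(a1$atoms), nrow(model$atoms))
  expect_equal(a1$atoms$z, model$atoms$z)
  a2 <- expand_assembly(model, "2")
  expect_identical(nrow(a2$atoms), 2L * nrow(model$atoms))
  expect_identical(unique(a2$atoms$copy), c(1L, 2L))
  expect_identical(a2$atoms$atom_index, 0:(nrow(a2$atoms) - 1L))
  expect_error(expand_assembly(model, "9"), "known: 1, 2")
})

test_that("expanded copies equal direct homogeneous application", {
  set.seed(17)
  R <- random_proper_rotation()
  t3 <- c(4, -2, 7)
  op <- list(rotation = as.vector(round(R, 3)), translation = t3)
  spec <- toy_spec(
    list(list(label_asym_id = "A", kind = "protein", n_residues = 5L)),
    assemblies = list("1" = list(operators = list(op))))
  model <- parse_structure_mmcif(make_toy_structure(spec)$mmcif)
  ex <- expand_assembly(model, "1")
  M <- model$opers[["1"]]
  direct <- t(M %*% rbind(t(as.matrix(model$atoms[, c("x", "y", "z")])), 1))
  expect_equal(as.matrix(ex$atoms[, c("x", "y", "z")]),
               direct[, 1:3], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("operator expressions support lists and ranges but not products", {
  expect_identical(mvspec:::parse_oper_expression("1,2", c("1", "2", "3")),
                   c("1", "2"))
  expect_identical(mvspec:::parse_oper_expression("1-4", as.character(1:4)),
                   as.character(1:4))
  expect_identical(mvspec:::parse_oper_expression("(1-2)", c("1", "2")),
                   c("1", "2"))
  expect_error(mvspec:::parse_oper_expression("(1-60)(61-88)", "1"),
               "not supported")
})

test_that("annotation rows become schema-scoped expressions", {
  blocks <- sp2_blocks()
  comp <- locate_table(blocks, category_name = "components")
  rows <- filter_rows(comp, "component", "Protein")
  exprs <- rows_to_expressions(rows, "chain")
  expect_identical(exprs[[1]], mvs_expression(label_asym_id = "A"))
  ann <- locate_table(blocks, category_name = "annotations")
  r1 <- rows_to_expressions(filter_rows(ann), "residue_range")[[1]]
  expect_identical(r1, mvs_expression(label_asym_id = "A",
                                      beg_label_seq_id = 9L,
                                      end_label_seq_id = 83L))
  # null consulted columns are wildcards: chain C row selects whole chain
  rC <- rows_to_expressions(filter_rows(ann), "residue_range")[[5]]
  expect_identical(rC, mvs_expression(label_asym_id = "C"))
  # all consulted columns null -> match-all
  tab <- mvspec:::new_annotation_table("t", list(label_asym_id = NA_character_))
  all_expr <- rows_to_expressions(filter_rows(tab), "chain")[[1]]
  expect_length(names(all_expr), 0L)
  expect_error(rows_to_expressions(
    data.frame(beg_label_seq_id = "abc", stringsAsFactors = FALSE),
    "residue_range"), "not an integer")
})

test_that("the last covering color layer wins (red 1-100 then blue 100-120)", {
  spec <- toy_spec(list(list(label_asym_id = "A", kind = "protein",
                             n_residues = 130L)))
  model <- parse_structure_mmcif(make_toy_structure(spec)$mmcif)
  sel <- function(b, e) resolve_selection(
    model, mvs_expression(beg_label_seq_id = b, end_label_seq_id = e))
  comp <- resolve_selection(model, "all")
  colors <- resolve_colors(model, comp, list(
    list(atoms = sel(1, 100), color = "red"),
    list(atoms = sel(100, 120), color = "blue")))
  at <- function(seq) colors[model$atoms$label_seq_id == seq]
  expect_identical(at(99), "red")
  expect_identical(at(100), "blue")
  expect_identical(at(120), "blue")
  expect_identical(at(121), NA_character_)
})

test_that("a single all-covering layer colors every atom; outside atoms stay unset", {
  model <- toy_mixed_model()
  all_idx <- resolve_selection(model, "all")
  colors <- resolve_colors(model, all_idx,
                           list(list(atoms = all_idx, color = "white")))
  expect_true(all(colors == "white"))
  # colors never leak outside the component
  comp <- resolve_selection(model, "protein")
  colors2 <- resolve_colors(model, comp,
                            list(list(atoms = all_idx, color = "white")))
  expect_true(all(is.na(colors2[-comp])))
})

test_that("random layer stacks match a sequential-overwrite oracle", {
  set.seed(41)
  model <- toy_mixed_model()
  n <- nrow(model$atoms)
  for (i in seq_len(100L)) {
    comp <- sort(sample.int(n, sample.int(n, 1L)))
    layers <- lapply(seq_len(sample.int(5L, 1L)), function(j) {
      list(atoms = sample.int(n, sample.int(n, 1L)),
           color = random_color())
    })
    got <- resolve_colors(model, comp, layers)
    want <- rep(NA_character_, n)
    for (layer in layers) for (a in layer$atoms) want[a] <- layer$color
    want[setdiff(seq_len(n), comp)] <- NA_character_
    expect_identical(got, want)
  }
})

test_that("grouped annotation labels instantiate once per group", {
  model <- parse_structure_mmcif(toy_structure_1h9t()$mmcif)
  ann <- locate_table(sp2_blocks(), category_name = "annotations")
  res <- resolve_labels(model, ann, "residue_range")
  texts <- vapply(res$instances, `[[`, character(1), "text")
  expect_length(res$instances, 15L)
  expect_identical(sum(texts == "Ligand binding site"), 4L)
  expect_identical(sum(texts == "Chloride"), 3L)
  expect_length(res$diagnostics, 0L)
  # group atom set is the union of its rows: group 2 spans 121-129 + 203-205
  lbs <- res$instances[texts == "Ligand binding site"]
  sizes <- sort(vapply(lbs, function(x) length(x$atoms), integer(1)))
  expect_identical(sizes, c(1L, 2L, 6L, 6L))
})

test_that("empty-selection label groups are dropped with a diagnostic", {
  spec <- toy_spec(list(list(label_asym_id = "A", kind = "protein",
                             n_residues = 5L)))
  model <- parse_structure_mmcif(make_toy_structure(spec)$mmcif)
  tab <- mvspec:::new_annotation_table("t", list(
    label_asym_id = c("A", "Z"),
    label = c("here", "nowhere")))
  res <- resolve_labels(model, tab, "chain")
  expect_length(res$instances, 1L)
  expect_match(res$diagnostics, "selects no atoms")
  expect_error(resolve_labels(model, tab, "chain", field_name = "group_id"),
               "independent")
  expect_error(resolve_labels(model, tab, "chain", field_name = "absent"),
               "not present")
})
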