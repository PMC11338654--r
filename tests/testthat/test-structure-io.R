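test_that("toy generator contract: chains, residues, seq ids", {
  txt <- make_toy_structure(toy_two_chain_spec())$mmcif
  model <- parse_structure_mmcif(txt)
  expect_identical(nrow(model$atoms), 6L)
  expect_identical(model$atoms$label_seq_id,
                   rep(1:3, 2L))
  expect_identical(model$atoms$atom_index, 0:5)
  expect_identical(unique(model$atoms$label_asym_id), c("A", "B"))
})

test_that("same spec yields identical bytes; entity categories parse back", {
  spec <- toy_mixed_spec()
  out1 <- make_toy_structure(spec)
  out2 <- make_toy_structure(spec)
  expect_identical(out1$mmcif, out2$mmcif)
  expect_identical(out1$pdb, out2$pdb)
  model <- parse_structure_mmcif(out1$mmcif)
  types <- vapply(model$entities, `[[`, character(1), "type")
  expect_identical(unname(types[model$atoms$label_entity_id[
    model$atoms$comp_id == "HOH"][1]]), "water")
  expect_identical(unname(types[model$atoms$label_entity_id[
    model$atoms$comp_id == "HEM"][1]]), "non-polymer")
})

test_that("missing atom_site and gzipped input give explicit errors", {
  expect_error(parse_structure_mmcif("data_x\nloop_\n_t.a\n1\n"),
               "no atom_site")
  gz <- as.raw(c(0x1f, 0x8b, 0x08, 0x00, 0x00, 0x00))  # gzip magic header
  expect_error(parse_structure_mmcif(gz), "Gzipped data not supported")
})

test_that("a single fixed-column PDB record parses field by field", {
  line <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
  model <- parse_structure_pdb(line)
  a <- model$atoms
  expect_identical(nrow(a), 1L)
  expect_identical(a$auth_asym_id, "A")
  expect_identical(a$auth_seq_id, 1L)
  expect_identical(a$label_asym_id, "A")  # mirrored namespace
  expect_identical(a$label_atom_id, "CA")
  expect_identical(c(a$x, a$y, a$z), c(1, 2, 3))
  expect_error(parse_structure_pdb("ATOM      1  CA  ALA"), "truncated")
})

test_that("HETATM HOH infers a water entity", {
  line <- "HETATM    9  O   HOH W   1       0.000   0.000   0.000  1.00  0.00           O"
  model <- parse_structure_pdb(line)
  expect_identical(model$entities[[model$atoms$label_entity_id[1]]]$type,
                   "water")
  expect_true(classify_atoms(model)$water)
})

test_that("mmCIF and PDB renderings agree on the author namespace", {
  out <- make_toy_structure(toy_mixed_spec())
  m1 <- parse_structure_mmcif(out$mmcif)
  m2 <- parse_structure_pdb(out$pdb)
  cols <- c("auth_asym_id", "auth_seq_id", "auth_atom_id", "comp_id",
            "x", "y", "z")
  expect_identical(m1$atoms[, cols], m2$atoms[, cols])
})

test_that("classification follows the entity/component rules", {
  model <- toy_mixed_model()
  cls <- classify_atoms(model)
  at <- model$atoms
  expect_true(all(cls$water[at$comp_id == "HOH"]))
  expect_true(all(cls$polymer[at$comp_id == "ALA"] &
                    cls$protein[at$comp_id == "ALA"]))
  expect_true(all(cls$polymer[at$comp_id == "DA"] &
                    cls$nucleic[at$comp_id == "DA"]))
  expect_true(all(cls$ion[at$comp_id == "CL"]))
  expect_true(all(cls$ligand[at$comp_id == "HEM"]))
  expect_false(any(cls$ion[at$comp_id == "HEM"]))
})

test_that("classification partitions at the entity level", {
  set.seed(11)
  kinds <- c("protein", "dna", "rna", "ligand", "ion", "water", "branched")
  for (rep_i in 1:5) {
    n <- sample(2:5, 1)
    chains <- lapply(seq_len(n), function(i) {
      list(label_asym_id = LETTERS[i], kind = sample(kinds, 1),
           n_residues = sample(1:4, 1))
    })
    model <- parse_structure_mmcif(
      make_toy_structure(toy_spec(chains))$mmcif)
    cls <- classify_atoms(model)
    base <- cls$water + cls$ion + cls$ligand + cls$branched + cls$polymer
    expect_true(all(base == 1L))
    expect_true(all(cls$protein <= cls$polymer))
    expect_true(all(cls$nucleic <= cls$polymer))
  }
})

test_that("atom fields agree with an independent mmCIF reader (gemmi)", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(23)
  kinds <- c("protein", "dna", "ligand", "ion", "water")
  dir <- tempfile("fixtures")
  dir.create(dir)
  files <- character(0)
  models <- list()
  for (i in seq_len(20L)) {
    chains <- lapply(seq_len(sample(1:4, 1)), function(j) {
      list(label_asym_id = LETTERS[j], kind = sample(kinds, 1),
           n_residues = sample(1:5, 1))
    })
    txt <- make_toy_structure(toy_spec(chains, seed = i))$mmcif
    f <- file.path(dir, sprintf("toy%02d.cif", i))
    writeLines(sub("\n$", "", txt), f)
    files <- c(files, f)
    models[[i]] <- parse_structure_mmcif(txt)
  }
  script <- file.path(dir, "dump.py")
  writeLines(c(
    "import sys, gemmi",
    "cols = ['id','type_symbol','label_atom_id','label_comp_id',",
    "        'label_asym_id','label_entity_id','label_seq_id',",
    "        'Cartn_x','Cartn_y','Cartn_z','auth_seq_id','auth_asym_id']",
    "for path in sys.argv[1:]:",
    "    block = gemmi.cif.read(path).sole_block()",
    "    for row in block.find('_atom_site.', cols):",
    "        print(path + '|' + '|'.join(row[i] for i in range(len(cols))))"
  ), script)
  out <- system2("python", c(script, files), stdout = TRUE)
  skip_if(length(out) == 0L, "gemmi unavailable")
  parts <- strsplit(out, "|", fixed = TRUE)
  byfile <- split(parts, vapply(parts, `[[`, character(1), 1L))
  for (i in seq_along(files)) {
    rows <- byfile[[files[i]]]
    a <- models[[i]]$atoms
    expect_identical(length(rows), nrow(a))
    g <- function(k) vapply(rows, `[[`, character(1), k)
    expect_identical(as.integer(g(2)), a$atom_id)
    expect_identical(g(3), a$type_symbol)
    expect_identical(g(4), a$label_atom_id)
    expect_identical(g(5), a$comp_id)
    expect_identical(g(6), a$label_asym_id)
    expect_identical(g(7), a$label_entity_id)
    seq_chr <- g(8)
    expect_identical(suppressWarnings(as.integer(ifelse(seq_chr == ".",
                                                        NA, seq_chr))),
                     a$label_seq_id)
    expect_equal(as.double(g(9)), a$x)
    expect_equal(as.double(g(10)), a$y)
    expect_equal(as.double(g(11)), a$z)
    expect_identical(as.integer(g(12)), a$auth_seq_id)
    expect_identical(g(13), a$auth_asym_id)
  }
})
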