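# Shared fixtures: the worked-example annotation file, toy structure specs,
# and random generators for property-style tests.

sp2_annotation_text <- function() {
  path <- system.file("extdata", "annotations-1h9t.cif", package = "mvspec")
  paste(readLines(path), collapse = "\n")
}

sp2_blocks <- function() parse_annotation_cif(sp2_annotation_text())

toy_two_chain_spec <- function() {
  toy_spec(list(
    list(label_asym_id = "A", kind = "protein", n_residues = 3L),
    list(label_asym_id = "B", kind = "protein", n_residues = 3L)
  ))
}

# mixed-content toy: protein, DNA, heme ligand, chloride ion, waters
toy_mixed_spec <- function() {
  toy_spec(list(
    list(label_asym_id = "A", kind = "protein", n_residues = 6L),
    list(label_asym_id = "B", kind = "dna", n_residues = 4L),
    list(label_asym_id = "E", kind = "ligand", comp = "HEM"),
    list(label_asym_id = "F", kind = "ion", comp = "CL"),
    list(label_asym_id = "W", kind = "water", n_residues = 2L)
  ))
}

toy_mixed_model <- function() {
  parse_structure_mmcif(make_toy_structure(toy_mixed_spec())$mmcif)
}

random_proper_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_color <- function() {
  if (stats::runif(1) < 0.5) {
    sprintf("#%06x", sample.int(16777216L, 1L) - 1L)
  } else {
    sample(c("red", "steelblue", "tomato", "gold", "white"), 1L)
  }
}

random_expression <- function() {
  fields <- list()
  if (stats::runif(1) < 0.6) {
    fields$label_asym_id <- sample(c("A", "B", "E", "F", "W", "Z"), 1L)
  }
  if (stats::runif(1) < 0.3) fields$label_seq_id <- sample.int(8L, 1L)
  if (stats::runif(1) < 0.3) {
    b <- sample.int(6L, 1L)
    fields$beg_label_seq_id <- b
    fields$end_label_seq_id <- b + sample.int(3L, 1L)
  }
  if (stats::runif(1) < 0.25) {
    fields$label_atom_id <- sample(c("CA", "P", "FE", "NA", "CL", "O"), 1L)
  }
  if (stats::runif(1) < 0.2) {
    fields$type_symbol <- sample(c("C", "P", "FE", "N", "CL", "O"), 1L)
  }
  if (stats::runif(1) < 0.2) fields$auth_seq_id <- sample.int(8L, 1L)
  if (stats::runif(1) < 0.15) fields$atom_index <- sample.int(20L, 1L) - 1L
  if (stats::runif(1) < 0.15) fields$atom_id <- sample.int(20L, 1L)
  if (stats::runif(1) < 0.15) {
    fields$label_entity_id <- sample(as.character(1:5), 1L)
  }
  do.call(mvs_expression, fields)
}

random_selector <- function() {
  u <- stats::runif(1)
  if (u < 0.3) {
    sample(c("all", "polymer", "protein", "nucleic", "ligand", "ion",
             "water", "branched"), 1L)
  } else if (u < 0.7) {
    random_expression()
  } else {
    lapply(seq_len(sample.int(3L, 1L)), function(i) random_expression())
  }
}

# grammar-valid random document (built through the builder, so construction
# itself enforces validity)
random_document <- random_state_document

# independent brute-force oracle for expression matching: per-atom loop
# with explicit field comparisons (kept deliberately separate from the
# vectorized implementation)
oracle_match_expression <- function(atoms, expr) {
  out <- logical(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    ok <- TRUE
    for (nm in names(expr)) {
      v <- expr[[nm]]
      a <- switch(nm,
        beg_label_seq_id = , end_label_seq_id = atoms$label_seq_id[i],
        beg_auth_seq_id = , end_auth_seq_id = atoms$auth_seq_id[i],
        atoms[[nm]][i])
      if (is.na(a)) { ok <- FALSE; break }
      hit <- switch(nm,
        beg_label_seq_id = , beg_auth_seq_id = a >= v,
        end_label_seq_id = , end_auth_seq_id = a <= v,
        type_symbol = toupper(a) == toupper(v),
        a == v)
      if (!hit) { ok <- FALSE; break }
    }
    out[i] <- ok
  }
  out
}

write_tmp <- function(text, fileext, dir = tempdir()) {
  path <- tempfile(fileext = fileext, tmpdir = dir)
  writeLines(sub("\n$", "", text), path)
  path
}
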