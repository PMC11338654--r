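# ---------------------------------------------------------------------------
# Deterministic toy-structure generator.  Coordinates sit on an integer
# lattice (atom ordinal, residue number, 10 * chain ordinal) so transformed
# copies are checkable by hand.  The same spec always produces identical
# bytes.
# ---------------------------------------------------------------------------

toy_chain_kinds <- c("protein", "dna", "rna", "ligand", "ion", "water",
                     "branched")

#' Describe a toy structure
#'
#' @param chains list of chain descriptions:
#'   `list(label_asym_id, kind, n_residues, comp)` where `kind` is one of
#'   `protein`, `dna`, `rna`, `ligand`, `ion`, `water`, `branched` and
#'   `comp` optionally overrides the default component for the kind.
#' @param assemblies optional named list (names are assembly ids); each
#'   element is `list(operators = list(list(rotation = <9>, translation =
#'   <3>)), asym_ids = <chains or NULL for all>, oper_expression =
#'   <override or NULL>)`.
#' @param seed integer recorded in the file header; the generator is fully
#'   deterministic for a fixed spec.
#' @return a spec of class `mvs_toy_spec` for [make_toy_structure()].
#' @export
toy_spec <- function(chains, assemblies = NULL, seed = 0L) {
  chains <- lapply(chains, function(ch) {
    stopifnot(is_string(ch$label_asym_id), is_string(ch$kind))
    if (!ch$kind %in% toy_chain_kinds) {
      mvs_stop("unknown toy chain kind: ", ch$kind)
    }
    ch$n_residues <- as.integer(ch$n_residues %||% 1L)
    ch$comp <- ch$comp %||% switch(ch$kind,
      protein = "ALA", dna = "DA", rna = "A", ligand = "HEM", ion = "CL",
      water = "HOH", branched = "NAG")
    ch
  })
  structure(list(chains = chains, assemblies = assemblies,
                 seed = as.integer(seed)),
            class = "mvs_toy_spec")
}

toy_residue_atoms <- function(kind, comp) {
  switch(kind,
    protein = list(names = "CA", elems = "C"),
    dna = , rna = list(names = "P", elems = "P"),
    ligand = if (comp == "HEM") {
      list(names = c("FE", "NA", "NB", "NC", "ND"),
           elems = c("FE", "N", "N", "N", "N"))
    } else {
      list(names = c("C1", "C2"), elems = c("C", "C"))
    },
    ion = list(names = comp, elems = comp),
    water = list(names = "O", elems = "O"),
    branched = list(names = c("C1", "O5"), elems = c("C", "O"))
  )
}

toy_atom_table <- function(spec) {
  rows <- list()
  serial <- 0L
  for (ci in seq_along(spec$chains)) {
    ch <- spec$chains[[ci]]
    is_poly <- ch$kind %in% c("protein", "dna", "rna")
    at <- toy_residue_atoms(ch$kind, ch$comp)
    for (ri in seq_len(ch$n_residues)) {
      for (ai in seq_along(at$names)) {
        serial <- serial + 1L
        rows[[serial]] <- data.frame(
          group = if (is_poly) "ATOM" else "HETATM",
          id = serial,
          name = at$names[ai], elem = at$elems[ai],
          comp = ch$comp, asym = ch$label_asym_id,
          entity = as.character(ci),
          seq = if (is_poly) ri else NA_integer_,
          auth_seq = ri,
          x = as.double(ai - 1L), y = as.double(ri),
          z = as.double(10L * ci),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

toy_entity_rows <- function(spec) {
  type <- vapply(spec$chains, function(ch) switch(ch$kind,
    protein = , dna = , rna = "polymer",
    water = "water", branched = "branched", "non-polymer"), character(1))
  poly <- vapply(spec$chains, function(ch) switch(ch$kind,
    protein = "polypeptide(L)", dna = "polydeoxyribonucleotide",
    rna = "polyribonucleotide", NA_character_), character(1))
  list(id = as.character(seq_along(spec$chains)), type = type, poly = poly)
}

#' Emit a toy structure as mmCIF and PDB text
#'
#' @param spec a [toy_spec()].
#' @return `list(mmcif = <text>, pdb = <text>)`; both render the same atoms
#'   (the PDB rendering carries the author namespace only).
#' @examples
#' s <- toy_spec(list(list(label_asym_id = "A", kind = "protein",
#'                         n_residues = 5)))
#' model <- parse_structure_mmcif(make_toy_structure(s)$mmcif)
#' nrow(model$atoms)
#' @export
make_toy_structure <- function(spec) {
  stopifnot(inherits(spec, "mvs_toy_spec"))
  at <- toy_atom_table(spec)
  ent <- toy_entity_rows(spec)
  num <- function(v) sprintf("%.3f", v)
  lines <- c("data_toy", paste0("# toy structure, seed ", spec$seed), "#")
  lines <- c(lines, "loop_", "_entity.id", "_entity.type",
             paste(ent$id, ent$type), "#")
  has_poly <- !is.na(ent$poly)
  if (any(has_poly)) {
    lines <- c(lines, "loop_", "_entity_poly.entity_id", "_entity_poly.type",
               paste(ent$id[has_poly],
                     vapply(ent$poly[has_poly], cif_format_cell,
                            character(1))), "#")
  }
  if (length(spec$assemblies)) {
    all_asym <- vapply(spec$chains, `[[`, character(1), "label_asym_id")
    oper_rows <- character(0)
    gen_rows <- character(0)
    next_op <- 0L
    for (aid in names(spec$assemblies)) {
      a <- spec$assemblies[[aid]]
      op_ids <- character(0)
      for (op in a$operators) {
        next_op <- next_op + 1L
        id <- as.character(next_op)
        op_ids <- c(op_ids, id)
        R <- matrix(as.double(op$rotation %||% c(diag(3))), 3, 3)
        t3 <- as.double(op$translation %||% c(0, 0, 0))
        oper_rows <- c(oper_rows, paste(
          id,
          paste(num(as.vector(t(R))), collapse = " "),
          paste(num(t3), collapse = " ")))
      }
      gen_rows <- c(gen_rows, paste(
        aid,
        cif_format_cell(a$oper_expression %||%
                          paste(op_ids, collapse = ",")),
        paste(a$asym_ids %||% all_asym, collapse = ",")))
    }
    lines <- c(lines, "loop_", "_pdbx_struct_assembly.id",
               names(spec$assemblies), "#")
    lines <- c(lines, "loop_", "_pdbx_struct_assembly_gen.assembly_id",
               "_pdbx_struct_assembly_gen.oper_expression",
               "_pdbx_struct_assembly_gen.asym_id_list", gen_rows, "#")
    lines <- c(lines, "loop_", "_pdbx_struct_oper_list.id",
               sprintf("_pdbx_struct_oper_list.matrix[%d][%d]",
                       rep(1:3, each = 3), rep(1:3, 3)),
               sprintf("_pdbx_struct_oper_list.vector[%d]", 1:3),
               oper_rows, "#")
  }
  lines <- c(lines, "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id",
                      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                      "occupancy", "B_iso_or_equiv", "auth_seq_id",
                      "auth_comp_id", "auth_asym_id", "auth_atom_id",
                      "pdbx_PDB_model_num")))
  lines <- c(lines, paste(
    at$group, at$id, at$elem, at$name, ".", at$comp, at$asym, at$entity,
    ifelse(is.na(at$seq), ".", as.character(at$seq)), ".",
    num(at$x), num(at$y), num(at$z), "1.00", "0.00",
    at$auth_seq, at$comp, at$asym, at$name, "1"), "#")
  mmcif <- paste0(paste(lines, collapse = "\n"), "\n")

  pdb_name <- function(name, elem) {
    if (nchar(name) >= 4L) return(substr(name, 1, 4))
    if (nchar(elem) == 1L) sprintf(" %-3s", name) else sprintf("%-4s", name)
  }
  pdb_lines <- c(sprintf("REMARK 999 TOY STRUCTURE SEED %d", spec$seed),
                 vapply(seq_len(nrow(at)), function(i) {
    sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            at$group[i], at$id[i], pdb_name(at$name[i], at$elem[i]), " ",
            at$comp[i], at$asym[i], at$auth_seq[i], " ",
            at$x[i], at$y[i], at$z[i], 1, 0, at$elem[i])
  }, character(1)), "END")
  list(mmcif = mmcif, pdb = paste0(paste(pdb_lines, collapse = "\n"), "\n"))
}
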