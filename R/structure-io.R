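# ---------------------------------------------------------------------------
# Minimal structure reading: mmCIF (PDBx atom_site & friends) and legacy PDB
# into a flat atom table plus entity metadata and assembly definitions, and
# a deterministic toy-structure generator used throughout the tests.
# ---------------------------------------------------------------------------

# monatomic components treated as the "ion" selector class
monatomic_ion_comps <- c(
  "LI", "NA", "K", "RB", "CS", "MG", "CA", "SR", "BA", "MN", "FE", "FE2",
  "CO", "NI", "CU", "CU1", "ZN", "CD", "HG", "AL", "GA", "TL", "PB", "F",
  "CL", "BR", "I", "IOD", "AU", "AG", "PT", "SM", "EU", "GD", "TB", "YB",
  "LU", "W", "MO", "V", "CR", "3CO", "3NI", "MN3", "AU3", "OH", "NH4"
)

standard_aa_comps <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL", "MSE")
dna_comps <- c("DA", "DC", "DG", "DT", "DU", "DI")
rna_comps <- c("A", "C", "G", "U", "I")

empty_atom_table <- function() {
  data.frame(atom_index = integer(0), atom_id = integer(0),
             label_atom_id = character(0), auth_atom_id = character(0),
             type_symbol = character(0), label_asym_id = character(0),
             auth_asym_id = character(0), label_seq_id = integer(0),
             auth_seq_id = integer(0), pdbx_PDB_ins_code = character(0),
             label_entity_id = character(0), comp_id = character(0),
             x = double(0), y = double(0), z = double(0),
             model_num = integer(0), stringsAsFactors = FALSE)
}

new_structure_model <- function(atoms, entities, assemblies = list(),
                                opers = list(), source_text = NULL) {
  structure(list(atoms = atoms, entities = entities,
                 assemblies = assemblies, opers = opers,
                 source_text = source_text),
            class = "mvs_structure")
}

ensure_text <- function(input, what = "input") {
  if (is.raw(input)) {
    if (length(input) >= 2L && input[1] == as.raw(0x1f) &&
        input[2] == as.raw(0x8b)) {
      mvs_stop("Gzipped data not supported. Use unzipped files.",
               class = "mvs_gzip_error")
    }
    return(rawToChar(input))
  }
  if (!is.character(input)) mvs_stop(what, " must be text or raw bytes")
  paste(input, collapse = "\n")
}

infer_poly_type <- function(comps) {
  comps <- unique(comps)
  if (all(comps %in% standard_aa_comps)) return("polypeptide(L)")
  if (all(comps %in% dna_comps)) return("polydeoxyribonucleotide")
  if (all(comps %in% rna_comps)) return("polyribonucleotide")
  NA_character_
}

#' Parse an mmCIF structure file
#'
#' Reads the `atom_site` category into a flat atom table and, when present,
#' `entity`, `entity_poly`, `pdbx_struct_assembly_gen` and
#' `pdbx_struct_oper_list`. Without an `entity` category, one entity per
#' chain is inferred from the residue content.
#'
#' @param input mmCIF text or raw bytes (gzipped input is rejected with an
#'   explicit message).
#' @return a structure model: `list(atoms, entities, assemblies, opers,
#'   source_text)` of class `mvs_structure`. `atoms` is a data.frame with
#'   one row per atom (`atom_index` is a dense 0-based ordinal per model);
#'   `entities` maps `label_entity_id` to `list(type, poly_type)`;
#'   `assemblies` maps assembly id to generator records; `opers` maps
#'   operator id to a 4x4 matrix (last row 0,0,0,1).
#' @export
parse_structure_mmcif <- function(input) {
  text <- ensure_text(input, "mmCIF")
  blocks <- tryCatch(cif_read_blocks(text), error = function(e) {
    mvs_stop("File parsing error: ", conditionMessage(e),
             class = "mvs_parse_error")
  })
  if (!length(blocks)) mvs_stop("File parsing error: no data_ block",
                                class = "mvs_parse_error")
  tables <- blocks[[1]]$tables
  as_tab <- tables[["atom_site"]]
  if (is.null(as_tab)) {
    mvs_stop("File parsing error: no atom_site category found",
             class = "mvs_parse_error")
  }
  col <- function(nm, fallback = NULL) {
    v <- as_tab$columns[[nm]]
    if (is.null(v) && !is.null(fallback)) v <- as_tab$columns[[fallback]]
    v
  }
  n <- as_tab$n_rows
  need <- function(v, nm) {
    if (is.null(v)) {
      mvs_stop("File parsing error: atom_site lacks column ", nm,
               class = "mvs_parse_error")
    }
    v
  }
  int_or_na <- function(v) {
    if (is.null(v)) return(rep(NA_integer_, n))
    suppressWarnings(as.integer(v))
  }
  xyz <- lapply(c("Cartn_x", "Cartn_y", "Cartn_z"), function(nm) {
    as.double(need(col(nm), nm))
  })
  label_atom <- col("label_atom_id", "auth_atom_id")
  auth_atom <- col("auth_atom_id", "label_atom_id")
  label_asym <- need(col("label_asym_id", "auth_asym_id"), "label_asym_id")
  auth_asym <- col("auth_asym_id", "label_asym_id")
  comp <- need(col("label_comp_id", "auth_comp_id"), "label_comp_id")
  model_num <- int_or_na(col("pdbx_PDB_model_num"))
  model_num[is.na(model_num)] <- 1L
  entity_col <- col("label_entity_id")
  atoms <- data.frame(
    atom_index = NA_integer_,
    atom_id = int_or_na(need(col("id"), "id")),
    label_atom_id = label_atom %||% rep(NA_character_, n),
    auth_atom_id = auth_atom %||% rep(NA_character_, n),
    type_symbol = col("type_symbol") %||% rep(NA_character_, n),
    label_asym_id = label_asym,
    auth_asym_id = auth_asym %||% label_asym,
    label_seq_id = int_or_na(col("label_seq_id")),
    auth_seq_id = int_or_na(col("auth_seq_id")),
    pdbx_PDB_ins_code = col("pdbx_PDB_ins_code") %||% rep(NA_character_, n),
    label_entity_id = entity_col %||% rep(NA_character_, n),
    comp_id = comp,
    x = xyz[[1]], y = xyz[[2]], z = xyz[[3]],
    model_num = model_num,
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$label_entity_id)) {
    # fabricate one entity id per chain
    ids <- match(atoms$label_asym_id, unique(atoms$label_asym_id))
    atoms$label_entity_id <- ifelse(is.na(atoms$label_entity_id),
                                    as.character(ids),
                                    atoms$label_entity_id)
  }
  atoms$atom_index <- stats::ave(seq_len(n), atoms$model_num,
                                 FUN = seq_along) - 1L
  entities <- parse_entities(tables, atoms)
  ops <- parse_assemblies(tables)
  new_structure_model(atoms, entities, ops$assemblies, ops$opers,
                      source_text = text)
}

# entity records from _entity/_entity_poly, or inferred from atom content
parse_entities <- function(tables, atoms) {
  entities <- list()
  et <- tables[["entity"]]
  if (!is.null(et) && !is.null(et$columns$id)) {
    types <- et$columns$type %||% rep(NA_character_, et$n_rows)
    for (i in seq_len(et$n_rows)) {
      entities[[et$columns$id[i]]] <- list(type = types[i],
                                           poly_type = NA_character_)
    }
  }
  ep <- tables[["entity_poly"]]
  if (!is.null(ep) && !is.null(ep$columns$entity_id)) {
    ptypes <- ep$columns$type %||% rep(NA_character_, ep$n_rows)
    for (i in seq_len(ep$n_rows)) {
      id <- ep$columns$entity_id[i]
      if (is.null(entities[[id]])) {
        entities[[id]] <- list(type = "polymer", poly_type = ptypes[i])
      } else {
        entities[[id]]$poly_type <- ptypes[i]
      }
    }
  }
  for (id in unique(atoms$label_entity_id)) {
    if (!is.null(entities[[id]])) next
    sel <- atoms$label_entity_id == id
    comps <- unique(atoms$comp_id[sel])
    if (all(comps %in% c("HOH", "DOD", "WAT"))) {
      entities[[id]] <- list(type = "water", poly_type = NA_character_)
    } else if (sum(!is.na(unique(atoms$label_seq_id[sel]))) > 1L) {
      entities[[id]] <- list(type = "polymer",
                             poly_type = infer_poly_type(comps))
    } else {
      entities[[id]] <- list(type = "non-polymer", poly_type = NA_character_)
    }
  }
  entities
}

parse_assemblies <- function(tables) {
  assemblies <- list()
  opers <- list()
  ol <- tables[["pdbx_struct_oper_list"]]
  if (!is.null(ol) && !is.null(ol$columns$id)) {
    for (i in seq_len(ol$n_rows)) {
      m <- diag(4)
      for (r in 1:3) {
        for (cc in 1:3) {
          v <- ol$columns[[sprintf("matrix[%d][%d]", r, cc)]]
          if (!is.null(v)) m[r, cc] <- as.double(v[i])
        }
        v <- ol$columns[[sprintf("vector[%d]", r)]]
        if (!is.null(v)) m[r, 4] <- as.double(v[i])
      }
      opers[[ol$columns$id[i]]] <- m
    }
  }
  ag <- tables[["pdbx_struct_assembly_gen"]]
  if (!is.null(ag) && !is.null(ag$columns$assembly_id)) {
    oexpr <- ag$columns$oper_expression %||% rep(NA_character_, ag$n_rows)
    alist <- ag$columns$asym_id_list %||% rep(NA_character_, ag$n_rows)
    for (i in seq_len(ag$n_rows)) {
      id <- ag$columns$assembly_id[i]
      gen <- list(
        oper_expression = oexpr[i],
        asym_ids = trimws(strsplit(alist[i] %||% "", ",", fixed = TRUE)[[1]])
      )
      assemblies[[id]] <- c(assemblies[[id]] %||% list(), list(gen))
    }
  }
  list(assemblies = assemblies, opers = opers)
}

#' Parse a legacy PDB structure file
#'
#' Reads fixed-column `ATOM`/`HETATM` records. The legacy format carries
#' only the author namespace, so `label_*` fields mirror `auth_*` and
#' entities are inferred (one per chain and record class; `HOH` becomes
#' water, `ATOM` chains become polymer).
#'
#' @param input PDB text or raw bytes.
#' @return a structure model (see [parse_structure_mmcif()]).
#' @export
parse_structure_pdb <- function(input) {
  text <- ensure_text(input, "PDB")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  model_num <- 1L
  recs <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    tag <- substr(line, 1, 6)
    if (startsWith(tag, "MODEL")) {
      model_num <- suppressWarnings(as.integer(trimws(substr(line, 11, 14))))
      if (is.na(model_num)) model_num <- 1L
      next
    }
    if (!(tag %in% c("ATOM  ", "HETATM"))) next
    if (nchar(line) < 54L) {
      mvs_stop("line ", ln, ": truncated ", trimws(tag), " record (",
               nchar(line), " columns, need at least 54)",
               class = "mvs_parse_error")
    }
    f <- function(a, b) trimws(substr(line, a, b))
    recs[[length(recs) + 1L]] <- list(
      record = trimws(tag),
      atom_id = suppressWarnings(as.integer(f(7, 11))),
      atom_name = f(13, 16),
      comp = f(18, 20),
      chain = substr(line, 22, 22),
      seq = suppressWarnings(as.integer(f(23, 26))),
      icode = f(27, 27),
      x = as.double(f(31, 38)), y = as.double(f(39, 46)),
      z = as.double(f(47, 54)),
      element = if (nchar(line) >= 78L) f(77, 78) else "",
      model = model_num
    )
  }
  n <- length(recs)
  if (!n) mvs_stop("File parsing error: no ATOM/HETATM records",
                   class = "mvs_parse_error")
  g <- function(nm, how) vapply(recs, `[[`, how, nm)
  chain <- g("chain", character(1))
  record <- g("record", character(1))
  comp <- g("comp", character(1))
  icode <- g("icode", character(1)); icode[icode == ""] <- NA_character_
  elem <- g("element", character(1)); elem[elem == ""] <- NA_character_
  # entity classes: ATOM -> polymer chain entity; HETATM water / non-polymer
  ecls <- ifelse(record == "ATOM", "polymer",
                 ifelse(comp %in% c("HOH", "DOD", "WAT"), "water",
                        "non-polymer"))
  ekey <- paste(chain, ecls, ifelse(ecls == "non-polymer", comp, ""))
  entity_id <- as.character(match(ekey, unique(ekey)))
  seq_ <- g("seq", integer(1))
  atoms <- data.frame(
    atom_index = NA_integer_,
    atom_id = g("atom_id", integer(1)),
    label_atom_id = g("atom_name", character(1)),
    auth_atom_id = g("atom_name", character(1)),
    type_symbol = elem,
    label_asym_id = chain, auth_asym_id = chain,
    label_seq_id = ifelse(ecls == "polymer", seq_, NA_integer_),
    auth_seq_id = seq_,
    pdbx_PDB_ins_code = icode,
    label_entity_id = entity_id,
    comp_id = comp,
    x = g("x", double(1)), y = g("y", double(1)), z = g("z", double(1)),
    model_num = g("model", integer(1)),
    stringsAsFactors = FALSE
  )
  atoms$atom_index <- stats::ave(seq_len(n), atoms$model_num,
                                 FUN = seq_along) - 1L
  entities <- list()
  for (i in seq_len(n)) {
    id <- entity_id[i]
    if (!is.null(entities[[id]])) next
    sel <- entity_id == id
    entities[[id]] <- list(
      type = ecls[i],
      poly_type = if (ecls[i] == "polymer") {
        infer_poly_type(comp[sel])
      } else NA_character_
    )
  }
  new_structure_model(atoms, entities, source_text = text)
}

#' Classify atoms into the built-in selector classes
#'
#' Computes membership of every atom in the named selector classes:
#' `water` (entity water or `HOH`), `polymer` (polymer entity), `protein`
#' (polymer with a polypeptide type), `nucleic` (polymer with a ribo- or
#' deoxyribonucleotide type), `branched` (branched entity), `ion`
#' (non-polymer monatomic component from the embedded ion list), `ligand`
#' (any other non-polymer).
#'
#' @param model a structure model.
#' @return data.frame of logicals with one row per atom and columns
#'   `polymer`, `protein`, `nucleic`, `branched`, `ligand`, `ion`, `water`.
#' @export
classify_atoms <- function(model) {
  stopifnot(inherits(model, "mvs_structure"))
  atoms <- model$atoms
  etype <- vapply(atoms$label_entity_id, function(id) {
    model$entities[[id]]$type %||% NA_character_
  }, character(1), USE.NAMES = FALSE)
  ptype <- vapply(atoms$label_entity_id, function(id) {
    model$entities[[id]]$poly_type %||% NA_character_
  }, character(1), USE.NAMES = FALSE)
  water <- etype == "water" | atoms$comp_id %in% c("HOH", "DOD", "WAT")
  polymer <- !water & etype == "polymer"
  protein <- polymer & !is.na(ptype) & grepl("polypeptide", ptype)
  nucleic <- polymer & !is.na(ptype) &
    (grepl("ribonucleotide", ptype) | grepl("deoxyribonucleotide", ptype))
  branched <- !water & etype == "branched"
  nonpoly <- !water & !polymer & !branched
  ion <- nonpoly & atoms$comp_id %in% monatomic_ion_comps
  ligand <- nonpoly & !ion
  data.frame(polymer = polymer, protein = protein, nucleic = nucleic,
             branched = branched, ligand = ligand, ion = ion, water = water)
}
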