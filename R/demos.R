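# ---------------------------------------------------------------------------
# Worked example views: the three demonstration scripts of the format
# (superposition of two structures, annotation-driven components/colors/
# labels, and labels/camera/canvas control), plus matching toy structures
# for resolving them offline.
# ---------------------------------------------------------------------------

#' Printed pairwise-alignment matrix for the 1oj6/5mjd example
#'
#' The 4x4 homogeneous matrix (row-vector convention) reported by the
#' RCSB pairwise structure alignment service for superposing chain A of
#' PDB 5mjd onto chain A of PDB 1oj6, as 16 row-major values.
#'
#' @return numeric vector of 16 values.
#' @seealso [convert_alignment_matrix()]
#' @export
alignment_matrix_1oj6_5mjd <- function() {
  c(-0.3965220392, 0.9180228028, 0.0020990366, 0,
    0.9068461183, 0.3913367028, 0.1564790811, 0,
    0.1428299346, 0.0639509075, -0.9876790426, 0,
    -17.6360858967, 7.9707613147, 88.5461324803, 1)
}

#' Demonstration views
#'
#' Each function builds one of the package's worked-example view documents:
#'
#' * `demo_view_superposition()` — two structures (PDB 1oj6 and 5mjd)
#'   superposed by a rigid-body transform, polymer in cartoon, ligands in
#'   ball-and-stick, one color per structure.
#' * `demo_view_annotations()` — one structure (PDB 1h9t) whose components,
#'   colors, labels and tooltips are all driven by an external annotation
#'   file.
#' * `demo_view_labels()` — the first heme ligand of PDB 4hhb in
#'   ball-and-stick with the iron ion recolored, labeled and tooltipped,
#'   plus canvas background and explicit camera.
#'
#' @param url,annotation_uri override the structure / annotation locations
#'   (e.g. to point at local toy fixtures).
#' @param timestamp fixed metadata timestamp for reproducible serialization.
#' @return an `mvs_state` document.
#' @name demo-views
NULL

#' @rdname demo-views
#' @param url1,url2 structure locations for the two superposed entries.
#' @export
demo_view_superposition <- function(
    url1 = "https://files.wwpdb.org/download/1oj6.cif",
    url2 = "https://files.wwpdb.org/download/5mjd.cif",
    timestamp = NULL) {
  b <- mvs_builder(timestamp = timestamp)
  structure1 <- b |> mvs_download(url1) |> mvs_parse("mmcif") |>
    mvs_assembly_structure(assembly_id = "1")
  structure2 <- b |> mvs_download(url2) |> mvs_parse("mmcif") |>
    mvs_assembly_structure(assembly_id = "1") |>
    mvs_transform(
      rotation = c(-0.39652203922082313, 0.918022802798312,
                   0.002099036562725462, 0.9068461182538327,
                   0.39133670281585825, 0.1564790811487865,
                   0.14282993460796656, 0.06395090751149791,
                   -0.9876790426086504),
      translation = c(-17.636085896690037, 7.970761314734439,
                      88.54613248028247))
  structure1 |> mvs_component("polymer") |> mvs_representation("cartoon") |>
    mvs_color("#e19039")
  structure1 |> mvs_component("ligand") |>
    mvs_representation("ball_and_stick") |> mvs_color("#eec190")
  structure2 |> mvs_component("polymer") |> mvs_representation("cartoon") |>
    mvs_color("#4b7fcc")
  structure2 |> mvs_component("ligand") |>
    mvs_representation("ball_and_stick") |> mvs_color("#9cb8e3")
  mvs_document(b)
}

#' @rdname demo-views
#' @export
demo_view_annotations <- function(
    url = "https://files.wwpdb.org/download/1h9t.cif",
    annotation_uri = "./annotations-1h9t.cif",
    timestamp = NULL) {
  b <- mvs_builder(timestamp = timestamp)
  structure <- b |> mvs_download(url) |> mvs_parse("mmcif") |>
    mvs_model_structure()
  protein <- structure |> mvs_component_from_uri(
    uri = annotation_uri, format = "cif", block_header = "1h9t_annotations",
    category_name = "components", field_name = "component",
    field_values = "Protein", schema = "chain")
  dna <- structure |> mvs_component_from_uri(
    uri = annotation_uri, format = "cif", category_name = "components",
    field_values = "DNA", schema = "chain")
  ions <- structure |> mvs_component_from_uri(
    uri = annotation_uri, format = "cif", category_name = "components",
    field_values = c("Gold", "Chloride"), schema = "chain")
  protein |> mvs_representation("cartoon") |> mvs_color_from_uri(
    uri = annotation_uri, format = "cif", block_header = "1h9t_annotations",
    category_name = "annotations", field_name = "color",
    schema = "residue_range")
  dna |> mvs_representation("ball_and_stick") |> mvs_color_from_uri(
    uri = annotation_uri, format = "cif", category_name = "annotations",
    schema = "residue_range")
  ions |> mvs_representation("surface") |> mvs_color_from_uri(
    uri = annotation_uri, format = "cif", category_name = "annotations",
    schema = "residue_range")
  structure |> mvs_label_from_uri(
    uri = annotation_uri, format = "cif", block_header = "1h9t_annotations",
    category_name = "annotations", field_name = "label",
    schema = "residue_range")
  structure |> mvs_tooltip_from_uri(
    uri = annotation_uri, format = "cif", block_header = "1h9t_annotations",
    category_name = "annotations", field_name = "label",
    schema = "residue_range")
  mvs_document(b)
}

#' @rdname demo-views
#' @export
demo_view_labels <- function(
    url = "https://www.ebi.ac.uk/pdbe/entry-files/download/4hhb_updated.cif",
    timestamp = NULL) {
  b <- mvs_builder(timestamp = timestamp)
  structure <- b |> mvs_download(url) |> mvs_parse("mmcif") |>
    mvs_assembly_structure(assembly_id = "1")
  fe_selector <- mvs_expression(label_asym_id = "E", label_atom_id = "FE")
  ligand <- structure |>
    mvs_component(mvs_expression(label_asym_id = "E"))
  ligand |> mvs_representation("ball_and_stick") |>
    mvs_color("#ffffff") |>
    mvs_color(color = "#ff4500", selector = fe_selector)
  fe <- structure |> mvs_component(fe_selector)
  fe |> mvs_label("Iron Ion") |>
    mvs_tooltip("Additional info that appears only on mouseover")
  b |> mvs_canvas("#ffcf6b")
  b |> mvs_camera(target = c(18, 18, 24), position = c(30, 12, 25))
  mvs_document(b)
}

#' Toy structures matching the demonstration views
#'
#' Synthetic stand-ins (integer-lattice coordinates, one atom per residue)
#' with the same chain layout as the real entries, so the demo documents
#' can be resolved offline: `toy_structure_1h9t()` has protein chains A/B
#' (residues 1-231), DNA chains C/D, gold ions E/H and chloride ions F/G/I;
#' `toy_structure_4hhb()` has four globin chains A-D and heme ligands in
#' chains E-H (the heme carries an FE atom); both expose assembly "1" with
#' the identity operator.
#'
#' @return `list(mmcif, pdb)` text, as from [make_toy_structure()].
#' @name toy-demo-structures
NULL

#' @rdname toy-demo-structures
#' @export
toy_structure_1h9t <- function() {
  ident <- list(operators = list(list(rotation = c(diag(3)),
                                      translation = c(0, 0, 0))))
  spec <- toy_spec(
    chains = list(
      list(label_asym_id = "A", kind = "protein", n_residues = 231L),
      list(label_asym_id = "B", kind = "protein", n_residues = 231L),
      list(label_asym_id = "C", kind = "dna", n_residues = 12L),
      list(label_asym_id = "D", kind = "dna", n_residues = 12L),
      list(label_asym_id = "E", kind = "ion", comp = "AU"),
      list(label_asym_id = "H", kind = "ion", comp = "AU"),
      list(label_asym_id = "F", kind = "ion", comp = "CL"),
      list(label_asym_id = "G", kind = "ion", comp = "CL"),
      list(label_asym_id = "I", kind = "ion", comp = "CL")
    ),
    assemblies = list("1" = ident)
  )
  make_toy_structure(spec)
}

#' @rdname toy-demo-structures
#' @export
toy_structure_4hhb <- function() {
  ident <- list(operators = list(list(rotation = c(diag(3)),
                                      translation = c(0, 0, 0))))
  spec <- toy_spec(
    chains = list(
      list(label_asym_id = "A", kind = "protein", n_residues = 141L),
      list(label_asym_id = "B", kind = "protein", n_residues = 146L),
      list(label_asym_id = "C", kind = "protein", n_residues = 141L),
      list(label_asym_id = "D", kind = "protein", n_residues = 146L),
      list(label_asym_id = "E", kind = "ligand", comp = "HEM"),
      list(label_asym_id = "F", kind = "ligand", comp = "HEM"),
      list(label_asym_id = "G", kind = "ligand", comp = "HEM"),
      list(label_asym_id = "H", kind = "ligand", comp = "HEM")
    ),
    assemblies = list("1" = ident)
  )
  make_toy_structure(spec)
}
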