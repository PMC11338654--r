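# mvspec

Molecular visualizations are hard to reproduce: every 3D viewer has its own
session format, so a carefully composed view of a structure — which chains
are shown, in which representation, colored and labeled how — cannot be
handed to a colleague who uses a different tool. The MolViewSpec approach
solves this by describing a view *declaratively*: a JSON state file (MVSJ)
holds a tree of typed nodes

```
download → parse → structure → component → representation → color
                            ↘ label/tooltip          camera · canvas
```

that any compliant viewer can interpret. `mvspec` is an R toolkit for this
format, aimed at structural bioinformaticians who want to build, check,
transform and *headlessly resolve* such view descriptions:

* a grammar-aware fluent **builder** (`mvs_builder()`, `mvs_download()`,
  `mvs_component()`, ... ) that cannot produce invalid trees;
* strict **MVSJ serialization** (`serialize_mvsj()` / `parse_mvsj()`),
  byte-stable and round-trip safe;
* **annotation tables** in CIF and JSON (`parse_annotation_cif()`,
  `filter_rows()`, `group_rows()`): independent-variable columns
  (`label_asym_id`, `beg_label_seq_id`, ...) select substructures, dependent
  columns assign component names, colors, labels and tooltips;
* minimal **structure readers** for mmCIF and legacy PDB plus a
  deterministic toy-structure generator for testing;
* a **resolver** (`flatten_scene()`) that materializes a state document
  against coordinates: selection expressions (AND over set fields, ranges
  inclusive), rigid-body transforms `x' = R x + t` (R column-major),
  biological-assembly expansion, last-writer-wins color layering, and
  per-group label instantiation via `group_id`;
* deterministic **MVSX bundles** (`mvsx_pack()` / `mvsx_unpack()`): a ZIP
  with the state as `index.mvsj` plus its assets, so relative references
  resolve offline;
* a **CLI** (`exec/mvs`): `validate`, `pack`, `unpack`, `flatten`,
  `convert-annotations`, `matrix-convert`.

## Worked example

Superposition needs a rigid-body transform. Alignment services report a
4×4 homogeneous matrix (row-vector convention); `convert_alignment_matrix()`
splits it into the rotation/translation vectors a transform node expects:

```r
library(mvspec)
m <- jsonlite::fromJSON(system.file("extdata", "alignment-1oj6-5mjd.json",
                                    package = "mvspec"))
convert_alignment_matrix(m)
#> $rotation
#> [1] -0.396522039  0.918022803  0.002099037  0.906846118  0.391336703
#> [6]  0.156479081  0.142829935  0.063950908 -0.987679043
#>
#> $translation
#> [1] -17.636086   7.970761  88.546132
```

Build an annotation-driven view and resolve it against a (toy) structure:

```r
dir <- tempdir()
writeLines(toy_structure_1h9t()$mmcif, file.path(dir, "1h9t.cif"))
file.copy(system.file("extdata", "annotations-1h9t.cif", package = "mvspec"),
          file.path(dir, "annotations-1h9t.cif"))

doc <- demo_view_annotations(url = "./1h9t.cif")
state <- file.path(dir, "protocol2.mvsj")
writeLines(serialize_mvsj(doc), state)

scene <- flatten_scene(doc, mvs_fetcher("offline", base = state))
str(scene_summary(scene)[1:6])
#> List of 6
#>  $ n_structures     : int 1
#>  $ n_atoms          : int 491
#>  $ n_components     : int 3
#>  $ n_representations: int 3
#>  $ n_labels         : int 15
#>  $ n_tooltips       : int 15
```

Three components (Protein = chains A+B, DNA = C+D, ions = E/F/G/H/I) come
from the `components` category of the annotation file; the 22 rows of its
`annotations` category collapse to 15 label instances because the eleven
`Ligand binding site` rows share four `group_id` values while null-group
rows stay separate (so three separate `Chloride` labels). `scene_table()`
returns the flat per-atom table (coordinates, component membership, final
color after last-writer-wins layering, tooltip text).

Pack everything for drag-and-drop sharing:

```r
mvsx_pack(state, file.path(dir, c("annotations-1h9t.cif", "1h9t.cif")),
          out = file.path(dir, "protocol2.mvsx"))
```

To open a hosted state in a MolViewSpec-aware viewer, use
`https://molstar.org/viewer/?mvs-format={mvsj|mvsx}&mvs-url={URL}`.

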