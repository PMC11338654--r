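---
title: "Declarative molecular views: the data model and its resolution semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Declarative molecular views: the data model and its resolution semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvspec)
```

## The state-tree model

A view description is a metadata header plus a tree of typed nodes. The
grammar is small and strict:

| parent           | allowed children |
|------------------|------------------|
| root             | download, camera, canvas |
| download         | parse |
| parse            | structure |
| structure        | transform, component, component_from_uri/_from_source, label_from_uri/_from_source, tooltip_from_uri/_from_source |
| component(*)     | representation, label, tooltip, focus |
| representation   | color, color_from_uri, color_from_source |

Everything else is a leaf. Each kind carries a closed parameter record —
unknown keys are rejected both at construction and at parse time, so
format drift surfaces immediately rather than as silently ignored fields.
Value-level mistakes (say, a parse format outside `mmcif`/`bcif`/`pdb`)
are deliberately *not* exceptions during parsing: they are collected by
`validate_tree()` as data, with a node path, so a whole file can be
audited in one pass. The builder, by contrast, fails fast: a document
assembled through `mvs_builder()` verbs cannot violate the grammar, which
is the invariant the serialization round-trip fuzzing relies on.

Sibling order is semantic. Color layers apply in document order, multiple
transform children compose in document order, and the last camera or
canvas node wins. Nothing in the resolver sorts children.

### Serialization

MVSJ output uses a fixed key order (document: `metadata`, `root`; node:
`kind`, `params`, `children`; params in schema order) and a fixed number
format: the shortest decimal that round-trips through a double (15
significant digits when that parses back exactly, `%.17g` otherwise).
Consequently `serialize → parse → serialize` is byte-identical for a fixed
indent, which makes state files diffable and archives deterministic. The
format version is written as `"1"`; documents declaring a newer version
are refused with an explicit message rather than half-parsed.

## Selections

A component expression is a partial atom address over the `label_*` and
`auth_*` namespaces plus `type_symbol`, `atom_id` and the 0-based
`atom_index`. Matching is a conjunction: an atom matches when every *set*
field matches; unset fields are wildcards; `beg_*`/`end_*` ranges are
inclusive; a list of expressions is a union. An atom whose consulted field
is null (e.g. `label_seq_id` of a ligand) never matches a constraint on
that field. The test suite checks the vectorized matcher against a
deliberately naive per-atom scan on hundreds of random expressions.

Named selectors (`polymer`, `protein`, `nucleic`, `branched`, `ligand`,
`ion`, `water`, `all`) are entity-level classes: water and ions and
ligands partition the non-polymer entities, `protein`/`nucleic` are
polymer subsets keyed on the polymer type string. The monatomic-ion table
is embedded (NA, K, CL, MG, CA, ZN, FE, AU, ...) because coordinate files
do not flag ions as such; a non-polymer component outside that table is a
ligand.

## Annotation tables

An annotation table is a named column store — one CIF category (`loop_`)
or one JSON file. Independent-variable columns
(`label_entity_id` ... `atom_index`, `group_id`) select substructures;
any other column is a dependent value column. Conventions chosen where
the format description is silent:

* `?` is treated like `.` (both are standard CIF null markers).
* `group_id` values compare as **text** (`"1"` differs from `"01"`);
  grouping is first-appearance ordered, null-group rows stay singletons.
* a value column that collides with an independent column name is an
  error rather than a silent reinterpretation.
* multi-line semicolon text fields are outside the supported subset and
  produce a parse error pointing at the CIF specification.

The *schema* of an annotation reference decides which independent columns
are consulted: `chain` reads `label_entity_id` + `label_asym_id`,
`residue_range` adds the `beg`/`end` pair, `auth_*` schemas read only the
author namespace (plus insertion codes), `all_atomic` reads everything.
Null consulted cells widen the selection (a chain row with no residue
numbers selects the whole chain).

## Resolution semantics

`flatten_scene()` materializes a document against coordinates fetched
through an explicit fetcher contract (local disk, bundle member, or —
opt-in — http(s)). Decisions worth recording:

* **Model choice.** Only the first model of a multi-model file is
  resolved; model selection is out of scope.
* **Assemblies.** Operator expressions support plain lists (`"1,2"`) and
  ranges (`"1-60"`); parenthesized operator *products* are refused with an
  explicit unsupported-feature error rather than approximated. Expanded
  copies record their operator id and copy ordinal; `atom_index` is
  re-densified so downstream `atom_index`-based annotations address the
  expanded structure.
* **Transforms.** `x' = R x + t` with the 9-vector decoded column-major.
  Orthonormality is checked as `max |RᵀR − I|`: above `1e-3` a warning,
  above `1e-1` an error. The thresholds bracket honest numerical noise in
  published alignment matrices (the worked-example matrix has a defect of
  about `6e-11`) while refusing matrices that would shear the structure.
* **Colors.** Layers are collected per representation in document order,
  annotation rows in file order, and applied by sequential overwrite: the
  last covering layer wins; uncovered atoms stay unset. An inline color
  selector that reaches outside its component is intersected with the
  component and reported as a diagnostic — the alternative (coloring
  atoms the representation does not draw) has no visible meaning.
* **Labels/tooltips.** One instance per row group; the instance's atom
  set is the union of its rows' selections; groups that select nothing
  are dropped with a diagnostic, not an error, so partially matching
  annotation files still load.
* **Focus.** The format leaves concrete camera placement to viewers, so
  the resolver only *proposes* one: target = selection centroid, position
  = target + 2.5 · (bounding radius, floored at 1 Å) along +z, up =
  (0, 1, 0). The factor 2.5 comfortably frames a unit sphere under
  typical perspective fields of view; it is a documented stand-in, kept
  separate from explicitly authored camera nodes, which always win.
* **Empty selections** are warnings (diagnostics), not errors.

## Bundles

An MVSX bundle is a ZIP whose `index.mvsj` member is the state file;
relative references resolve to member paths (query strings rejected, no
escaping the archive root). The writer emits stored (uncompressed)
entries with zeroed DOS timestamps and name-sorted members, so packing is
deterministic and `pack → unpack → pack` is byte-identical — a property
the tests assert directly. Compression was deliberately traded away:
annotation and state files are small, and reproducible bytes are worth
more than a few kilobytes.

## The toy-structure generator

Tests and offline demos run on generated structures, not PDB downloads.
The generator emits mmCIF and legacy PDB renderings of the same atoms
with one atom per residue (CA for polypeptides, P for nucleotides, the
real heteroatom set for a heme, single atoms for ions/waters) on an
integer lattice `(atom ordinal, residue number, 10 × chain ordinal)` —
transforms and assembly operators are therefore checkable by hand. Entity
and polymer-type categories, assembly generators and operator matrices
are written explicitly. The same spec always produces identical bytes.

What this emulates: the addressing structure of real coordinate files —
both namespaces, entity records, null seq ids on heteroatoms, assemblies.
What it does not: realistic geometry, altlocs, insertion codes in use,
multi-character chain ids, occupancies, multi-model ensembles, or the
sheer scale of real entries. Passing tests therefore demonstrate correct
*bookkeeping*, not robustness to every quirk of archival files; the
structure readers are validated field-by-field against an independent
mmCIF reader on generated fixtures, which transfers to well-formed real
files but not to malformed ones.

The stand-ins for the demo entries (`toy_structure_1h9t()`,
`toy_structure_4hhb()`) copy only the chain layout of the originals
(chain ids, entity kinds, residue counts) — enough for every annotation
row to resolve — and are labelled synthetic throughout.

## Problem sizes and runtime

The property suites use 200 random documents for the serialization round
trip, 300 random expressions against the exhaustive per-atom oracle, 100
random color-layer stacks, 50 random rotations for the homogeneous-matrix
equivalence, and 20 generated structures for the independent-reader
comparison; toy structures run to ~500 atoms. These sizes were chosen so
the whole suite exercises every code path in about a minute on one core
while keeping the random-case counts large enough that a systematic
off-by-one (an exclusive range end, a missed null) would essentially
always be hit.

## Known limitations

* BinaryCIF (structures and annotations) is recognized but delegated: no
  codec ships with the package, so `bcif` inputs produce an explicit
  unsupported-format error.
* No rendering: representation types are carried as opaque tags; meshes,
  bonds and secondary structure are viewer concerns.
* Whether the reference viewer accepts this writer's MVSJ byte-for-byte
  is untested here; the format's own documentation remains authoritative
  for interoperability questions.
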