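Package: mvspec
Title: Build, Annotate, Resolve and Bundle Declarative Molecular Views
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the MolViewSpec declarative molecular-visualization
    format. Provides a grammar-aware fluent builder for view state trees,
    strict MVSJ (JSON) serialization and parsing, readers and writers for
    MolViewSpec annotation tables in CIF and JSON with the schema and
    group_id semantics, minimal mmCIF and legacy PDB structure readers with
    a deterministic toy-structure generator, a resolver that materializes a
    state document against coordinates into flat per-atom scene tables
    (selections, rigid-body transforms, assembly expansion, color layering,
    labels and tooltips), a deterministic MVSX (ZIP) bundle format, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'colors.R'
    'state-model.R'
    'mvsj.R'
    'builder.R'
    'cif.R'
    'annotation-io.R'
    'structure-io.R'
    'toy-structure.R'
    'resolver.R'
    'zip.R'
    'mvsx.R'
    'fetcher.R'
    'demos.R'
    'random.R'
    'cli.R'
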