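# end-to-end scene flattening against toy structures

local_annotation_dir <- function(env = parent.frame()) {
  dir <- tempfile("scene")
  dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE), envir = env)
  writeLines(sub("\n$", "", toy_structure_1h9t()$mmcif),
             file.path(dir, "1h9t.cif"))
  file.copy(system.file("extdata", "annotations-1h9t.cif",
                        package = "mvspec"),
            file.path(dir, "annotations-1h9t.cif"))
  dir
}

annotation_scene <- function(dir) {
  doc <- demo_view_annotations(url = "./1h9t.cif",
                               timestamp = "2024-01-01T00:00:00Z")
  state <- file.path(dir, "protocol2.mvsj")
  writeLines(sub("\n$", "", serialize_mvsj(doc)), state)
  list(doc = doc, state = state,
       scene = flatten_scene(doc, mvs_fetcher("offline", base = state)))
}

test_that("the annotation-driven view resolves to 3 components, no camera", {
  dir <- local_annotation_dir()
  sc <- annotation_scene(dir)$scene
  s <- scene_summary(sc)
  expect_identical(s$n_components, 3L)
  expect_identical(s$n_representations, 3L)
  expect_identical(s$n_labels, 15L)
  expect_identical(s$n_tooltips, 15L)
  expect_null(s$camera)
  expect_null(s$canvas)
  # component atom sets follow the component table: protein = chains A+B
  comps <- sc$structures[[1]]$components
  atoms <- sc$structures[[1]]$model$atoms
  expect_identical(sort(unique(atoms$label_asym_id[comps[[1]]$atoms])),
                   c("A", "B"))
  expect_identical(sort(unique(atoms$label_asym_id[comps[[3]]$atoms])),
                   c("E", "F", "G", "H", "I"))
})

test_that("annotation colors layer in file order over each representation", {
  dir <- local_annotation_dir()
  sc <- annotation_scene(dir)$scene
  tab <- scene_table(sc)
  pick <- function(chain, seq) {
    tab$color[tab$label_asym_id == chain &
                (is.na(tab$label_seq_id) | tab$label_seq_id == seq)][1]
  }
  expect_identical(pick("A", 9), "#dd6600")
  expect_identical(pick("A", 57), "red")     # later row overwrites
  expect_identical(pick("A", 84), "#008800")
  expect_identical(pick("C", 1), "#1100aa")
  expect_identical(pick("F", 1), "#00dd00")
  expect_identical(tab$color[tab$label_asym_id == "A" &
                               tab$label_seq_id == 1][1], NA_character_)
})

test_that("a document with no representations yields empty color tables", {
  dir <- tempfile("empty"); dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE))
  writeLines(sub("\n$", "", make_toy_structure(toy_two_chain_spec())$mmcif),
             file.path(dir, "toy.cif"))
  b <- mvs_builder(timestamp = "2024-01-01T00:00:00Z")
  b |> mvs_download("./toy.cif") |> mvs_parse("mmcif") |>
    mvs_model_structure() |> mvs_component("polymer")
  doc <- mvs_document(b)
  scene <- flatten_scene(doc, mvs_fetcher("offline",
                                          base = file.path(dir, "x.mvsj")))
  expect_identical(scene_summary(scene)$n_representations, 0L)
  expect_true(all(is.na(scene_table(scene)$color)))
})

test_that("_from_source equals _from_uri given the table embedded in the CIF", {
  dir <- tempfile("src"); dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE))
  # embed the annotation block into the structure file itself
  toy <- toy_structure_1h9t()$mmcif
  combined <- paste0(toy, sp2_annotation_text(), "\n")
  writeLines(sub("\n$", "", combined), file.path(dir, "1h9t.cif"))
  file.copy(system.file("extdata", "annotations-1h9t.cif",
                        package = "mvspec"),
            file.path(dir, "annotations-1h9t.cif"))
  state <- file.path(dir, "s.mvsj")

  build <- function(from_source) {
    b <- mvs_builder(timestamp = "2024-01-01T00:00:00Z")
    s <- b |> mvs_download("./1h9t.cif") |> mvs_parse("mmcif") |>
      mvs_model_structure()
    comp <- if (from_source) {
      mvs_component_from_source(s, schema = "chain",
                                block_header = "1h9t_annotations",
                                category_name = "components",
                                field_values = "Protein")
    } else {
      mvs_component_from_uri(s, uri = "./annotations-1h9t.cif",
                             format = "cif", schema = "chain",
                             block_header = "1h9t_annotations",
                             category_name = "components",
                             field_values = "Protein")
    }
    rep_ <- mvs_representation(comp, "cartoon")
    if (from_source) {
      mvs_color_from_source(rep_, schema = "residue_range",
                            block_header = "1h9t_annotations",
                            category_name = "annotations")
      mvs_label_from_source(s, schema = "residue_range",
                            block_header = "1h9t_annotations",
                            category_name = "annotations")
    } else {
      mvs_color_from_uri(rep_, uri = "./annotations-1h9t.cif",
                         format = "cif", schema = "residue_range",
                         block_header = "1h9t_annotations",
                         category_name = "annotations")
      mvs_label_from_uri(s, uri = "./annotations-1h9t.cif", format = "cif",
                         schema = "residue_range",
                         block_header = "1h9t_annotations",
                         category_name = "annotations")
    }
    mvs_document(b)
  }
  fetcher <- mvs_fetcher("offline", base = state)
  sc_uri <- flatten_scene(build(FALSE), fetcher)
  sc_src <- flatten_scene(build(TRUE), fetcher)
  tab_uri <- scene_table(sc_uri)
  tab_src <- scene_table(sc_src)
  tab_uri$components <- tab_src$components <- NULL  # paths differ by kind
  expect_identical(tab_src, tab_uri)
  expect_identical(length(sc_src$labels), length(sc_uri$labels))
})

test_that("inline labels/tooltips and camera/canvas land in the scene", {
  dir <- tempfile("bp3"); dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE))
  writeLines(sub("\n$", "", toy_structure_4hhb()$mmcif),
             file.path(dir, "4hhb.cif"))
  doc <- demo_view_labels(url = "./4hhb.cif",
                          timestamp = "2024-01-01T00:00:00Z")
  scene <- flatten_scene(doc, mvs_fetcher("offline",
                                          base = file.path(dir, "s.mvsj")))
  s <- scene_summary(scene)
  expect_identical(s$n_labels, 1L)
  expect_identical(s$n_tooltips, 1L)
  expect_identical(scene$labels[[1]]$text, "Iron Ion")
  expect_length(scene$labels[[1]]$atoms, 1L)
  expect_identical(s$canvas$background_color, "#ffcf6b")
  expect_identical(s$camera$target, c(18, 18, 24))
  # the iron recolor wins over the white base coat on that atom
  tab <- scene_table(scene)
  fe <- tab$label_atom_id == "FE" & tab$label_asym_id == "E"
  expect_identical(unique(tab$color[fe]), "#ff4500")
  expect_identical(unique(tab$color[tab$label_asym_id == "E" & !fe]),
                   "#ffffff")
})

test_that("focus proposes a camera over the component's bounding sphere", {
  dir <- tempfile("focus"); dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE))
  writeLines(sub("\n$", "", make_toy_structure(toy_two_chain_spec())$mmcif),
             file.path(dir, "toy.cif"))
  b <- mvs_builder(timestamp = "2024-01-01T00:00:00Z")
  comp <- b |> mvs_download("./toy.cif") |> mvs_parse("mmcif") |>
    mvs_model_structure() |> mvs_component("all")
  mvs_focus(comp)
  scene <- flatten_scene(mvs_document(b),
                         mvs_fetcher("offline",
                                     base = file.path(dir, "s.mvsj")))
  fc <- scene$focus_camera
  expect_false(is.null(fc))
  atoms <- scene$structures[[1]]$model$atoms
  expect_equal(fc$target,
               unname(colMeans(as.matrix(atoms[, c("x", "y", "z")]))))
  expect_gt(sum((fc$position - fc$target)^2), 0)
})

test_that("structure transforms compose in document order", {
  dir <- tempfile("tr"); dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE))
  writeLines(sub("\n$", "", make_toy_structure(toy_two_chain_spec())$mmcif),
             file.path(dir, "toy.cif"))
  rot_z <- c(0, 1, 0, -1, 0, 0, 0, 0, 1)  # 90 degrees about z
  b <- mvs_builder(timestamp = "2024-01-01T00:00:00Z")
  s <- b |> mvs_download("./toy.cif") |> mvs_parse("mmcif") |>
    mvs_model_structure()
  s <- mvs_transform(s, rotation = rot_z)
  s <- mvs_transform(s, translation = c(5, 0, 0))
  scene <- flatten_scene(mvs_document(b),
                         mvs_fetcher("offline",
                                     base = file.path(dir, "s.mvsj")))
  raw <- parse_structure_mmcif(
    paste(readLines(file.path(dir, "toy.cif")), collapse = "\n"))
  want <- apply_transform(apply_transform(
    as.matrix(raw$atoms[, c("x", "y", "z")]), rotation = rot_z),
    translation = c(5, 0, 0))
  got <- as.matrix(scene$structures[[1]]$model$atoms[, c("x", "y", "z")])
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("fetch failures name the URI and scenario", {
  f_off <- mvs_fetcher("offline", base = tempdir())
  expect_error(fetch_resource(f_off, "https://example.org/a.cif"),
               "remote fetch disabled.*https://example.org/a.cif")
  expect_error(fetch_resource(f_off, "./nope.cif"), "nope.cif")
  f_web <- mvs_fetcher("offline", base = tempdir(), allow_disk = FALSE)
  expect_error(fetch_resource(f_web, "./x.cif"), "MVSX bundle")
})
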