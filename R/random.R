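# Random grammar-valid document generator, used for fuzzing the
# serialization round trip.  Built through the builder, so every generated
# document is valid by construction.

rand_expr <- function() {
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
    fields$label_atom_id <- sample(c("CA", "P", "FE", "CL", "O"), 1L)
  }
  if (stats::runif(1) < 0.2) {
    fields$type_symbol <- sample(c("C", "P", "FE", "N", "CL", "O"), 1L)
  }
  if (stats::runif(1) < 0.2) fields$auth_seq_id <- sample.int(8L, 1L)
  if (stats::runif(1) < 0.15) fields$atom_index <- sample.int(20L, 1L) - 1L
  if (stats::runif(1) < 0.15) fields$atom_id <- sample.int(20L, 1L)
  do.call(mvs_expression, fields)
}

rand_selector <- function() {
  u <- stats::runif(1)
  if (u < 0.3) {
    sample(named_selectors, 1L)
  } else if (u < 0.7) {
    rand_expr()
  } else {
    lapply(seq_len(sample.int(3L, 1L)), function(i) rand_expr())
  }
}

rand_color <- function() {
  if (stats::runif(1) < 0.5) {
    sprintf("#%06x", sample.int(16777216L, 1L) - 1L)
  } else {
    sample(svg_color_keywords, 1L)
  }
}

rand_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  as.vector(Q)
}

#' Generate a random grammar-valid state document
#'
#' Draws node counts, selectors, colors, transforms and camera settings
#' from R's RNG (seed with [set.seed()] for reproducibility). Useful for
#' property-style testing of the serialization round trip; every output
#' passes [validate_tree()].
#'
#' @return an `mvs_state` document.
#' @export
random_state_document <- function() {
  b <- mvs_builder(timestamp = "2024-01-01T00:00:00Z")
  for (di in seq_len(sample.int(2L, 1L))) {
    s <- b |>
      mvs_download(sprintf("https://example.org/%d.cif", di)) |>
      mvs_parse(sample(parse_formats, 1L))
    s <- if (stats::runif(1) < 0.5) {
      mvs_model_structure(s)
    } else {
      mvs_assembly_structure(s, assembly_id = as.character(sample.int(3L, 1L)))
    }
    if (stats::runif(1) < 0.4) {
      s <- mvs_transform(s, rotation = rand_rotation(),
                         translation = stats::rnorm(3) * 10)
    }
    for (ci in seq_len(sample.int(3L, 1L))) {
      comp <- mvs_component(s, rand_selector())
      if (stats::runif(1) < 0.3) mvs_label(comp, paste("label", ci))
      if (stats::runif(1) < 0.3) mvs_tooltip(comp, paste("tip", ci))
      if (stats::runif(1) < 0.2) mvs_focus(comp)
      for (ri in seq_len(sample.int(2L, 1L) - (stats::runif(1) < 0.3))) {
        rep_ <- mvs_representation(comp, sample(representation_types, 1L))
        for (li in seq_len(sample.int(3L, 1L) - 1L)) {
          mvs_color(rep_, rand_color(),
                    selector = if (stats::runif(1) < 0.5) rand_selector())
        }
        if (stats::runif(1) < 0.2) {
          mvs_color_from_uri(rep_, uri = "./ann.cif", format = "cif",
                             schema = sample(annotation_schemas, 1L))
        }
      }
    }
    if (stats::runif(1) < 0.3) {
      mvs_component_from_uri(s, uri = "./ann.cif", format = "cif",
                             schema = "chain",
                             field_values = c("Protein", "DNA"))
    }
    if (stats::runif(1) < 0.2) {
      mvs_label_from_uri(s, uri = "./ann.cif", format = "cif",
                         schema = "residue_range")
    }
  }
  if (stats::runif(1) < 0.4) mvs_canvas(b, rand_color())
  if (stats::runif(1) < 0.4) {
    mvs_camera(b, target = stats::rnorm(3), position = stats::rnorm(3) + 20)
  }
  mvs_document(b)
}
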