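# ---------------------------------------------------------------------------
# MVSX bundles: a ZIP archive whose member "index.mvsj" is the state file
# and whose other members are the assets its relative URI references point
# to.  Plus URI-reference resolution across the deployment scenarios
# (served over http(s), loaded from disk, packed in a bundle).
# ---------------------------------------------------------------------------

has_uri_scheme <- function(x) grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x)

normalize_rel_path <- function(p, what = "URI reference") {
  parts <- strsplit(p, "/", fixed = TRUE)[[1]]
  out <- character(0)
  for (seg in parts) {
    if (seg == "" || seg == ".") next
    if (seg == "..") {
      if (!length(out)) {
        mvs_stop(what, " '", p, "' escapes its base directory",
                 class = "mvs_uri_error")
      }
      out <- out[-length(out)]
    } else {
      out <- c(out, seg)
    }
  }
  paste(out, collapse = "/")
}

#' Resolve a URI reference against a base
#'
#' Absolute references are returned unchanged. Relative references are
#' joined to the base state file's directory; inside a bundle they resolve
#' to a member path (query strings are rejected there, and references may
#' not escape the bundle).
#'
#' @param reference the URI reference (e.g. `"./annotations-1h9t.cif"`).
#' @param base a state-file location (path or URL) or an `mvs_bundle`.
#' @return the absolute location: a URL, a file path, or (for a bundle)
#'   `list(member = <archive path>)`.
#' @examples
#' resolve_uri("./annotations-1h9t.cif", "https://example.org/view.mvsj")
#' @export
resolve_uri <- function(reference, base = NULL) {
  if (!is_string(reference) || !nzchar(reference)) {
    mvs_stop("URI reference must be a non-empty string",
             class = "mvs_uri_error")
  }
  if (has_uri_scheme(reference)) return(reference)
  if (inherits(base, "mvs_bundle")) {
    if (grepl("[?#]", reference)) {
      mvs_stop("query strings / fragments are not supported inside a ",
               "bundle: '", reference, "'", class = "mvs_uri_error")
    }
    if (startsWith(reference, "/")) {
      mvs_stop("absolute paths are not valid bundle references: '",
               reference, "'", class = "mvs_uri_error")
    }
    return(list(member = normalize_rel_path(reference)))
  }
  if (is.null(base)) return(reference)
  stopifnot(is_string(base))
  if (has_uri_scheme(base)) {
    m <- regexec("^([A-Za-z][A-Za-z0-9+.-]*://[^/]*)(/.*)?$", base)[[1]]
    origin <- regmatches(base, regexec(
      "^([A-Za-z][A-Za-z0-9+.-]*://[^/]*)", base))[[1]][2]
    path <- substring(base, nchar(origin) + 1L)
    dir <- sub("[^/]*$", "", path)
    if (startsWith(reference, "/")) {
      return(paste0(origin, "/", normalize_rel_path(reference)))
    }
    joined <- normalize_rel_path(paste0(dir, "/", reference))
    return(paste0(origin, "/", joined))
  }
  dir <- dirname(base)
  if (startsWith(reference, "/")) return(reference)
  file.path(dir, normalize_rel_path(reference))
}

# relative URI references (download urls and annotation uris) in a document
collect_relative_refs <- function(doc) {
  walk2 <- function(node) {
    out <- character(0)
    for (key in c("url", "uri")) {
      v <- node$params[[key]]
      if (!is.null(v) && !has_uri_scheme(v)) out <- c(out, v)
    }
    c(out, unlist(lapply(node$children, walk2)))
  }
  unique(walk2(doc$root) %||% character(0))
}

#' Pack a state file and its assets into an MVSX bundle
#'
#' The archive is deterministic (stored entries, zeroed timestamps, sorted
#' member order): the same inputs always give identical bytes. Every
#' relative URI reference in the state must resolve to a packed asset.
#'
#' @param state_path path to the `.mvsj` state file (becomes member
#'   `index.mvsj`).
#' @param asset_paths paths to asset files (archived under their base
#'   names).
#' @param out optional output path (`.mvsx`); when given the bytes are also
#'   written there.
#' @return raw vector of archive bytes (invisibly when `out` is given).
#' @export
mvsx_pack <- function(state_path, asset_paths = character(0), out = NULL) {
  state_bytes <- readBin(state_path, "raw", n = file.info(state_path)$size)
  doc <- parse_mvsj(rawToChar(state_bytes))
  members <- list("index.mvsj" = state_bytes)
  for (p in asset_paths) {
    if (!file.exists(p)) mvs_stop("asset not found: ", p)
    members[[basename(p)]] <- readBin(p, "raw", n = file.info(p)$size)
  }
  refs <- collect_relative_refs(doc)
  dangling <- refs[!vapply(refs, function(r) {
    normalize_rel_path(r) %in% names(members)
  }, logical(1))]
  if (length(dangling)) {
    mvs_stop("relative reference(s) with no matching asset: ",
             paste(dangling, collapse = ", "),
             class = "mvs_pack_error")
  }
  bytes <- zip_build(members)
  if (!is.null(out)) {
    writeBin(bytes, out)
    return(invisible(bytes))
  }
  bytes
}

#' Unpack an MVSX bundle
#'
#' @param x archive bytes (raw) or a path to an `.mvsx` file.
#' @return an `mvs_bundle`: `list(index = <parsed state document>,
#'   index_text, assets = <named list of raw member bytes>)`.
#' @export
mvsx_unpack <- function(x) {
  members <- zip_extract(x)
  if (!("index.mvsj" %in% names(members))) {
    mvs_stop("not an MVSX bundle: no member named 'index.mvsj' (members: ",
             paste(names(members), collapse = ", "), ")",
             class = "mvs_bundle_error")
  }
  index_text <- rawToChar(members[["index.mvsj"]])
  structure(list(index = parse_mvsj(index_text),
                 index_text = index_text,
                 assets = members[setdiff(names(members), "index.mvsj")]),
            class = "mvs_bundle")
}
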