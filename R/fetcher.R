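# ---------------------------------------------------------------------------
# Resource fetching contract: URI -> bytes, across the deployment
# scenarios (local disk, MVSX bundle member, remote http(s)).
# ---------------------------------------------------------------------------

#' Create a resource fetcher
#'
#' @param mode `"offline"`/`"local"` read only from disk (and bundle);
#'   `"remote"` additionally allows http(s) URLs.
#' @param base location the state file was loaded from (directory path or
#'   URL); relative references resolve against it.
#' @param bundle optional `mvs_bundle`; relative references then resolve to
#'   bundle members.
#' @param allow_disk set `FALSE` to emulate contexts without disk access
#'   (web viewers cannot read local files next to a dropped state file;
#'   bundles exist to work around that).
#' @return an `mvs_fetcher` for [fetch_resource()] / [flatten_scene()].
#' @export
mvs_fetcher <- function(mode = c("local", "offline", "remote"), base = NULL,
                        bundle = NULL, allow_disk = TRUE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, base = base, bundle = bundle,
                 allow_disk = isTRUE(allow_disk)),
            class = "mvs_fetcher")
}

read_file_raw <- function(path) {
  readBin(path, "raw", n = file.info(path)$size)
}

#' Fetch the bytes behind a URI reference
#'
#' @param fetcher an [mvs_fetcher()].
#' @param uri absolute URI or reference relative to the fetcher's base /
#'   bundle.
#' @return raw vector of bytes. Errors name the URI and the scenario that
#'   failed (wrong location, remote fetch disabled, disk access disallowed,
#'   missing bundle member).
#' @export
fetch_resource <- function(fetcher, uri) {
  stopifnot(inherits(fetcher, "mvs_fetcher"))
  resolved <- resolve_uri(uri, fetcher$bundle %||% fetcher$base)
  if (is.list(resolved)) {  # bundle member
    member <- resolved$member
    if (identical(member, "index.mvsj")) {
      return(charToRaw(fetcher$bundle$index_text))
    }
    bytes <- fetcher$bundle$assets[[member]]
    if (is.null(bytes)) {
      mvs_stop("bundle has no member '", member, "' (referenced as '", uri,
               "'); members: ",
               paste(names(fetcher$bundle$assets), collapse = ", "),
               class = "mvs_fetch_error")
    }
    return(bytes)
  }
  if (grepl("^https?://", resolved)) {
    if (fetcher$mode != "remote") {
      mvs_stop("remote fetch disabled (", fetcher$mode, " mode): '", uri,
               "'. Host the file locally, pack it into an MVSX bundle, or ",
               "enable remote fetching; remote servers must also send CORS ",
               "headers for browser viewers.", class = "mvs_fetch_error")
    }
    con <- url(resolved, open = "rb")
    on.exit(close(con), add = TRUE)
    chunks <- list()
    repeat {
      chunk <- readBin(con, "raw", n = 65536L)
      if (!length(chunk)) break
      chunks[[length(chunks) + 1L]] <- chunk
    }
    return(do.call(c, chunks) %||% raw(0))
  }
  path <- sub("^file://", "", resolved)
  if (!fetcher$allow_disk) {
    mvs_stop("local file access is not permitted in this context: '", uri,
             "'. Browsers do not allow a dropped state file to read other ",
             "files from disk; pack the assets into an MVSX bundle instead.",
             class = "mvs_fetch_error")
  }
  if (!file.exists(path)) {
    mvs_stop("file not found: '", path, "' (referenced as '", uri,
             "'). Check that the URI points at the intended location.",
             class = "mvs_fetch_error")
  }
  read_file_raw(path)
}

#' Flatten the state document inside a bundle
#'
#' Convenience wrapper: resolves the bundle's `index.mvsj` with a fetcher
#' bound to the bundle's members.
#'
#' @param bundle an `mvs_bundle` from [mvsx_unpack()].
#' @param mode fetch mode for non-bundle (absolute) references.
#' @return an `mvs_scene`.
#' @export
flatten_bundle <- function(bundle, mode = "offline") {
  stopifnot(inherits(bundle, "mvs_bundle"))
  flatten_scene(bundle$index, mvs_fetcher(mode, bundle = bundle))
}
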