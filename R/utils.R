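`%||%` <- function(x, y) if (is.null(x)) y else x

mvs_stop <- function(..., class = "mvs_error", call. = FALSE) {
  stop(structure(
    class = c(class, "mvs_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

mvs_warn <- function(...) warning(paste0(...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_number_vec <- function(x, n) {
  is.numeric(x) && length(x) == n && all(is.finite(x))
}

#' @noRd
max_abs <- function(m) max(abs(m))

# sup-norm distance of t(R) %*% R from the identity; gauges orthonormality
rotation_orthonormality_defect <- function(rotation) {
  R <- matrix(as.double(rotation), 3L, 3L)  # column-major, as stored
  max_abs(crossprod(R) - diag(3))
}

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub('"', '\\"', s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  for (code in c(1:8, 11L, 12L, 14:31)) {
    ch <- intToUtf8(code)
    if (any(grepl(ch, s, fixed = TRUE))) {
      s <- gsub(ch, sprintf("\\u%04x", code), s, fixed = TRUE)
    }
  }
  s
}

# shortest decimal that round-trips through double; keeps serialization
# byte-stable across serialize -> parse -> serialize
json_number <- function(v) {
  vapply(v, function(x) {
    if (is.na(x)) return("null")
    if (x == floor(x) && abs(x) < 2^53) {
      s <- sprintf("%.0f", x)
      return(s)
    }
    s <- as.character(x)                 # 15 significant digits
    if (as.numeric(s) != x) s <- sprintf("%.17g", x)
    s
  }, character(1))
}
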