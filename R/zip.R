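# ---------------------------------------------------------------------------
# Minimal deterministic ZIP container: stored (uncompressed) entries,
# zeroed DOS timestamps, members sorted by name, so identical inputs give
# identical archive bytes.  Reading delegates to utils::unzip.
# ---------------------------------------------------------------------------

# 32-bit xor on doubles (R integers are signed 32-bit)
xor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

crc32_table <- local({
  tab <- numeric(256)
  poly <- 3988292384  # 0xEDB88320
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      odd <- c %% 2
      c <- floor(c / 2)
      if (odd == 1) c <- xor32(c, poly)
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- 4294967295  # 0xFFFFFFFF
  ints <- as.integer(bytes)
  for (b in ints) {
    idx <- bitwXor(as.integer(crc %% 256), b)
    crc <- xor32(crc32_table[idx + 1], floor(crc / 256))
  }
  xor32(crc, 4294967295)
}

u16_raw <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
u32_raw <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

# members: named list of raw vectors; returns archive bytes
zip_build <- function(members) {
  stopifnot(is.list(members), !is.null(names(members)),
            all(nzchar(names(members))))
  nms <- sort(names(members))
  locals <- list()
  centrals <- list()
  offset <- 0
  # fixed DOS date 1980-01-01, time 00:00 (the format's epoch)
  dos_time <- u16_raw(0); dos_date <- u16_raw(33)
  for (nm in nms) {
    data <- members[[nm]]
    stopifnot(is.raw(data))
    name_raw <- charToRaw(nm)
    crc <- crc32(data)
    sz <- length(data)
    hdr <- c(u32_raw(67324752),            # local header signature
             u16_raw(20), u16_raw(0), u16_raw(0),  # version, flags, stored
             dos_time, dos_date, u32_raw(crc), u32_raw(sz), u32_raw(sz),
             u16_raw(length(name_raw)), u16_raw(0))
    locals[[nm]] <- c(hdr, name_raw, data)
    centrals[[nm]] <- c(u32_raw(33639248), # central header signature
                        u16_raw(20), u16_raw(20), u16_raw(0), u16_raw(0),
                        dos_time, dos_date, u32_raw(crc), u32_raw(sz),
                        u32_raw(sz), u16_raw(length(name_raw)), u16_raw(0),
                        u16_raw(0), u16_raw(0), u16_raw(0), u32_raw(0),
                        u32_raw(offset), name_raw)
    offset <- offset + length(locals[[nm]])
  }
  central <- do.call(c, unname(centrals)) %||% raw(0)
  eocd <- c(u32_raw(101010256), u16_raw(0), u16_raw(0),
            u16_raw(length(nms)), u16_raw(length(nms)),
            u32_raw(length(central)), u32_raw(offset), u16_raw(0))
  c(do.call(c, unname(locals)) %||% raw(0), central, eocd)
}

# returns named list of raw vectors
zip_extract <- function(x) {
  path <- if (is.raw(x)) {
    tf <- tempfile(fileext = ".zip")
    writeBin(x, tf)
    tf
  } else {
    stopifnot(is_string(x))
    x
  }
  info <- tryCatch(utils::unzip(path, list = TRUE), error = function(e) {
    mvs_stop("not a readable ZIP archive: ", conditionMessage(e),
             class = "mvs_zip_error")
  })
  nms <- info$Name
  nms <- nms[!endsWith(nms, "/")]  # skip directory entries
  if (any(grepl("^/", nms)) || any(grepl("(^|/)\\.\\.(/|$)", nms))) {
    mvs_stop("archive member path escapes the archive root: ",
             paste(nms[grepl("^/|(^|/)\\.\\.(/|$)", nms)], collapse = ", "),
             class = "mvs_zip_security_error")
  }
  exdir <- tempfile("zipx")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  utils::unzip(path, exdir = exdir)
  out <- lapply(nms, function(nm) {
    f <- file.path(exdir, nm)
    readBin(f, "raw", n = file.info(f)$size)
  })
  names(out) <- nms
  out
}
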