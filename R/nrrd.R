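# Minimal NRRD0004 reader/writer: axis-aligned geometry, raw or gzip
# encoding, scalar 3D grids and 3-component vector grids. Covers what
# this package exchanges with 3D Slicer-style pipelines; arbitrary
# space-direction matrices are rejected rather than silently sheared.

nrrd_types <- list(
  "signed char" = list(what = "integer", size = 1L, signed = TRUE),
  "int8" = list(what = "integer", size = 1L, signed = TRUE),
  "uchar" = list(what = "integer", size = 1L, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1L, signed = FALSE),
  "uint8" = list(what = "integer", size = 1L, signed = FALSE),
  "short" = list(what = "integer", size = 2L, signed = TRUE),
  "int16" = list(what = "integer", size = 2L, signed = TRUE),
  "ushort" = list(what = "integer", size = 2L, signed = FALSE),
  "unsigned short" = list(what = "integer", size = 2L, signed = FALSE),
  "uint16" = list(what = "integer", size = 2L, signed = FALSE),
  "int" = list(what = "integer", size = 4L, signed = TRUE),
  "int32" = list(what = "integer", size = 4L, signed = TRUE),
  "uint" = list(what = "integer", size = 4L, signed = FALSE),
  "uint32" = list(what = "integer", size = 4L, signed = FALSE),
  "float" = list(what = "numeric", size = 4L, signed = TRUE),
  "double" = list(what = "numeric", size = 8L, signed = TRUE)
)

parse_nrrd_vectors <- function(txt) {
  # "(a,b,c) (d,e,f) ..." with "none" entries allowed -> list of numeric/NULL
  toks <- regmatches(txt, gregexpr("\\([^)]*\\)|none", txt))[[1]]
  lapply(toks, function(t) {
    if (identical(t, "none")) return(NULL)
    as.numeric(strsplit(gsub("[()]", "", t), ",")[[1]])
  })
}

read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header is text up to the first blank line
  nl <- which(bytes == as.raw(10L))
  sep <- NA_integer_
  prev <- 0L
  for (p in nl) {
    seg <- if (p - prev > 1L) bytes[(prev + 1L):(p - 1L)] else raw(0)
    seg <- seg[seg != as.raw(13L)]
    if (length(seg) == 0L && prev > 0L) { sep <- p; break }
    prev <- p
  }
  if (is.na(sep)) stop("truncated NRRD header (no blank line)", call. = FALSE)
  lines <- strsplit(rawToChar(bytes[seq_len(sep - 1L)]), "\r?\n")[[1]]
  if (!grepl("^NRRD000[1-5]$", lines[1])) {
    stop("not an NRRD file: ", path, call. = FALSE)
  }
  fields <- list()
  for (line in lines[-1]) {
    if (line == "" || startsWith(line, "#")) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) != 3) stop("malformed NRRD header line: ", line, call. = FALSE)
    fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  type <- fields[["type"]]
  if (is.null(type) || is.null(nrrd_types[[type]])) {
    stop("unsupported NRRD type: ", type %||% "<missing>", call. = FALSE)
  }
  tinfo <- nrrd_types[[type]]
  ndim <- as.integer(fields[["dimension"]])
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != ndim) stop("NRRD sizes/dimension mismatch", call. = FALSE)
  endian <- fields[["endian"]] %||% "little"
  encoding <- fields[["encoding"]] %||% "raw"
  n <- prod(sizes)
  payload <- bytes[(sep + 1L):length(bytes)]
  if (encoding %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    stop("unsupported NRRD encoding: ", encoding, call. = FALSE)
  }
  if (length(payload) < n * tinfo$size) {
    stop("truncated NRRD data", call. = FALSE)
  }
  vals <- readBin(payload, tinfo$what, n = n, size = tinfo$size,
                  signed = if (tinfo$size >= 4L) TRUE else tinfo$signed,
                  endian = endian)
  data <- array(vals, sizes)

  kinds <- if (!is.null(fields[["kinds"]])) {
    strsplit(fields[["kinds"]], "\\s+")[[1]]
  } else {
    rep("domain", ndim)
  }
  domain_axes <- which(kinds == "domain")
  spacing <- NULL
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    dirs <- dirs[!vapply(dirs, is.null, logical(1))]
    if (length(dirs) != 3) stop("expected 3 domain space directions", call. = FALSE)
    dmat <- do.call(cbind, dirs)
    if (any(abs(dmat - diag(diag(dmat))) > 1e-9) || any(diag(dmat) <= 0)) {
      stop("only axis-aligned, positively oriented NRRD space directions are supported",
           call. = FALSE)
    }
    spacing <- diag(dmat)
  } else if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    spacing <- sp[domain_axes]
  }
  if (is.null(spacing) || anyNA(spacing)) {
    stop("NRRD header carries no voxel spacing metadata", call. = FALSE)
  }
  origin <- if (!is.null(fields[["space origin"]])) {
    parse_nrrd_vectors(fields[["space origin"]])[[1]]
  } else {
    c(0, 0, 0)
  }
  list(data = data, spacing = spacing, origin = origin, kinds = kinds,
       type = type)
}

write_nrrd <- function(data, path, spacing, origin, type,
                       kinds = rep("domain", length(dim(data)))) {
  tinfo <- nrrd_types[[type]]
  if (is.null(tinfo)) stop("unsupported NRRD type: ", type, call. = FALSE)
  sizes <- dim(data)
  dom <- 0L
  dir_str <- character(length(sizes))
  for (a in seq_along(sizes)) {
    if (kinds[a] != "domain") {
      dir_str[a] <- "none"
    } else {
      dom <- dom + 1L
      d <- c(0, 0, 0)
      d[dom] <- spacing[dom]
      dir_str[a] <- sprintf("(%.17g,%.17g,%.17g)", d[1], d[2], d[3])
    }
  }
  header <- c(
    "NRRD0004",
    "# written by ffdseg",
    paste0("type: ", type),
    paste0("dimension: ", length(sizes)),
    paste0("sizes: ", paste(sizes, collapse = " ")),
    "space: right-anterior-superior",
    paste0("space directions: ", paste(dir_str, collapse = " ")),
    paste0("kinds: ", paste(kinds, collapse = " ")),
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.17g,%.17g,%.17g)", origin[1], origin[2], origin[3]),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  vals <- as.vector(data)
  vals <- if (tinfo$what == "integer") as.integer(vals) else as.numeric(vals)
  writeBin(vals, con, size = tinfo$size, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
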