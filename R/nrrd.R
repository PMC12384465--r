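# Minimal NRRD support: 3-D scalar data, attached ("NRRD000X" + header +
# blob in one file), raw or gzip encodings, little-endian. Covers the
# subset of the format the pipeline exchanges; anything else is rejected
# with a clear error rather than guessed at.

nrrd_type_map <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8" = list(what = "integer", size = 1, signed = TRUE),
  "uchar" = list(what = "integer", size = 1, signed = FALSE),
  "uint8" = list(what = "integer", size = 1, signed = FALSE),
  "short" = list(what = "integer", size = 2, signed = TRUE),
  "int16" = list(what = "integer", size = 2, signed = TRUE),
  "ushort" = list(what = "integer", size = 2, signed = FALSE),
  "uint16" = list(what = "integer", size = 2, signed = FALSE),
  "int" = list(what = "integer", size = 4, signed = TRUE),
  "int32" = list(what = "integer", size = 4, signed = TRUE),
  "float" = list(what = "numeric", size = 4, signed = TRUE),
  "double" = list(what = "numeric", size = 8, signed = TRUE))

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000[0-9]$", magic))
    stop_pericor("not an NRRD file: ", path, class = "pericor_io_error")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop_pericor("truncated NRRD header: ", path,
                   class = "pericor_io_error")
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  dimension <- as.integer(fields$dimension)
  if (is.na(dimension) || dimension != 3L)
    stop_pericor("only 3-D NRRD volumes are supported",
                 class = "pericor_format_error")
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  type <- nrrd_type_map[[fields$type]]
  if (is.null(type))
    stop_pericor("unsupported NRRD type: ", fields$type,
                 class = "pericor_format_error")
  encoding <- fields$encoding %||% "raw"
  endian <- if (!is.null(fields$endian)) fields$endian else "little"

  spacing <- origin <- NULL
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    M <- do.call(cbind, dirs)
    if (any(abs(M[row(M) != col(M)]) > 1e-6 * max(abs(diag(M)))))
      stop_pericor("oblique NRRD space directions are not supported",
                   class = "pericor_format_error")
    spacing <- abs(diag(M))
  } else if (!is.null(fields$spacings)) {
    spacing <- abs(as.numeric(strsplit(fields$spacings, "\\s+")[[1]]))
  } else spacing <- c(1, 1, 1)
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  else origin <- c(0, 0, 0)

  n <- prod(sizes)
  raw_data <- readBin(con, "raw", n = n * type$size * 4 + 1024L)
  if (identical(encoding, "gzip")) raw_data <- memDecompress(raw_data, "gzip")
  else if (!identical(encoding, "raw"))
    stop_pericor("unsupported NRRD encoding: ", encoding,
                 class = "pericor_format_error")
  vals <- readBin(raw_data, type$what, n = n, size = type$size,
                  signed = type$signed,
                  endian = if (endian == "big") "big" else "little")
  if (length(vals) != n)
    stop_pericor("NRRD data shorter than header sizes: ", path,
                 class = "pericor_io_error")
  list(voxels = array(as.numeric(vals), dim = sizes),
       spacing = spacing, origin = origin)
}

parse_nrrd_vectors <- function(s) {
  toks <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(toks, function(t)
    as.numeric(strsplit(gsub("[()]", "", t), ",")[[1]]))
}

write_nrrd <- function(voxels, spacing, origin, path, type = "double",
                       encoding = "gzip") {
  tp <- nrrd_type_map[[type]]
  if (is.null(tp))
    stop_pericor("unsupported NRRD type: ", type,
                 class = "pericor_format_error")
  sizes <- dim(voxels)
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           "space: left-posterior-superior",
           paste0("sizes: ", paste(sizes, collapse = " ")),
           paste0("space directions: ",
                  sprintf("(%g,0,0) (0,%g,0) (0,0,%g)",
                          spacing[1], spacing[2], spacing[3])),
           "kinds: domain domain domain",
           "endian: little",
           paste0("encoding: ", encoding),
           paste0("space origin: ",
                  sprintf("(%g,%g,%g)", origin[1], origin[2], origin[3])))
  payload <- writeBin(as.vector(voxels,
                                mode = if (tp$what == "integer") "integer"
                                       else "double"),
                      raw(), size = tp$size, endian = "little")
  if (identical(encoding, "gzip")) payload <- memCompress(payload, "gzip")
  else if (!identical(encoding, "raw"))
    stop_pericor("unsupported NRRD encoding: ", encoding,
                 class = "pericor_format_error")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n\n")), con)
  writeBin(payload, con)
  invisible(path)
}
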