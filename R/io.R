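#' Write a hyperspectral cube to disk
#'
#' Two on-disk formats are supported. `"envi"` writes a flat binary BSQ file
#' (`<path>.img`, float32, little-endian) plus a text header (`<path>.hdr`)
#' carrying the wavelength list; this is the native format of most
#' hyperspectral toolchains. `"tiff"` writes a single multi-directory TIFF
#' (32-bit float); because the TIFF writer stores samples in \[0, 1\], values
#' are min-max normalized on write and the scale/offset plus the wavelength
#' list are recorded in a JSON metadata sidecar (`<path>.json`) and undone
#' on read.
#'
#' @param cube a [hyperspec_cube()].
#' @param path output path; for ENVI give the path without extension (or with
#'   `.img`), for TIFF a `.tif`/`.tiff` path.
#' @param format `"envi"` or `"tiff"`; inferred from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @seealso [read_cube()]
#' @export
write_cube <- function(cube, path, format = c("auto", "envi", "tiff")) {
  stopifnot(inherits(cube, "hyperspec_cube"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "envi"
  if (format == "envi") write_envi(cube, path) else write_cube_tiff(cube, path)
  invisible(path)
}

#' Read a hyperspectral cube from disk
#'
#' Reads ENVI (BSQ or BIL interleave, data types 4/5/2/12, via the `.hdr`
#' header) or TIFF cubes written by [write_cube()]. Wavelength metadata is
#' mandatory: an ENVI header without a `wavelength` field, or a TIFF without
#' its JSON sidecar, is a format error.
#'
#' @param path file path (ENVI `.img`/headerless binary or `.tif`).
#' @return A [hyperspec_cube()].
#' @export
read_cube <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) read_cube_tiff(path)
  else read_envi(path)
}

write_envi <- function(cube, path) {
  path <- sub("\\.img$", "", path)
  d <- dim(cube$reflectance)
  hdr <- c(
    "ENVI",
    "description = {chlorotex hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {", paste(format(cube$wavelengths, digits = 10,
                                          trim = TRUE), collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".img"), "wb")
  on.exit(close(con))
  # BSQ: band-sequential; within a band, sample (column) varies fastest
  for (b in seq_len(d[3]))
    writeBin(as.vector(t(cube$reflectance[, , b])), con,
             size = 4L, endian = "little")
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  fields <- list()
  # key = value, where value may be a {...} block spanning lines
  m <- gregexpr("([a-zA-Z][a-zA-Z0-9 ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt, perl = TRUE)
  for (piece in regmatches(txt, m)[[1]]) {
    key <- tolower(trimws(sub("=.*", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    fields[[key]] <- val
  }
  fields
}

read_envi <- function(path) {
  base <- sub("\\.(img|hdr)$", "", path)
  hdr_path <- paste0(base, ".hdr")
  img_path <- if (file.exists(paste0(base, ".img"))) paste0(base, ".img") else base
  if (!file.exists(hdr_path))
    stop(sprintf("format error: ENVI header '%s' not found", hdr_path), call. = FALSE)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  for (k in need) if (is.null(h[[k]]))
    stop(sprintf("format error: ENVI header missing field '%s'", k), call. = FALSE)
  if (is.null(h[["wavelength"]]))
    stop("format error: ENVI header missing field 'wavelength'", call. = FALSE)
  ns <- as.integer(h[["samples"]]); nl <- as.integer(h[["lines"]])
  nb <- as.integer(h[["bands"]])
  wl <- as.numeric(strsplit(gsub("[{}]", "", h[["wavelength"]]), ",")[[1]])
  if (length(wl) != nb)
    stop(sprintf("format error: header lists %d wavelengths but %d bands",
                 length(wl), nb), call. = FALSE)
  dt <- as.integer(h[["data type"]])
  spec <- switch(as.character(dt),
                 "2" = list(what = "integer", size = 2L),
                 "4" = list(what = "numeric", size = 4L),
                 "5" = list(what = "numeric", size = 8L),
                 "12" = list(what = "integer", size = 2L),
                 stop(sprintf("format error: unsupported ENVI data type %d", dt),
                      call. = FALSE))
  endian <- if (identical(h[["byte order"]], "1")) "big" else "little"
  n <- ns * nl * nb
  raw <- readBin(img_path, spec$what, n = n, size = spec$size, endian = endian)
  if (length(raw) != n)
    stop("format error: ENVI binary shorter than header dimensions", call. = FALSE)
  il <- tolower(trimws(h[["interleave"]]))
  arr <- array(NA_real_, c(nl, ns, nb))
  if (il == "bsq") {
    dim(raw) <- c(ns, nl, nb)
    arr <- aperm(raw, c(2, 1, 3))
  } else if (il == "bil") {
    dim(raw) <- c(ns, nb, nl)
    arr <- aperm(raw, c(3, 1, 2))
  } else stop(sprintf("format error: unsupported interleave '%s'", il), call. = FALSE)
  hyperspec_cube(arr, wl)
}

write_cube_tiff <- function(cube, path) {
  d <- dim(cube$reflectance)
  lo <- min(cube$reflectance); hi <- max(cube$reflectance)
  scale <- if (hi > lo) hi - lo else 1
  jsonlite::write_json(list(wavelengths = cube$wavelengths,
                            offset = lo, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  planes <- lapply(seq_len(d[3]), function(b)
    (cube$reflectance[, , b] - lo) / scale)
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  invisible(path)
}

read_cube_tiff <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  if (!file.exists(paste0(path, ".json")))
    stop("format error: TIFF lacks its wavelength metadata sidecar",
         call. = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  if (is.null(meta$wavelengths))
    stop("format error: TIFF description lacks field 'wavelengths'", call. = FALSE)
  if (length(planes) != length(meta$wavelengths))
    stop(sprintf("format error: TIFF has %d planes but %d wavelengths",
                 length(planes), length(meta$wavelengths)), call. = FALSE)
  arr <- array(0, c(dim(planes[[1]]), length(planes)))
  for (b in seq_along(planes))
    arr[, , b] <- planes[[b]] * meta$scale + meta$offset
  hyperspec_cube(arr, meta$wavelengths)
}

#' Write a single-band image (e.g. a mask or chlorophyll map) as TIFF
#'
#' Values are min-max normalized for storage with scale/offset in a JSON
#' sidecar (see [write_cube()]); `NA` pixels are stored as the minimum and
#' flagged in an `NA` index list.
#'
#' @param image numeric matrix.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  nas <- which(is.na(image))
  v <- image; v[nas] <- min(image, na.rm = TRUE)
  lo <- min(v); hi <- max(v); scale <- if (hi > lo) hi - lo else 1
  jsonlite::write_json(list(offset = lo, scale = scale, na_idx = nas),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  tiff::writeTIFF((v - lo) / scale, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  out <- img * meta$scale + meta$offset
  if (length(meta$na_idx)) out[meta$na_idx] <- NA_real_
  out
}

#' Read and validate a ground-point table
#'
#' CSV with header `id,row,col,spad,plot`. Coordinates are 1-based pixel
#' (row, col) positions; set `zero_based = TRUE` for tables produced by
#' 0-based tooling (both coordinates are then incremented by one).
#'
#' @param path CSV path.
#' @param dim optional `c(rows, cols)` image size used to check bounds.
#' @param zero_based logical; convert 0-based coordinates on read.
#' @return data.frame with columns id, row, col, spad, plot.
#' @export
read_ground_points <- function(path, dim = NULL, zero_based = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "row", "col", "spad", "plot")
  if (!all(need %in% names(df)))
    stop(sprintf("format error: ground table must have columns %s",
                 paste(need, collapse = ",")), call. = FALSE)
  if (zero_based) { df$row <- df$row + 1L; df$col <- df$col + 1L }
  if (anyDuplicated(df$id)) stop("ground table: point ids must be unique", call. = FALSE)
  if (!is.null(dim) &&
      any(df$row < 1 | df$row > dim[1] | df$col < 1 | df$col > dim[2]))
    stop("ground table: point coordinates outside image bounds", call. = FALSE)
  df[, need]
}

#' @rdname read_ground_points
#' @param points data.frame as returned by `read_ground_points`.
#' @export
write_ground_points <- function(points, path) {
  write.csv(points[, c("id", "row", "col", "spad", "plot")], path,
            row.names = FALSE)
  invisible(path)
}
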