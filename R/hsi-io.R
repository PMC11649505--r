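# Hyperspectral cube and label-mask containers with file I/O.
#
# Supported cube formats: ENVI header (.hdr) + raw binary (BSQ/BIL/BIP
# interleaves, float32/float64/int16/uint16), multi-page grayscale TIFF
# (baseline, uncompressed, little-endian; one page per band), and an RDS
# container holding data + wavelengths. Masks: PGM (P2/P5) or RDS. No binary
# fixtures ship with the package; files are written at run time.

#' Construct a hyperspectral cube
#'
#' @param data numeric array `[H, W, B]` (band axis last), all finite.
#' @param wavelengths_nm strictly increasing length-B numeric (nanometres).
#' @param source_id free-form provenance string.
#' @return an object of class `HsiCube`.
#' @export
hsi_cube <- function(data, wavelengths_nm, source_id = "") {
  d <- dim(data)
  if (length(d) != 3L || any(d < 1L)) stop("data must be an [H, W, B] array")
  if (length(wavelengths_nm) != d[3L]) {
    stop(sprintf("wavelength count %d != band count %d", length(wavelengths_nm), d[3L]))
  }
  if (any(diff(wavelengths_nm) <= 0)) stop("wavelengths must be strictly increasing")
  if (!all(is.finite(data))) stop("cube contains non-finite values")
  structure(list(data = data, wavelengths_nm = as.numeric(wavelengths_nm),
                 source_id = source_id), class = "HsiCube")
}

#' @export
print.HsiCube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("HsiCube %dx%d pixels, %d bands (%.2f-%.2f nm)%s\n",
              d[1L], d[2L], d[3L], min(x$wavelengths_nm), max(x$wavelengths_nm),
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Construct a label mask
#'
#' @param labels integer array `[H, W]` with values in `0..num_classes-1`.
#' @param num_classes number of classes C (>= 2).
#' @return an object of class `LabelMask`.
#' @export
label_mask <- function(labels, num_classes = 2L) {
  if (length(dim(labels)) != 2L) stop("labels must be an [H, W] array")
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (any(labels != floor(labels)) || any(labels < 0) || any(labels >= num_classes)) {
    stop(sprintf("labels must be integers in [0, %d)", num_classes))
  }
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 num_classes = as.integer(num_classes)), class = "LabelMask")
}

cube_format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         hdr = , img = , raw = "envi",
         tif = , tiff = "tiff_stack",
         rds = "rds_container",
         stop(sprintf("cannot infer cube format from extension '.%s'", ext)))
}

#' Read a hyperspectral cube
#'
#' @param path file path (for ENVI, either the `.hdr` or the raw file).
#' @param format `"envi"`, `"tiff_stack"` or `"rds_container"`; inferred from
#'   the extension when missing.
#' @param wavelength_start,wavelength_step fallback wavelength grid (nm) used
#'   when the file carries no wavelengths (defaults 450 and 6.25).
#' @return an [hsi_cube()].
#' @export
read_cube <- function(path, format = NULL, wavelength_start = 450,
                      wavelength_step = 6.25) {
  if (is.null(format)) format <- cube_format_from_path(path)
  switch(format,
         envi = read_cube_envi(path, wavelength_start, wavelength_step),
         tiff_stack = read_cube_tiff(path, wavelength_start, wavelength_step),
         rds_container = read_cube_rds(path),
         stop(sprintf("unsupported cube format '%s'", format)))
}

#' Write a hyperspectral cube
#'
#' ENVI and the RDS container round-trip exactly (float64); TIFF stores
#' float32 planes (round-trips within float32 rounding).
#'
#' @param cube an [hsi_cube()].
#' @param path output path (ENVI writes `path.hdr` plus the raw file).
#' @param format as in [read_cube()].
#' @export
write_cube <- function(cube, path, format = NULL) {
  stopifnot(inherits(cube, "HsiCube"))
  if (is.null(format)) format <- cube_format_from_path(path)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir))
  switch(format,
         envi = write_cube_envi(cube, path),
         tiff_stack = write_cube_tiff(cube, path),
         rds_container = saveRDS(list(data = cube$data,
                                      wavelengths_nm = cube$wavelengths_nm,
                                      source_id = cube$source_id), path),
         stop(sprintf("unsupported cube format '%s'", format)))
  invisible(path)
}

read_cube_rds <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$data) || is.null(obj$wavelengths_nm)) {
    stop(sprintf("not a cube container: %s", path))
  }
  hsi_cube(obj$data, obj$wavelengths_nm, obj$source_id %||% basename(path))
}

## ---- ENVI -----------------------------------------------------------------

envi_paths <- function(path) {
  if (tolower(tools::file_ext(path)) == "hdr") {
    hdr <- path
    base <- sub("\\.hdr$", "", path, ignore.case = TRUE)
    raw <- NULL
    for (ext in c("", ".raw", ".img", ".dat")) {
      if (file.exists(paste0(base, ext))) { raw <- paste0(base, ext); break }
    }
    if (is.null(raw)) stop(sprintf("no raw data file found for header %s", path))
  } else {
    raw <- path
    hdr <- paste0(path, ".hdr")
    if (!file.exists(hdr)) hdr <- paste0(sub("\\.[^.]+$", "", path), ".hdr")
    if (!file.exists(hdr)) stop(sprintf("no ENVI header found for %s", path))
  }
  list(hdr = hdr, raw = raw)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  fields <- list()
  # key = value, where value may be a {...} block spanning lines
  pat <- gregexpr("([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt, perl = TRUE)
  ms <- regmatches(txt, pat)[[1]]
  for (m in ms) {
    eq <- regexpr("=", m)
    key <- tolower(trimws(substr(m, 1, eq - 1)))
    val <- trimws(substr(m, eq + 1, nchar(m)))
    fields[[key]] <- val
  }
  fields
}

envi_num_list <- function(val) {
  val <- gsub("[{}\n]", " ", val)
  as.numeric(strsplit(trimws(val), "\\s*,\\s*|\\s+")[[1]])
}

read_cube_envi <- function(path, wavelength_start, wavelength_step) {
  pp <- envi_paths(path)
  if (!file.exists(pp$raw)) stop(sprintf("file not found: %s", pp$raw))
  h <- parse_envi_header(pp$hdr)
  need <- c("samples", "lines", "bands")
  if (!all(need %in% names(h))) stop(sprintf("ENVI header %s lacks samples/lines/bands", pp$hdr))
  W <- as.integer(h$samples); H <- as.integer(h$lines); B <- as.integer(h$bands)
  dtype <- as.integer(h[["data type"]] %||% "4")
  interleave <- tolower(h$interleave %||% "bsq")
  byte_order <- as.integer(h[["byte order"]] %||% "0")
  endian <- if (byte_order == 0L) "little" else "big"
  spec <- switch(as.character(dtype),
                 "1" = list(what = "integer", size = 1L, signed = FALSE),
                 "2" = list(what = "integer", size = 2L, signed = TRUE),
                 "4" = list(what = "numeric", size = 4L),
                 "5" = list(what = "numeric", size = 8L),
                 "12" = list(what = "integer", size = 2L, signed = FALSE),
                 stop(sprintf("unsupported ENVI data type %d", dtype)))
  n <- W * H * B
  expect_bytes <- n * spec$size
  if (file.size(pp$raw) < expect_bytes) {
    stop(sprintf("ENVI raw %s holds %d bytes, header declares %d (%dx%dx%d): format mismatch",
                 pp$raw, file.size(pp$raw), expect_bytes, H, W, B))
  }
  con <- file(pp$raw, "rb"); on.exit(close(con))
  vals <- readBin(con, what = spec$what, n = n, size = spec$size,
                  signed = spec$signed %||% TRUE, endian = endian)
  data <- switch(interleave,
                 bsq = aperm(array(vals, c(W, H, B)), c(2L, 1L, 3L)),
                 bil = aperm(array(vals, c(W, B, H)), c(3L, 1L, 2L)),
                 bip = aperm(array(vals, c(B, W, H)), c(3L, 2L, 1L)),
                 stop(sprintf("unsupported interleave '%s'", interleave)))
  wl <- if (!is.null(h$wavelength)) envi_num_list(h$wavelength) else
    wavelength_start + wavelength_step * (seq_len(B) - 1L)
  if (length(wl) != B) {
    stop(sprintf("ENVI header declares %d wavelengths for %d bands", length(wl), B))
  }
  hsi_cube(data, wl, source_id = basename(pp$raw))
}

write_cube_envi <- function(cube, path) {
  base <- sub("\\.hdr$", "", path, ignore.case = TRUE)
  raw <- if (tolower(tools::file_ext(base)) %in% c("raw", "img", "dat")) base else paste0(base, ".raw")
  hdr <- paste0(sub("\\.(raw|img|dat)$", "", raw, ignore.case = TRUE), ".hdr")
  d <- dim(cube$data)
  # BSQ float64 for exact round-trips
  con <- file(raw, "wb")
  writeBin(as.vector(aperm(cube$data, c(2L, 1L, 3L))), con, size = 8L, endian = "little")
  close(con)
  writeLines(c(
    "ENVI",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    paste0("wavelength = {", paste(format(cube$wavelengths_nm, trim = TRUE), collapse = ", "), "}")
  ), hdr)
  invisible(raw)
}

## ---- minimal baseline TIFF (uncompressed, little-endian) ------------------

tiff_pack_ifd_entry <- function(tag, type, count, value_raw, offset_if_large) {
  # returns list(entry = 12 raw bytes, extra = raw payload or NULL)
  sizes <- c(`1` = 1L, `3` = 2L, `4` = 4L)
  total <- sizes[[as.character(type)]] * count
  ent <- c(writeBin(as.integer(tag), raw(), size = 2L, endian = "little"),
           writeBin(as.integer(type), raw(), size = 2L, endian = "little"),
           writeBin(as.integer(count), raw(), size = 4L, endian = "little"))
  if (total <= 4L) {
    pad <- c(value_raw, raw(4L - length(value_raw)))
    list(entry = c(ent, pad), extra = NULL)
  } else {
    list(entry = c(ent, writeBin(as.integer(offset_if_large), raw(), size = 4L, endian = "little")),
         extra = value_raw)
  }
}

u16r <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32r <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

write_cube_tiff <- function(cube, path) {
  d <- dim(cube$data)
  H <- d[1L]; W <- d[2L]; B <- d[3L]
  strip_bytes <- H * W * 4L
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(u16r(42L), con)
  # layout: header(8) | B strips | B IFDs (fixed size, no external payloads)
  strip_off <- 8L + (seq_len(B) - 1L) * strip_bytes
  ifd_entries <- 8L
  ifd_size <- 2L + 12L * ifd_entries + 4L
  ifd_off <- 8L + B * strip_bytes + (seq_len(B) - 1L) * ifd_size
  writeBin(u32r(ifd_off[1L]), con)
  for (b in seq_len(B)) {
    plane <- t(cube$data[, , b])                  # row-major pixel order
    writeBin(as.vector(plane), con, size = 4L, endian = "little")
  }
  for (b in seq_len(B)) {
    writeBin(u16r(ifd_entries), con)
    ent <- function(tag, type, count, vraw) {
      writeBin(c(u16r(tag), u16r(type), u32r(count), vraw, raw(4L - length(vraw)))[1:12], con)
    }
    ent(256L, 3L, 1L, u16r(W))                    # ImageWidth
    ent(257L, 3L, 1L, u16r(H))                    # ImageLength
    ent(258L, 3L, 1L, u16r(32L))                  # BitsPerSample
    ent(259L, 3L, 1L, u16r(1L))                   # Compression: none
    ent(262L, 3L, 1L, u16r(1L))                   # Photometric: BlackIsZero
    ent(273L, 4L, 1L, u32r(strip_off[b]))         # StripOffsets
    ent(279L, 4L, 1L, u32r(strip_bytes))          # StripByteCounts
    ent(339L, 3L, 1L, u16r(3L))                   # SampleFormat: IEEE float
    nxt <- if (b < B) ifd_off[b + 1L] else 0L
    writeBin(u32r(nxt), con)
  }
  invisible(path)
}

read_cube_tiff <- function(path, wavelength_start, wavelength_step) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 8L) stop(sprintf("not a TIFF file: %s", path))
  magic <- rawToChar(bytes[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop(sprintf("not a TIFF file: %s", path))
  rd <- function(off, size, n = 1L, what = "integer", signed = TRUE) {
    # readBin only honours `signed` for 1- and 2-byte integers
    sg <- if (what == "integer" && size <= 2L) signed else TRUE
    readBin(bytes[(off + 1L):(off + size * n)], what, n = n, size = size,
            signed = sg, endian = endian)
  }
  ifd_off <- rd(4L, 4L)
  planes <- list()
  while (ifd_off != 0L) {
    n_ent <- rd(ifd_off, 2L, signed = FALSE)
    tags <- list()
    for (i in seq_len(n_ent)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- rd(e, 2L, signed = FALSE)
      type <- rd(e + 2L, 2L, signed = FALSE)
      count <- rd(e + 4L, 4L)
      tsize <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)[as.character(type)]
      if (is.na(tsize)) next
      voff <- if (tsize * count <= 4L) e + 8L else rd(e + 8L, 4L)
      vals <- rd(voff, tsize, count, signed = FALSE)
      tags[[as.character(tag)]] <- vals
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop(sprintf("TIFF %s: missing required tags", path))
    W <- tags[["256"]][1L]; H <- tags[["257"]][1L]
    bits <- (tags[["258"]] %||% 8L)[1L]
    comp <- (tags[["259"]] %||% 1L)[1L]
    sfmt <- (tags[["339"]] %||% 1L)[1L]
    spp <- (tags[["277"]] %||% 1L)[1L]
    if (comp != 1L) stop(sprintf("TIFF %s: only uncompressed data supported", path))
    if (spp != 1L) stop(sprintf("TIFF %s: only single-sample (grayscale) pages supported", path))
    offs <- tags[["273"]]; cnts <- tags[["279"]]
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      if (sfmt == 3L && bits == 32L) {
        vals <- c(vals, rd(offs[s], 4L, cnts[s] %/% 4L, what = "numeric"))
      } else if (sfmt %in% c(1L, 2L) && bits == 16L) {
        vals <- c(vals, rd(offs[s], 2L, cnts[s] %/% 2L, signed = sfmt == 2L))
      } else if (sfmt %in% c(1L, 2L) && bits == 8L) {
        vals <- c(vals, as.numeric(rd(offs[s], 1L, cnts[s], signed = FALSE)))
      } else {
        stop(sprintf("TIFF %s: unsupported sample format %d/%d bits", path, sfmt, bits))
      }
    }
    if (length(vals) != H * W) stop(sprintf("TIFF %s: strip sizes disagree with page size", path))
    planes[[length(planes) + 1L]] <- t(matrix(vals, W, H))   # stored row-major
    ifd_off <- rd(ifd_off + 2L + n_ent * 12L, 4L)
  }
  B <- length(planes)
  data <- array(0, c(dim(planes[[1L]]), B))
  for (b in seq_len(B)) data[, , b] <- planes[[b]]
  wl <- wavelength_start + wavelength_step * (seq_len(B) - 1L)
  hsi_cube(data, wl, source_id = basename(path))
}

## ---- masks ----------------------------------------------------------------

#' Write a label mask
#'
#' PGM (binary P5, 8-bit) or RDS, chosen by extension; both round-trip labels
#' exactly.
#' @param mask a [label_mask()].
#' @param path output path ending in `.pgm` or `.rds`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "LabelMask"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    saveRDS(list(labels = mask$labels, num_classes = mask$num_classes), path)
  } else if (ext == "pgm") {
    if (max(mask$labels) > 255L) stop("PGM masks support at most 256 classes")
    con <- file(path, "wb"); on.exit(close(con))
    d <- dim(mask$labels)
    writeLines(c("P5", sprintf("%d %d", d[2L], d[1L]), "255"), con, sep = "\n")
    writeBin(as.raw(as.vector(t(mask$labels))), con)
  } else {
    stop(sprintf("unsupported mask format '.%s'", ext))
  }
  invisible(path)
}

#' Read a label mask
#'
#' @param path `.pgm` or `.rds` file.
#' @param num_classes number of classes the labels must respect; defaults to
#'   `max(labels) + 1` (at least 2).
#' @return a [label_mask()].
#' @export
read_mask <- function(path, num_classes = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    obj <- readRDS(path)
    nc <- num_classes %||% obj$num_classes
    return(label_mask(obj$labels, nc))
  }
  if (ext != "pgm") stop(sprintf("unsupported mask format '.%s'", ext))
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!magic %in% c("P2", "P5")) stop(sprintf("not a PGM file: %s", path))
  hdr <- integer(0)
  while (length(hdr) < 3L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*", "", line)
    hdr <- c(hdr, as.integer(strsplit(trimws(line), "\\s+")[[1]]))
  }
  W <- hdr[1L]; H <- hdr[2L]
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", W * H))
  } else {
    scan(con, what = integer(), n = W * H, quiet = TRUE)
  }
  labels <- t(matrix(vals, W, H))
  nc <- num_classes %||% max(2L, max(labels) + 1L)
  label_mask(labels, nc)
}

## ---- false-color preview --------------------------------------------------

#' False-color rendering of a hyperspectral cube
#'
#' Picks the bands nearest to the configured display wavelengths (default
#' 650/550/450 nm for R/G/B) and min-max scales each to 0..255. A constant
#' band renders as zeros.
#'
#' @param cube an [hsi_cube()] with at least 3 bands.
#' @param display_nm length-3 wavelengths (nm) for the R, G, B channels.
#' @return integer array `[H, W, 3]` in 0..255.
#' @export
false_color <- function(cube, display_nm = c(650, 550, 450)) {
  stopifnot(inherits(cube, "HsiCube"))
  d <- dim(cube$data)
  if (d[3L] < 3L) stop("false_color needs at least 3 bands")
  out <- array(0L, c(d[1L], d[2L], 3L))
  for (i in 1:3) {
    b <- which.min(abs(cube$wavelengths_nm - display_nm[i]))
    plane <- cube$data[, , b]
    rng <- range(plane)
    if (rng[2L] > rng[1L]) {
      out[, , i] <- as.integer(round(255 * (plane - rng[1L]) / (rng[2L] - rng[1L])))
    }
  }
  out
}

#' Band selected for each false-color channel
#' @inheritParams false_color
#' @return integer band indices (length 3).
#' @export
false_color_bands <- function(cube, display_nm = c(650, 550, 450)) {
  vapply(display_nm, function(w) which.min(abs(cube$wavelengths_nm - w)), integer(1))
}
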