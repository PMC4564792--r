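# Volume I/O. NIfTI goes through RNifti; NRRD (raw / gzip encodings,
# attached header, axis-aligned space directions) and raw-plus-JSON-sidecar
# files are handled here directly. Intensities are taken as already
# HU-calibrated: no rescale slope/intercept handling, values pass through
# bit-identically. Orientation is resolved once at this boundary: arrays are
# (x, y, z) with z the axial slice index.

volume_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", p)) "nifti"
  else if (grepl("\\.nrrd$", p)) "nrrd"
  else if (grepl("\\.raw$", p)) "raw"
  else stop(sprintf("unsupported volume format: %s", basename(path)),
            call. = FALSE)
}

#' Read a CT volume
#'
#' Reads a 3D scalar volume from NIfTI-1 (`.nii`, `.nii.gz`), NRRD
#' (`.nrrd`, `raw` or `gzip` encoding), or raw int16/float64 with a JSON
#' sidecar (`vol.raw` + `vol.json` declaring `shape`, `dtype`, `spacing`,
#' `origin`).
#'
#' @param path Path to the volume file.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  x <- read_any_volume(path)
  volume_image(x$data, x$spacing, x$origin)
}

#' Write a CT volume
#'
#' Inverse of [read_volume()]; the written file reads back with bit-identical
#' voxel data. Geometry round-trips exactly for NRRD and raw sidecars;
#' NIfTI headers store spacing and origin as 32-bit floats.
#'
#' @param vol A [volume_image()].
#' @param path Output path; format chosen by extension as in [read_volume()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  write_any_volume(vol$data, vol$spacing, vol$origin, path)
  invisible(path)
}

#' Read / write a label volume
#'
#' Same formats as [read_volume()], with integer values enforced: a file
#' containing non-integer values is rejected.
#'
#' @param path Path to the label file.
#' @return `read_labels()` returns a [label_volume()].
#' @export
read_labels <- function(path) {
  x <- read_any_volume(path)
  if (any(x$data != round(x$data)))
    stop("label file contains non-integer values", call. = FALSE)
  label_volume(x$data, x$spacing, x$origin)
}

#' @rdname read_labels
#' @param lab A [label_volume()].
#' @export
write_labels <- function(lab, path) {
  stopifnot(inherits(lab, "label_volume"))
  write_any_volume(lab$data, lab$spacing, lab$origin, path, integer_ok = TRUE)
  invisible(path)
}

read_any_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  switch(volume_format(path),
         nifti = read_nifti_volume(path),
         nrrd = read_nrrd_volume(path),
         raw = read_raw_volume(path))
}

write_any_volume <- function(data, spacing, origin, path, integer_ok = FALSE) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("directory does not exist: %s", dir), call. = FALSE)
  switch(volume_format(path),
         nifti = write_nifti_volume(data, spacing, origin, path),
         nrrd = write_nrrd_volume(data, spacing, origin, path),
         raw = write_raw_volume(data, spacing, origin, path))
  invisible(path)
}

# ---- NIfTI -----------------------------------------------------------------

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop(sprintf("expected a 3D image, got %dD: %s", length(dim(a)),
                 basename(path)), call. = FALSE)
  sp <- abs(RNifti::pixdim(img))[1:3]
  m <- RNifti::xform(img)
  org <- if (is.matrix(m) && all(dim(m) == c(4L, 4L))) m[1:3, 4] else c(0, 0, 0)
  attributes(a) <- list(dim = dim(a))   # plain array, no NIfTI baggage
  list(data = a, spacing = sp, origin = unname(org))
}

write_nifti_volume <- function(data, spacing, origin, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  qf <- diag(c(spacing, 1))
  qf[1:3, 4] <- origin
  attr(qf, "code") <- 2L
  img <- RNifti::`qform<-`(img, value = qf)
  dt <- if (is.integer(data)) "int32" else "double"
  RNifti::writeNifti(img, path, datatype = dt)
}

# ---- NRRD ------------------------------------------------------------------

nrrd_types <- c(int16 = "short", int32 = "int", float64 = "double")

read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000", magic))
    stop(sprintf("not an NRRD file: %s", basename(path)), call. = FALSE)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L)
      stop("truncated NRRD header", call. = FALSE)
    if (ln == "") break
    if (grepl("^#", ln)) next
    kv <- regmatches(ln, regexec("^([^:]+):=?\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  ndim <- as.integer(fields[["dimension"]] %||% NA)
  if (is.na(ndim) || ndim != 3L)
    stop(sprintf("expected a 3D NRRD, got dimension %s", ndim), call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- fields[["type"]] %||% stop("NRRD header lacks type", call. = FALSE)
  enc <- tolower(fields[["encoding"]] %||% "raw")
  endian <- tolower(fields[["endian"]] %||% "little")
  n <- prod(sizes)
  payload <- readBin(con, "raw", n = file.size(path))
  if (enc %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (enc != "raw") {
    stop(sprintf("unsupported NRRD encoding: %s", enc), call. = FALSE)
  }
  rcon <- rawConnection(payload)
  on.exit(close(rcon), add = TRUE)
  vals <- switch(type,
    "short" = , "int16" = , "signed short" =
      readBin(rcon, "integer", n = n, size = 2L, signed = TRUE, endian = endian),
    "int" = , "int32" = , "signed int" =
      readBin(rcon, "integer", n = n, size = 4L, endian = endian),
    "double" = , "float64" =
      readBin(rcon, "double", n = n, size = 8L, endian = endian),
    "float" = , "float32" =
      readBin(rcon, "double", n = n, size = 4L, endian = endian),
    stop(sprintf("unsupported NRRD type: %s", type), call. = FALSE))
  if (length(vals) != n)
    stop("NRRD payload shorter than declared sizes", call. = FALSE)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    for (k in 1:3) {
      v <- dirs[[k]]
      if (sum(v != 0) != 1L || v[k] == 0)
        stop("only axis-aligned NRRD space directions are supported",
             call. = FALSE)
      spacing[k] <- abs(v[k])
    }
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- abs(as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]]))
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  list(data = array(vals, dim = sizes), spacing = spacing, origin = origin)
}

parse_nrrd_vectors <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(m, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

write_nrrd_volume <- function(data, spacing, origin, path) {
  int_like <- is.integer(data) ||
    (all(data == round(data)) && max(abs(data)) < 2^31)
  type <- if (!int_like) "double"
  else if (max(abs(data)) < 2^15) "short" else "int"
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %s", paste(dim(data), collapse = " ")),
    "encoding: raw",
    sprintf("endian: %s", .Platform$endian),
    "space: left-posterior-superior",
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            spacing[1], spacing[2], spacing[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            origin[1], origin[2], origin[3]),
    "")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  v <- as.vector(data)
  if (type == "short") writeBin(as.integer(v), con, size = 2L)
  else if (type == "int") writeBin(as.integer(v), con, size = 4L)
  else writeBin(as.double(v), con, size = 8L)
}

# ---- raw + JSON sidecar ----------------------------------------------------

sidecar_path <- function(path) sub("\\.raw$", ".json", path, ignore.case = TRUE)

read_raw_volume <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop(sprintf("raw volume requires a JSON sidecar: %s not found",
                 basename(side)), call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (key in c("shape", "dtype"))
    if (is.null(meta[[key]]))
      stop(sprintf("sidecar lacks required key '%s'", key), call. = FALSE)
  shape <- as.integer(meta$shape)
  if (length(shape) != 3L)
    stop(sprintf("expected a 3D shape in sidecar, got length %d",
                 length(shape)), call. = FALSE)
  n <- prod(shape)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- switch(as.character(meta$dtype),
    int16 = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                    endian = "little"),
    int32 = readBin(con, "integer", n = n, size = 4L, endian = "little"),
    float64 = readBin(con, "double", n = n, size = 8L, endian = "little"),
    stop(sprintf("unsupported raw dtype: %s", meta$dtype), call. = FALSE))
  if (length(vals) != n)
    stop("raw file shorter than sidecar shape", call. = FALSE)
  list(data = array(vals, dim = shape),
       spacing = as.numeric(meta$spacing %||% c(1, 1, 1)),
       origin = as.numeric(meta$origin %||% c(0, 0, 0)))
}

write_raw_volume <- function(data, spacing, origin, path) {
  int_like <- is.integer(data) ||
    (all(data == round(data)) && max(abs(data)) < 2^31)
  dtype <- if (!int_like) "float64"
  else if (max(abs(data)) < 2^15) "int16" else "int32"
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  v <- as.vector(data)
  switch(dtype,
         int16 = writeBin(as.integer(v), con, size = 2L, endian = "little"),
         int32 = writeBin(as.integer(v), con, size = 4L, endian = "little"),
         float64 = writeBin(as.double(v), con, size = 8L, endian = "little"))
  jsonlite::write_json(
    list(shape = dim(data), dtype = dtype, spacing = spacing, origin = origin),
    sidecar_path(path), auto_unbox = FALSE, digits = NA)
}
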