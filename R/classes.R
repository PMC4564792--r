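# Core containers. Plain lists with S3 classes; data lives in ordinary R
# arrays with axis order (x, y, z), z being the axial slice index. All
# internal indices are 1-based and bounding boxes are closed [lo, hi];
# external file formats use the 0-based half-open convention and are
# converted at the I/O boundary (see seeds_io.R).

#' CT volume container
#'
#' Wraps a 3D numeric array of Hounsfield-like intensities together with its
#' voxel spacing and world origin. Axis order is fixed as (x, y, z) with z
#' indexing axial slices.
#'
#' @param data 3D numeric array of intensities (HU).
#' @param spacing Numeric length-3, voxel size in mm; all components > 0.
#' @param origin Numeric length-3, world coordinates of the first voxel (mm).
#' @return An object of class `volume_image` with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- volume_image(array(0, c(4, 4, 4)), spacing = c(0.2, 0.2, 0.2))
#' dim(v$data)
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("every volume dimension must be >= 1", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("volume intensities must all be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' Per-tooth label volume
#'
#' Integer voxel grid aligned with a [volume_image()]: 0 is background and
#' label k >= 1 marks tooth k.
#'
#' @param data 3D integer array (nonnegative).
#' @param spacing,origin As in [volume_image()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("label data must be a 3D array", call. = FALSE)
  if (is.double(data) && any(data != round(data)))
    stop("labels must be integer-valued", call. = FALSE)
  storage.mode(data) <- "integer"
  if (anyNA(data) || any(data < 0L))
    stop("labels must be nonnegative integers", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite numbers", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "label_volume")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, spacing %s mm, HU range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- setdiff(sort(unique(as.integer(x$data))), 0L)
  cat(sprintf("<label_volume> %s voxels, %d labels%s\n",
              paste(dim(x$data), collapse = "x"), length(labs),
              if (length(labs)) paste0(" (", paste(head(labs, 20), collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Voxel bounding box
#'
#' Axis-aligned box in voxel indices, stored 1-based and closed on both ends.
#' `lo` and `hi` may be length 2 (in-slice) or 3 (volume).
#'
#' @param lo,hi Integer vectors of equal length (2 or 3), `lo <= hi`.
#' @return An object of class `bounding_box` with fields `lo`, `hi`.
#' @export
bounding_box <- function(lo, hi) {
  lo <- as.integer(round(lo)); hi <- as.integer(round(hi))
  if (length(lo) != length(hi) || !length(lo) %in% c(2L, 3L))
    stop("bounding box corners must both have length 2 or 3", call. = FALSE)
  if (any(lo < 1L) || any(hi < lo))
    stop("bounding box requires 1 <= lo <= hi on every axis", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> [%s] .. [%s]\n",
              paste(x$lo, collapse = ", "), paste(x$hi, collapse = ", ")))
  invisible(x)
}

# Clip a bounding box to grid dimensions.
clip_bbox <- function(bbox, dims) {
  nd <- length(bbox$lo)
  bounding_box(pmax(bbox$lo, 1L), pmin(bbox$hi, dims[seq_len(nd)]))
}

# In-slice (x, y) part of a 3D box.
bbox_xy <- function(bbox) {
  if (length(bbox$lo) == 2L) bbox
  else bounding_box(bbox$lo[1:2], bbox$hi[1:2])
}

#' Per-tooth seed set on a reference slice
#'
#' User input for [segment_teeth()]: the reference axial slice index, at
#' least one in-slice seed pixel per tooth, and a bounding box enclosing the
#' dentition.
#'
#' @param seeds Named list; element `"<tooth id>"` is an n x 2 matrix of
#'   (x, y) pixel coordinates on the reference slice (1-based).
#' @param bbox A 3D [bounding_box()] enclosing all teeth.
#' @param reference_slice Axial slice index (1-based) on which the seeds lie.
#' @return An object of class `tooth_seed_set`.
#' @export
tooth_seed_set <- function(seeds, bbox, reference_slice) {
  if (!is.list(seeds) || length(seeds) == 0L)
    stop("seeds must be a nonempty named list", call. = FALSE)
  ids <- names(seeds)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("tooth ids must be unique nonempty names", call. = FALSE)
  seeds <- lapply(seeds, function(s) {
    s <- matrix(as.integer(round(s)), ncol = 2)
    if (nrow(s) < 1L) stop("every tooth needs at least one seed", call. = FALSE)
    s
  })
  if (!inherits(bbox, "bounding_box") || length(bbox$lo) != 3L)
    stop("bbox must be a 3D bounding_box", call. = FALSE)
  for (id in ids) {
    s <- seeds[[id]]
    inside <- s[, 1] >= bbox$lo[1] & s[, 1] <= bbox$hi[1] &
      s[, 2] >= bbox$lo[2] & s[, 2] <= bbox$hi[2]
    if (!all(inside))
      stop(sprintf("seed for tooth %s lies outside the bounding box", id),
           call. = FALSE)
  }
  reference_slice <- as.integer(reference_slice)
  if (length(reference_slice) != 1L || is.na(reference_slice) ||
      reference_slice < bbox$lo[3] || reference_slice > bbox$hi[3])
    stop("reference_slice must lie inside the bounding box z-range",
         call. = FALSE)
  structure(list(seeds = seeds, bbox = bbox,
                 reference_slice = reference_slice),
            class = "tooth_seed_set")
}

#' @export
print.tooth_seed_set <- function(x, ...) {
  cat(sprintf("<tooth_seed_set> %d teeth, reference slice z = %d\n",
              length(x$seeds), x$reference_slice))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mask_area <- function(mask) sum(mask)

# Bounding box (2D) of a nonempty logical matrix, expanded by `pad` and
# clipped to the matrix extent.
mask_extent <- function(mask, pad = 0L) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  lo <- pmax(apply(w, 2, min) - pad, 1L)
  hi <- pmin(apply(w, 2, max) + pad, dim(mask))
  bounding_box(lo, hi)
}
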