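# Seed-set JSON interchange. The on-disk schema uses 0-based voxel indices
# and a half-open bounding box [min, max); internally everything is 1-based
# and closed. The conversion happens here and nowhere else.
#
# Schema: { "<tooth_id>": [[x, y, z], ...], ...,
#           "bbox": [xmin, ymin, zmin, xmax, ymax, zmax],
#           "reference_slice": z }

#' Read / write a seed set as JSON
#'
#' @param path JSON file path.
#' @return `read_seed_set()` returns a [tooth_seed_set()].
#' @export
read_seed_set <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$bbox) || is.null(obj$reference_slice))
    stop("seed file lacks bbox or reference_slice", call. = FALSE)
  bb <- as.numeric(obj$bbox)
  if (length(bb) != 6L)
    stop("bbox must have six entries [xmin,ymin,zmin,xmax,ymax,zmax]",
         call. = FALSE)
  bbox <- bounding_box(bb[1:3] + 1L, bb[4:6])      # half-open -> closed
  zref <- as.integer(obj$reference_slice) + 1L
  ids <- setdiff(names(obj), c("bbox", "reference_slice"))
  if (length(ids) == 0L) stop("seed file contains no teeth", call. = FALSE)
  seeds <- lapply(obj[ids], function(s) {
    if (!is.matrix(s)) s <- matrix(as.numeric(unlist(s)), ncol = 3,
                                   byrow = TRUE)
    storage.mode(s) <- "integer"
    s[, 1:2, drop = FALSE] + 1L
  })
  names(seeds) <- ids
  tooth_seed_set(seeds, bbox, zref)
}

#' @rdname read_seed_set
#' @param seeds A [tooth_seed_set()].
#' @export
write_seed_set <- function(seeds, path) {
  stopifnot(inherits(seeds, "tooth_seed_set"))
  z0 <- seeds$reference_slice - 1L
  obj <- lapply(seeds$seeds, function(s) {
    cbind(s - 1L, z0)                               # closed -> 0-based
  })
  obj$bbox <- c(seeds$bbox$lo - 1L, seeds$bbox$hi)  # closed -> half-open
  obj$reference_slice <- z0
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
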