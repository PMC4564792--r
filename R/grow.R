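# Queue-based seeded region growing and its inverse. A candidate voxel x
# joins the region A when it is adjacent to A, lies inside the bounding box,
# exceeds the threshold and satisfies |I(x) - mean(A)| < delta. Holes left
# by dark dentin and pulp are recovered by growing the *background* from the
# bounding-box boundary and complementing (inverse region growing).

#' Region-growing parameters
#'
#' @param delta Maximum allowed deviation (HU) of a candidate voxel from the
#'   region mean; > 0. The default of 60 HU corresponds to three standard
#'   deviations of the default phantom noise.
#' @param connectivity `NULL` (auto: 4 in 2D, 6 in 3D) or one of 4, 8 (2D) /
#'   6, 26 (3D).
#' @param mean_mode `"frozen"` (region mean fixed at the seed mean; the
#'   result is independent of seed ordering) or `"running"` (classic
#'   updating mean with FIFO order fixed by lexicographic voxel order).
#' @return An object of class `grow_params`.
#' @export
grow_params <- function(delta = 60, connectivity = NULL,
                        mean_mode = c("frozen", "running")) {
  mean_mode <- match.arg(mean_mode)
  if (!is.numeric(delta) || delta <= 0)
    stop("delta must be positive", call. = FALSE)
  if (!is.null(connectivity) && !connectivity %in% c(4L, 8L, 6L, 26L))
    stop("connectivity must be one of 4, 8 (2D) or 6, 26 (3D)", call. = FALSE)
  structure(list(delta = delta, connectivity = connectivity,
                 mean_mode = mean_mode),
            class = "grow_params")
}

default_connectivity <- function(nd, connectivity = NULL) {
  if (!is.null(connectivity)) {
    ok <- if (nd == 2L) c(4L, 8L) else c(6L, 26L)
    if (!connectivity %in% ok)
      stop(sprintf("connectivity %d is invalid for a %dD grid",
                   connectivity, nd), call. = FALSE)
    return(as.integer(connectivity))
  }
  if (nd == 2L) 4L else 6L
}

#' Seeded region growing
#'
#' Grows a region from seed voxels over a 2D or 3D intensity grid by
#' first-in-first-out queue expansion. A voxel joins the region iff it is
#' connectivity-adjacent to it, lies inside `bbox`, its intensity is at
#' least `threshold`, and it differs from the region mean by less than
#' `delta`. With the default frozen mean the result does not depend on the
#' order in which seeds are supplied or partitioned (see
#' [scatter_seeds()]).
#'
#' @param img Numeric matrix (2D) or 3D array of intensities.
#' @param seeds n x 2 or n x 3 integer matrix of seed voxels (1-based); each
#'   seed's intensity must be at least `threshold`.
#' @param threshold Minimum intensity (HU) for membership.
#' @param params A [grow_params()].
#' @param bbox Optional [bounding_box()] confining the growth.
#' @return Logical mask with the dimensions of `img`.
#' @examples
#' img <- matrix(c(100, 100, 100, 100, 300, 300), 2, 3)
#' grow(img, cbind(1, 1), threshold = 0, grow_params(delta = 50))
#' @export
grow <- function(img, seeds, threshold, params = grow_params(), bbox = NULL) {
  if (!is.array(img) && !is.matrix(img))
    stop("img must be a matrix or 3D array", call. = FALSE)
  dims <- dim(img)
  nd <- length(dims)
  if (!nd %in% c(2L, 3L)) stop("img must be 2D or 3D", call. = FALSE)
  seeds <- as_seed_matrix(seeds, nd)
  conn <- default_connectivity(nd, params$connectivity)
  bb <- bbox_args(bbox, dims)
  inb <- rep(TRUE, nrow(seeds))
  for (k in seq_len(nd))
    inb <- inb & seeds[, k] >= 1L & seeds[, k] <= dims[k]
  if (!all(inb)) stop("seed outside grid", call. = FALSE)
  if (any(img[seeds] < threshold))
    stop("seed intensity below threshold", call. = FALSE)
  cpp_grow(as.double(img), as.integer(dims), seeds, threshold, params$delta,
           conn, if (params$mean_mode == "frozen") 0L else 1L, bb$lo, bb$hi)
}

#' Fill enclosed cavities of a mask (inverse region growing)
#'
#' Grows the background from every bounding-box boundary voxel that is not
#' in the mask, using pure connectivity (no intensity test), and returns the
#' complement of that background within the box: the mask plus all enclosed
#' cavities. Outside the box the mask is returned unchanged. The operation
#' is idempotent and its output always contains its input.
#'
#' @param mask Logical matrix or 3D array.
#' @param bbox Optional [bounding_box()]; defaults to the full grid.
#' @param connectivity Background connectivity (`NULL` = 4 in 2D, 6 in 3D).
#' @return Logical mask of the same shape.
#' @export
fill_holes <- function(mask, bbox = NULL, connectivity = NULL) {
  if (!is.logical(mask) || !length(dim(mask)) %in% c(2L, 3L))
    stop("mask must be a logical matrix or 3D array", call. = FALSE)
  dims <- dim(mask)
  conn <- default_connectivity(length(dims), connectivity)
  bb <- bbox_args(bbox, dims)
  out <- cpp_fill_holes(mask, as.integer(dims), conn, bb$lo, bb$hi)
  # degenerate contract: a mask covering the whole box boundary yields the
  # full box, which deserves a note in interactive use
  if (all(boundary_of_box(mask, bb)))
    message("fill_holes: mask covers the entire bounding-box boundary; ",
            "returning the filled box")
  out
}

boundary_of_box <- function(mask, bb) {
  dims <- dim(mask)
  if (length(dims) == 2L) {
    sub <- mask[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], drop = FALSE]
    c(sub[1, ], sub[nrow(sub), ], sub[, 1], sub[, ncol(sub)])
  } else {
    sub <- mask[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3],
                drop = FALSE]
    c(sub[1, , ], sub[dim(sub)[1], , ], sub[, 1, ], sub[, dim(sub)[2], ],
      sub[, , 1], sub[, , dim(sub)[3]])
  }
}

#' Partition seeds into spatially interleaved groups
#'
#' Round-robin split of the seed list over its lexicographic (x, y, z)
#' order. The groups are pairwise disjoint, their union is the input, and -
#' because frozen-mean growing is order independent - growing from the full
#' set or jointly from any such partition yields the identical region. This
#' is the determinism contract that makes the algorithm safe to parallelise
#' by scattering seeds across workers.
#'
#' @param seeds n x 2 or n x 3 integer matrix of seed voxels.
#' @param n_parts Number of groups, >= 1; groups may be empty when
#'   `n_parts` exceeds the seed count.
#' @return List of `n_parts` seed matrices.
#' @export
scatter_seeds <- function(seeds, n_parts) {
  nd <- if (is.matrix(seeds)) ncol(seeds) else length(seeds[[1]])
  seeds <- as_seed_matrix(seeds, nd)
  n_parts <- as.integer(n_parts)
  if (n_parts < 1L) stop("n_parts must be at least 1", call. = FALSE)
  ord <- do.call(order, rev(lapply(seq_len(ncol(seeds)),
                                   function(j) seeds[, j])))
  sorted <- seeds[ord, , drop = FALSE]
  lapply(seq_len(n_parts), function(k) {
    if (k > nrow(sorted)) return(sorted[0, , drop = FALSE])
    sorted[seq(k, nrow(sorted), by = n_parts), , drop = FALSE]
  })
}
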