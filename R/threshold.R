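# Threshold extraction. The initial T-value separates the soft-tissue mode
# from the bone mode of the volume histogram (deepest-valley rule); per
# slice, the working threshold is the greatest value that keeps the
# seed-connected thresholded area within an allowed shrinkage of the
# previous slice's mask, found by bisection over the integer-HU bracket.

#' Threshold-search parameters
#'
#' @param t_min Lower HU bracket bound; `NULL` means "use the warm-start
#'   value passed to [optimal_slice_threshold()]".
#' @param t_max Upper HU bracket bound.
#' @param area_tolerance Allowed relative area shrinkage versus the previous
#'   slice's mask (the tau in `A(T) >= (1 - tau) * area(prev)`), in (0, 1).
#' @param bisection_tol Bracket width (HU) at which bisection stops; on
#'   integer-valued CT the default of 1 HU makes the search exact.
#' @param bone_premask_hu Optional mandible pre-mask threshold: voxels below
#'   it can be excluded before any per-slice work (1400 HU is the standard
#'   choice for extracting mandibular bone).
#' @param hist_bin_width Bin width (HU) used when the initial T-value is
#'   derived from the volume histogram.
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(t_min = NULL, t_max = 3000,
                             area_tolerance = 0.10, bisection_tol = 1,
                             bone_premask_hu = 1400, hist_bin_width = 10) {
  if (!is.null(t_min) && t_min >= t_max)
    stop("t_min must be below t_max", call. = FALSE)
  if (area_tolerance <= 0 || area_tolerance >= 1)
    stop("area_tolerance must be in (0, 1)", call. = FALSE)
  if (bisection_tol < 1)
    stop("bisection_tol must be at least 1 HU", call. = FALSE)
  structure(list(t_min = t_min, t_max = t_max,
                 area_tolerance = area_tolerance,
                 bisection_tol = bisection_tol,
                 bone_premask_hu = bone_premask_hu,
                 hist_bin_width = hist_bin_width),
            class = "threshold_params")
}

# Plateau-aware local maxima of a count vector: indices of runs strictly
# higher than both neighbours (run midpoint reported).
local_maxima <- function(counts) {
  n <- length(counts)
  if (n == 0L) return(integer())
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer()
  for (k in seq_along(r$values)) {
    left <- if (k == 1L) -Inf else r$values[k - 1L]
    right <- if (k == length(r$values)) -Inf else r$values[k + 1L]
    if (r$values[k] > left && r$values[k] > right && r$values[k] > 0)
      out <- c(out, (starts[k] + ends[k]) %/% 2L)
  }
  out
}

#' Initial T-value from a histogram
#'
#' Finds the threshold that separates the soft-tissue mode from the bone
#' mode: the deepest valley (minimum-count bin) between the two dominant
#' histogram peaks above the background peak. When the darkest local
#' maximum is also the global one and at least three peaks exist, it is
#' taken to be the (air) background peak and excluded. Ties in the valley
#' are broken toward the midpoint of the longest tied run of bins.
#'
#' @param h An [intensity_histogram()].
#' @return The initial T-value (HU), guaranteed to lie strictly between the
#'   two mode locations.
#' @export
initial_t_value <- function(h) {
  stopifnot(inherits(h, "intensity_histogram"))
  counts <- h$counts
  peaks <- local_maxima(counts)
  if (length(peaks) >= 3L && peaks[1] == which.max(counts))
    peaks <- peaks[-1]                      # drop the background (air) peak
  if (length(peaks) < 2L)
    stop("degenerate histogram: fewer than two intensity modes above ",
         "background; supply the initial T-value manually", call. = FALSE)
  top2 <- peaks[order(counts[peaks], decreasing = TRUE)[1:2]]
  p_lo <- min(top2); p_hi <- max(top2)
  between <- (p_lo + 1L):(p_hi - 1L)
  if (length(between) == 0L || p_hi - p_lo < 2L)
    stop("degenerate histogram: dominant modes are adjacent", call. = FALSE)
  seg <- counts[between]
  tied <- which(seg == min(seg))
  # midpoint of the longest contiguous tied run (first such run on a tie)
  runs <- split(tied, cumsum(c(1L, diff(tied) != 1L)))
  best <- runs[[which.max(lengths(runs))]]
  valley <- between[best[(length(best) + 1L) %/% 2L]]
  h$mids[valley]
}

#' Optimal per-slice threshold by bisection
#'
#' Let `A(T)` be the area of the connected component(s) of the thresholded
#' slice containing the seeds. `A` is non-increasing in `T`; the optimum is
#' the greatest `T` in the bracket with
#' `A(T) >= (1 - area_tolerance) * area(prev_mask)` - the leak-safest
#' threshold that still keeps the shape and size inherited from the
#' neighbouring slice. The search runs on the integer HU grid by bisection;
#' `t_init` (the T-value transmitted from the previous slice) is used as the
#' first probe, which speeds the search up but never changes the answer.
#'
#' @param slice_img 2D numeric matrix (HU), typically already denoised.
#' @param prev_mask Logical matrix: the previous slice's mask (nonempty).
#' @param t_init Warm-start threshold (HU).
#' @param seeds n x 2 integer matrix of seed pixels (1-based).
#' @param params A [threshold_params()].
#' @param connectivity Pixel connectivity used for `A(T)`, 4 or 8.
#' @param bbox Optional in-slice [bounding_box()] restricting `A(T)`.
#' @return The optimal threshold (HU).
#' @export
optimal_slice_threshold <- function(slice_img, prev_mask, t_init, seeds,
                                    params = threshold_params(),
                                    connectivity = 4L, bbox = NULL) {
  stopifnot(is.matrix(slice_img))
  if (!is.logical(prev_mask) || !any(prev_mask))
    stop("prev_mask must be a nonempty logical mask", call. = FALSE)
  seeds <- as_seed_matrix(seeds, 2L)
  target <- (1 - params$area_tolerance) * mask_area(prev_mask)
  lo <- as.integer(floor(params$t_min %||% t_init))
  hi <- as.integer(ceiling(params$t_max))
  t_init <- as.integer(round(t_init))
  if (t_init < lo || t_init > hi)
    stop("t_init must lie inside the search bracket", call. = FALSE)
  bb <- bbox_args(bbox, dim(slice_img))
  area_at <- function(t)
    cpp_threshold_component_area(slice_img, dim(slice_img), seeds, t,
                                 connectivity, bb$lo, bb$hi)
  if (area_at(lo) < target)
    stop_threshold_failure(lo, hi, target)
  if (area_at(hi) >= target) return(as.numeric(hi))
  # invariant: lo feasible, hi infeasible; warm start is just the first probe
  first <- TRUE
  while (hi - lo > params$bisection_tol) {
    mid <- if (first && t_init > lo && t_init < hi) t_init
    else (lo + hi) %/% 2L
    first <- FALSE
    if (area_at(mid) >= target) lo <- mid else hi <- mid
  }
  as.numeric(lo)
}

stop_threshold_failure <- function(lo, hi, target) {
  stop(structure(class = c("toothprop_threshold_failure", "error", "condition"),
                 list(message = sprintf(
                   "no threshold in [%d, %d] keeps the seed component above %.1f px",
                   lo, hi, target),
                   call = NULL)))
}

# Normalise seed input (matrix, data.frame or list of coordinate vectors)
# to an n x nd integer matrix.
as_seed_matrix <- function(seeds, nd) {
  if (is.list(seeds) && !is.data.frame(seeds))
    seeds <- do.call(rbind, seeds)
  seeds <- as.matrix(seeds)
  if (nrow(seeds) == 0L) stop("seeds must be nonempty", call. = FALSE)
  if (ncol(seeds) != nd)
    stop(sprintf("seeds must have %d coordinate columns", nd), call. = FALSE)
  storage.mode(seeds) <- "integer"
  seeds
}

# Convert an optional bounding box to the 1-based lo/hi vectors the C++
# routines expect (full grid when NULL).
bbox_args <- function(bbox, dims) {
  nd <- length(dims)
  if (is.null(bbox))
    return(list(lo = rep(1L, nd), hi = as.integer(dims)))
  if (!inherits(bbox, "bounding_box"))
    stop("bbox must be a bounding_box", call. = FALSE)
  if (length(bbox$lo) != nd)
    stop("bounding box dimensionality does not match the grid", call. = FALSE)
  if (any(bbox$hi > dims))
    stop("bounding box exceeds grid extent", call. = FALSE)
  list(lo = bbox$lo, hi = bbox$hi)
}
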