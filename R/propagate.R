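# The slice-propagation control loop. Starting from a user-seeded reference
# slice, per-tooth thresholds (T-values) and shapes travel slice to slice in
# both axial directions: denoise, re-derive seeds from the previous mask,
# re-optimise the threshold under the previous shape, grow, fill interior
# holes, prune branches that leaked into socket bone against the dilated
# previous mask, then accept/retry on an over-/under-segmentation check.

#' Propagation parameters
#'
#' @param median_kernel Odd width of the per-slice median denoising kernel.
#' @param dilation_radius Branch-removal dilation radius in pixels; the
#'   working range is 2-5.
#' @param size_change_max Fractional slice-to-slice area change that
#'   triggers the over-/under-segmentation retry, in (0, 1).
#' @param max_retries Maximum threshold-adjustment retries per tooth per
#'   slice.
#' @param retry_t_step Threshold adjustment (HU) applied per retry.
#' @return An object of class `propagation_params`.
#' @export
propagation_params <- function(median_kernel = 3L, dilation_radius = 3,
                               size_change_max = 0.3, max_retries = 5L,
                               retry_t_step = 20) {
  median_kernel <- as.integer(median_kernel)
  if (median_kernel < 1L || median_kernel %% 2L == 0L)
    stop("median_kernel must be odd and >= 1", call. = FALSE)
  if (dilation_radius < 2 || dilation_radius > 5)
    stop("dilation_radius must lie in [2, 5]", call. = FALSE)
  if (size_change_max <= 0 || size_change_max >= 1)
    stop("size_change_max must be in (0, 1)", call. = FALSE)
  if (max_retries < 1L) stop("max_retries must be >= 1", call. = FALSE)
  structure(list(median_kernel = median_kernel,
                 dilation_radius = dilation_radius,
                 size_change_max = size_change_max,
                 max_retries = as.integer(max_retries),
                 retry_t_step = retry_t_step),
            class = "propagation_params")
}

#' Median denoising of a slice
#'
#' Square median filter with reflected edges; `kernel = 1` is the identity.
#'
#' @param slice_img 2D numeric matrix.
#' @param kernel Odd kernel width in pixels.
#' @return Denoised matrix of the same shape.
#' @export
median_denoise <- function(slice_img, kernel = 3L) {
  if (!is.matrix(slice_img)) stop("slice_img must be a matrix", call. = FALSE)
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("kernel must be odd and >= 1", call. = FALSE)
  cpp_median2d(slice_img, kernel)
}

# Euclidean dilation/erosion via distance transforms, computed on a cropped
# window around the mask for speed.
dilate_mask <- function(mask, radius) {
  if (!any(mask) || radius <= 0) return(mask)
  ext <- mask_extent(mask, pad = as.integer(ceiling(radius)) + 1L)
  sub <- mask[ext$lo[1]:ext$hi[1], ext$lo[2]:ext$hi[2], drop = FALSE]
  d <- EBImage::distmap(1 - sub)          # distance to the mask
  out <- mask
  out[ext$lo[1]:ext$hi[1], ext$lo[2]:ext$hi[2]] <- sub | (d <= radius)
  out
}

erode_mask <- function(mask, radius) {
  if (!any(mask) || radius <= 0) return(mask)
  ext <- mask_extent(mask, pad = 1L)
  sub <- mask[ext$lo[1]:ext$hi[1], ext$lo[2]:ext$hi[2], drop = FALSE]
  # pad with background so the image border never protects mask pixels
  padded <- matrix(0, nrow(sub) + 2L, ncol(sub) + 2L)
  padded[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub
  d <- EBImage::distmap(padded)           # distance to background
  keep <- d[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L), drop = FALSE] > radius
  out <- mask
  out[ext$lo[1]:ext$hi[1], ext$lo[2]:ext$hi[2]] <- sub & keep
  out
}

# Distance of every pixel to a mask (0 inside the mask).
dist_to_mask <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  EBImage::distmap(1 - mask)
}

#' Remove branches leaked into socket bone
#'
#' Keeps only the part of the current mask that is compatible with the
#' previous slice's shape: the connected component of
#' `cur_mask & dilate(prev_mask, radius)` that contains the propagated
#' seeds. Everything outside the dilated previous mask - typically a thin
#' branch that leaked into the socket - is discarded.
#'
#' @param cur_mask,prev_mask Logical matrices; `prev_mask` nonempty.
#' @param radius Dilation radius in pixels (working range 2-5).
#' @param seeds n x 2 integer matrix of seed pixels.
#' @param connectivity Pixel connectivity (default 4).
#' @return Logical matrix, a subset of both `cur_mask` and the dilated
#'   `prev_mask`; empty when no seed survives the intersection.
#' @export
remove_branches <- function(cur_mask, prev_mask, radius, seeds,
                            connectivity = 4L) {
  stopifnot(is.logical(cur_mask), is.logical(prev_mask))
  if (!any(prev_mask)) stop("prev_mask must be nonempty", call. = FALSE)
  if (radius < 1) stop("radius must be at least 1 pixel", call. = FALSE)
  seeds <- as_seed_matrix(seeds, 2L)
  inter <- cur_mask & dilate_mask(prev_mask, radius)
  if (!any(inter)) return(inter)
  cpp_mask_component(inter, dim(inter), seeds, as.integer(connectivity))
}

#' Over-/under-segmentation check
#'
#' Compares the current and previous mask areas: with
#' `r = area(cur) / area(prev)`, returns `"over"` if
#' `r > 1 + size_change_max`, `"under"` if `r < 1 - size_change_max`, else
#' `"ok"`.
#'
#' @param cur_mask,prev_mask Logical matrices; `prev_mask` nonempty.
#' @param size_change_max Tolerated fractional area change.
#' @return One of `"ok"`, `"over"`, `"under"`.
#' @export
check_segmentation <- function(cur_mask, prev_mask, size_change_max = 0.3) {
  if (!any(prev_mask)) stop("prev_mask must be nonempty", call. = FALSE)
  r <- mask_area(cur_mask) / mask_area(prev_mask)
  if (r > 1 + size_change_max) "over"
  else if (r < 1 - size_change_max) "under"
  else "ok"
}

# Per-slice, per-tooth segmentation state.
slice_seg_state <- function(z, masks, t_values, status, bbox) {
  structure(list(z = as.integer(z), masks = masks, t_values = t_values,
                 status = status, bbox = bbox),
            class = "slice_seg_state")
}

#' @export
print.slice_seg_state <- function(x, ...) {
  act <- sum(x$status == "active")
  cat(sprintf("<slice_seg_state> z = %d, %d/%d teeth active\n",
              x$z, act, length(x$status)))
  invisible(x)
}

active_teeth <- function(state) names(state$status)[state$status == "active"]

#' Propagate the segmentation to one neighbouring slice
#'
#' Runs the per-slice pipeline for every active tooth independently:
#' median-denoise the slice; derive seeds from the previous mask (eroded by
#' one pixel, kept where the slice exceeds the previous T-value, with the
#' mask centroid as fallback); re-optimise the threshold by bisection,
#' warm-started at the previous T-value; grow; fill holes within the
#' tooth's local bounding box; remove branches against the dilated previous
#' mask; and check for over-/under-segmentation, retrying with an adjusted
#' threshold up to `max_retries` times before accepting the attempt whose
#' area ratio is closest to 1. A tooth whose mask comes out empty is marked
#' terminated (root apex or crown end reached). Pixels claimed by more than
#' one tooth are assigned to the tooth whose previous mask is nearest.
#'
#' When the threshold search has no feasible value (e.g. a transient shape
#' jump), the previous T-value is carried over unchanged and the event is
#' recorded in the log.
#'
#' @param prev A `slice_seg_state` with at least one active tooth.
#' @param slice_img 2D numeric matrix: the raw slice to segment.
#' @param params A [propagation_params()].
#' @param tparams A [threshold_params()].
#' @param gparams A [grow_params()].
#' @param z Index of the new slice (defaults to `prev$z + 1`).
#' @return A new `slice_seg_state`; its `log` attribute holds one row per
#'   processed tooth with the threshold, area, status and retry count.
#' @export
propagate_slice <- function(prev, slice_img, params = propagation_params(),
                            tparams = threshold_params(),
                            gparams = grow_params(),
                            z = prev$z + 1L) {
  stopifnot(inherits(prev, "slice_seg_state"))
  act <- active_teeth(prev)
  if (length(act) == 0L)
    stop("previous state has no active teeth", call. = FALSE)
  den <- median_denoise(slice_img, params$median_kernel)
  bbox2d <- bbox_xy(prev$bbox)
  conn <- default_connectivity(2L, gparams$connectivity)

  masks <- prev$masks
  tvals <- prev$t_values
  status <- prev$status
  seeds_used <- list()
  logs <- list()

  for (id in act) {
    pm <- prev$masks[[id]]
    pT <- prev$t_values[[id]]
    res <- segment_tooth_slice(den, pm, pT, params, tparams, gparams,
                               bbox2d, conn)
    seeds_used[[id]] <- res$seeds
    masks[[id]] <- res$mask
    tvals[[id]] <- res$t_value
    status[[id]] <- if (any(res$mask)) "active" else "terminated"
    logs[[id]] <- data.frame(z = z, tooth = id, t_value = res$t_value,
                             area = mask_area(res$mask),
                             status = status[[id]], retries = res$retries,
                             threshold_fallback = res$fallback,
                             stringsAsFactors = FALSE)
  }

  resolved <- resolve_contested(masks[act], prev$masks[act])
  for (id in act) {
    if (!identical(resolved[[id]], masks[[id]])) {
      # reassignment can split a mask; keep the seed-connected piece so every
      # per-slice mask stays connected (and, through the seeds inherited from
      # the previous mask, 3D-connected across slices)
      masks[[id]] <- seed_component(resolved[[id]], seeds_used[[id]], conn)
      logs[[id]]$area <- mask_area(masks[[id]])
      if (!any(masks[[id]])) {
        status[[id]] <- "terminated"
        logs[[id]]$status <- "terminated"
      }
    }
  }

  out <- slice_seg_state(z, masks, tvals, status, prev$bbox)
  attr(out, "log") <- do.call(rbind, unname(logs))
  out
}

# One tooth on one (denoised) slice: seeds -> threshold -> grow -> fill ->
# prune -> size check with retries.
segment_tooth_slice <- function(den, prev_mask, prev_t, params, tparams,
                                gparams, bbox2d, conn) {
  seeds <- derive_seeds(den, prev_mask, prev_t)
  empty <- prev_mask & FALSE

  t_cur <- prev_t
  fallback <- FALSE
  warm <- min(max(prev_t, tparams$t_min %||% prev_t), tparams$t_max)
  feasible <- tryCatch({
    t_cur <- optimal_slice_threshold(den, prev_mask, t_init = warm,
                                     seeds = seeds, params = tparams,
                                     connectivity = conn, bbox = bbox2d)
    TRUE
  }, toothprop_threshold_failure = function(e) FALSE)
  if (!feasible) fallback <- TRUE          # carry the previous T-value

  best <- NULL
  retries <- 0L
  repeat {
    keep <- seeds[den[seeds] >= t_cur, , drop = FALSE]
    if (nrow(keep) == 0L) {
      attempt <- list(mask = empty, r = 0)
    } else {
      m <- grow(den, keep, t_cur, gparams, bbox = bbox2d)
      ext <- mask_extent(m, pad = 1L)
      if (!is.null(ext)) m <- fill_holes(m, bbox = ext, connectivity = conn)
      m <- remove_branches(m, prev_mask, params$dilation_radius, keep,
                           connectivity = conn)
      attempt <- list(mask = m, r = mask_area(m) / mask_area(prev_mask))
    }
    if (is.null(best) || abs(attempt$r - 1) < abs(best$r - 1)) best <- attempt
    # the realized mask is held to the same (1 - tau) shape-continuity bound
    # the threshold search enforces on its raw-threshold surrogate; without
    # this, a threshold that is marginally feasible on the surrogate but
    # erodes the grown result can shrink the tooth a few percent per slice,
    # below the over/under detection limit
    under_lim <- 1 - min(params$size_change_max, tparams$area_tolerance)
    verdict <- if (attempt$r > 1 + params$size_change_max) "over"
    else if (attempt$r < under_lim) "under"
    else "ok"
    if (verdict == "ok") { best <- attempt; break }
    if (retries >= params$max_retries) break
    retries <- retries + 1L
    t_cur <- t_cur + if (verdict == "over") params$retry_t_step
    else -params$retry_t_step
  }
  list(mask = best$mask, t_value = t_cur, retries = retries,
       fallback = fallback, seeds = seeds)
}

# Component of `mask` holding the seeds that still lie inside it; falls back
# to the largest component when reassignment stole every seed pixel.
seed_component <- function(mask, seeds, conn) {
  if (!any(mask)) return(mask)
  inside <- mask[seeds]
  if (any(inside))
    return(cpp_mask_component(mask, dim(mask), seeds[inside, , drop = FALSE],
                              conn))
  px <- which(mask, arr.ind = TRUE)
  comps <- list()
  left <- mask
  while (any(left)) {
    p <- which(left, arr.ind = TRUE)[1, , drop = FALSE]
    cmp <- cpp_mask_component(left, dim(left), p, conn)
    comps[[length(comps) + 1L]] <- cmp
    left <- left & !cmp
  }
  comps[[which.max(vapply(comps, sum, 1))]]
}

# Seeds for the next slice: previous mask eroded by one pixel, kept where
# the (denoised) current slice still exceeds the previous T-value; the
# nearest in-mask pixel to the centroid serves as fallback.
derive_seeds <- function(den, prev_mask, prev_t) {
  er <- erode_mask(prev_mask, 1)
  cand <- which(er & den > prev_t, arr.ind = TRUE)
  if (nrow(cand) > 0L) {
    colnames(cand) <- NULL
    return(as_seed_matrix(cand, 2L))
  }
  px <- which(prev_mask, arr.ind = TRUE)
  ctr <- colMeans(px)
  i <- which.min((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2)
  as_seed_matrix(matrix(px[i, ], ncol = 2), 2L)
}

# Enforce pixel-disjointness across teeth: a pixel claimed by several teeth
# goes to the tooth whose previous mask is nearest (ties to the first tooth
# in id order).
resolve_contested <- function(masks, ref_masks) {
  if (length(masks) <= 1L) return(masks)
  acc <- Reduce(`+`, masks)
  contested <- which(acc > 1L)
  if (length(contested) == 0L) return(masks)
  dists <- vapply(names(masks), function(id) {
    dist_to_mask(ref_masks[[id]])[contested]
  }, numeric(length(contested)))
  dists <- matrix(dists, nrow = length(contested))
  winner <- apply(dists, 1, which.min)
  for (k in seq_along(masks)) {
    lose <- contested[winner != k]
    if (length(lose)) masks[[k]][lose] <- FALSE
  }
  masks
}

#' Segment all teeth of a volume by slice propagation
#'
#' Builds the reference-slice segmentation from the user seed set (growing
#' each tooth at the initial T-value derived from the volume histogram,
#' then filling holes), and propagates it independently toward increasing
#' and decreasing z until every tooth terminates or the bounding box ends.
#' The result is deterministic for fixed inputs and parameters.
#'
#' @param vol A [volume_image()].
#' @param seeds A [tooth_seed_set()].
#' @param tparams,gparams,params Parameter bundles
#'   ([threshold_params()], [grow_params()], [propagation_params()]).
#' @param t_init Optional manual initial T-value (HU); by default it is
#'   derived from the volume histogram with [initial_t_value()].
#' @param bone_premask If `TRUE`, voxels below `tparams$bone_premask_hu`
#'   are excluded from all per-slice work (mandible pre-extraction).
#' @param keep_trace If `TRUE`, keep every per-slice state in the result
#'   (memory-hungry; meant for diagnostics and invariant checks).
#' @return An object of class `tooth_segmentation` with fields `labels`
#'   (a [label_volume()]; tooth ids as integer labels), `log` (one row per
#'   slice per tooth: z, tooth, t_value, area, status, retries), `reference`
#'   (the reference-slice state), and optionally `trace`.
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_config(shape = c(64, 64, 16), n_teeth = 6,
#'                                       arch_radius_vox = 21,
#'                                       tooth_radius_vox = 3.6))
#' seg <- segment_teeth(ph$volume, ph$seeds)
#' table(seg$labels$data[seg$labels$data > 0])
#' }
#' @export
segment_teeth <- function(vol, seeds, tparams = threshold_params(),
                          gparams = grow_params(),
                          params = propagation_params(),
                          t_init = NULL, bone_premask = FALSE,
                          keep_trace = FALSE) {
  stopifnot(inherits(vol, "volume_image"), inherits(seeds, "tooth_seed_set"))
  dims <- dim(vol$data)
  bbox <- clip_bbox(seeds$bbox, dims)
  zref <- seeds$reference_slice
  data <- vol$data
  if (bone_premask)
    data[data < tparams$bone_premask_hu] <- min(data) - 1

  if (is.null(t_init)) {
    h <- intensity_histogram(data, bin_width = tparams$hist_bin_width)
    t_init <- initial_t_value(h)
  }
  # the search bracket is anchored at the histogram-derived initial T-value;
  # the per-slice warm start only steers the first bisection probe
  if (is.null(tparams$t_min)) tparams$t_min <- floor(t_init)

  ref <- reference_state(data, seeds, bbox, t_init, params, tparams, gparams)
  logs <- list(attr(ref, "log"))
  trace <- if (keep_trace) list(ref) else NULL

  states_up <- propagate_direction(ref, data, +1L, bbox, params, tparams,
                                   gparams)
  states_dn <- propagate_direction(ref, data, -1L, bbox, params, tparams,
                                   gparams)
  for (s in c(states_up, states_dn)) logs[[length(logs) + 1L]] <- attr(s, "log")
  if (keep_trace) trace <- c(trace, states_up, states_dn)

  lab <- array(0L, dim = dims)
  ids <- names(seeds$seeds)
  id_int <- as_label_ids(ids)
  stamp <- function(state) {
    for (id in names(state$masks)) {
      m <- state$masks[[id]]
      if (any(m)) {
        sl <- lab[, , state$z]
        sl[m] <- id_int[[id]]
        lab[, , state$z] <<- sl
      }
    }
  }
  stamp(ref)
  for (s in states_up) stamp(s)
  for (s in states_dn) stamp(s)

  out <- list(labels = label_volume(lab, vol$spacing, vol$origin),
              log = do.call(rbind, logs),
              reference = ref,
              t_init = t_init,
              trace = trace)
  class(out) <- "tooth_segmentation"
  out
}

#' @export
print.tooth_segmentation <- function(x, ...) {
  n <- length(unique(x$log$tooth))
  cat(sprintf("<tooth_segmentation> %d teeth over %d slices (t_init %.0f HU)\n",
              n, length(unique(x$log$z)), x$t_init))
  invisible(x)
}

as_label_ids <- function(ids) {
  v <- suppressWarnings(as.integer(ids))
  if (anyNA(v) || any(v < 1L) || anyDuplicated(v))
    v <- seq_along(ids)
  stats::setNames(as.list(v), ids)
}

# Reference-slice segmentation: grow each tooth from its user seeds at the
# initial T-value, fill holes; no previous shape exists yet, so no branch
# removal. Failure for any tooth is a hard error - the user must re-seed.
reference_state <- function(data, seeds, bbox, t_init, params, tparams,
                            gparams) {
  zref <- seeds$reference_slice
  den <- median_denoise(data[, , zref], params$median_kernel)
  bbox2d <- bbox_xy(bbox)
  conn <- default_connectivity(2L, gparams$connectivity)
  masks <- list()
  tvals <- list()
  status <- list()
  logs <- list()
  for (id in names(seeds$seeds)) {
    s <- seeds$seeds[[id]]
    if (any(den[s] < t_init))
      stop(sprintf("tooth %s: seed intensity below the initial T-value %.0f; re-seed on a brighter pixel",
                   id, t_init), call. = FALSE)
    m <- grow(den, s, t_init, gparams, bbox = bbox2d)
    ext <- mask_extent(m, pad = 1L)
    if (!is.null(ext)) m <- fill_holes(m, bbox = ext, connectivity = conn)
    if (!any(m))
      stop(sprintf("reference-slice segmentation failed for tooth %s; re-seed it", id),
           call. = FALSE)
    masks[[id]] <- m
    tvals[[id]] <- t_init
    status[[id]] <- "active"
  }
  seed_masks <- lapply(names(seeds$seeds), function(id) {
    m <- masks[[id]] & FALSE
    m[seeds$seeds[[id]]] <- TRUE
    m
  })
  names(seed_masks) <- names(seeds$seeds)
  masks <- resolve_contested(masks, seed_masks)
  for (id in names(masks))
    masks[[id]] <- seed_component(masks[[id]], seeds$seeds[[id]], conn)
  for (id in names(masks)) {
    if (!any(masks[[id]]))
      stop(sprintf("reference-slice mask for tooth %s vanished after overlap resolution; re-seed it", id),
           call. = FALSE)
    logs[[id]] <- data.frame(z = zref, tooth = id, t_value = t_init,
                             area = mask_area(masks[[id]]),
                             status = "active", retries = 0L,
                             threshold_fallback = FALSE,
                             stringsAsFactors = FALSE)
  }
  st <- slice_seg_state(zref, masks, tvals, status, bbox)
  attr(st, "log") <- do.call(rbind, unname(logs))
  st
}

propagate_direction <- function(ref, data, step, bbox, params, tparams,
                                gparams) {
  states <- list()
  state <- ref
  z <- ref$z + step
  zend <- if (step > 0L) bbox$hi[3] else bbox$lo[3]
  while (if (step > 0L) z <= zend else z >= zend) {
    if (length(active_teeth(state)) == 0L) break
    state <- propagate_slice(state, data[, , z], params, tparams, gparams,
                             z = z)
    states[[length(states) + 1L]] <- state
    z <- z + step
  }
  states
}
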