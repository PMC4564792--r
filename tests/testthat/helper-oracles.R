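# Independent oracles used against the package implementations. They are
# deliberately naive (fixed-point relaxation, brute-force distance scans)
# and share no code with the implementations they check.

# Naive region growing by fixed-point relaxation with a frozen seed mean:
# repeatedly add every voxel adjacent to the region that passes the
# intensity tests until nothing changes. Order-free by construction.
oracle_grow <- function(img, seeds, threshold, delta, connectivity,
                        bbox_lo = NULL, bbox_hi = NULL) {
  dims <- dim(img)
  nd <- length(dims)
  if (is.null(bbox_lo)) bbox_lo <- rep(1L, nd)
  if (is.null(bbox_hi)) bbox_hi <- dims
  offs <- oracle_offsets(nd, connectivity)
  inA <- array(FALSE, dims)
  inA[seeds] <- TRUE
  mu <- mean(img[seeds])
  pass <- array(FALSE, dims)
  idx_all <- which(array(TRUE, dims), arr.ind = TRUE)
  inbox <- rep(TRUE, nrow(idx_all))
  for (k in seq_len(nd))
    inbox <- inbox & idx_all[, k] >= bbox_lo[k] & idx_all[, k] <= bbox_hi[k]
  pass[idx_all[inbox, , drop = FALSE]] <- TRUE
  pass <- pass & img >= threshold & abs(img - mu) < delta
  pass[seeds] <- TRUE  # seeds belong to A by definition
  repeat {
    grew <- FALSE
    front <- which(inA, arr.ind = TRUE)
    for (i in seq_len(nrow(front))) {
      for (o in offs) {
        nb <- front[i, ] + o
        if (any(nb < 1L) || any(nb > dims)) next
        nbm <- matrix(nb, 1)
        if (!inA[nbm] && pass[nbm]) {
          inA[nbm] <- TRUE
          grew <- TRUE
        }
      }
    }
    if (!grew) break
  }
  inA
}

oracle_offsets <- function(nd, connectivity) {
  if (nd == 2L) {
    steps <- expand.grid(dx = -1:1, dy = -1:1)
    steps <- steps[!(steps$dx == 0 & steps$dy == 0), ]
    if (connectivity == 4L)
      steps <- steps[abs(steps$dx) + abs(steps$dy) == 1, ]
    lapply(seq_len(nrow(steps)), function(i) as.integer(steps[i, ]))
  } else {
    steps <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    steps <- steps[!(steps$dx == 0 & steps$dy == 0 & steps$dz == 0), ]
    if (connectivity == 6L)
      steps <- steps[abs(steps$dx) + abs(steps$dy) + abs(steps$dz) == 1, ]
    lapply(seq_len(nrow(steps)), function(i) as.integer(steps[i, ]))
  }
}

# Brute-force Euclidean dilation: a pixel is in the dilation iff some mask
# pixel lies within `radius`.
oracle_dilate <- function(mask, radius) {
  px <- which(mask, arr.ind = TRUE)
  out <- mask
  for (x in seq_len(nrow(mask))) for (y in seq_len(ncol(mask))) {
    if (out[x, y]) next
    d2 <- (px[, 1] - x)^2 + (px[, 2] - y)^2
    if (any(d2 <= radius^2)) out[x, y] <- TRUE
  }
  out
}

# Exhaustive scan for the greatest integer threshold whose seed-connected
# component keeps the required area. Uses the same A(T) primitive as the
# bisection (which is itself oracle-tested against oracle_grow), but scans
# every integer instead of bisecting.
oracle_scan_threshold <- function(slice_img, prev_mask, seeds, t_lo, t_hi,
                                  tau, connectivity = 4L) {
  target <- (1 - tau) * sum(prev_mask)
  dims <- dim(slice_img)
  for (t in seq(t_hi, t_lo)) {
    a <- toothprop:::cpp_threshold_component_area(
      slice_img, dims, seeds, t, connectivity, c(1L, 1L), dims)
    if (a >= target) return(t)
  }
  NA_integer_
}

# Random binary mask pair on a small grid (for metric property tests).
random_mask_pair <- function(dims = c(9L, 9L, 3L), p = 0.35) {
  n <- prod(dims)
  a <- array(runif(n) < p, dims)
  m <- array(runif(n) < p, dims)
  if (!any(m)) m[1] <- TRUE
  list(auto = a, manual = m)
}

# Small, fast phantom configurations for unit tests (overridable defaults).
small_cfg <- function(...) {
  args <- list(shape = c(48L, 48L, 12L), n_teeth = 4L,
               arch_radius_vox = 14, tooth_radius_vox = 3.4,
               noise_sigma = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_config, args)
}
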