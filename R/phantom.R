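# Synthetic dental-CT phantom. A mandible-like bone arch carries n_teeth
# tube-like teeth whose elliptical cross-sections drift gradually from slice
# to slice. Materials, darkest to lightest: air background, soft tissue,
# socket (alveolar) bone, tooth dentin/enamel shell. Each tooth contains an
# interior core (pulp chamber plus circumpulpal dentin) that is darker than
# the shell, so plain thresholding leaves interior holes - the failure mode
# the hole-filling step exists for. The tooth/socket contrast gap is a knob;
# shrinking it reproduces the near-isointense regime that makes dental CT
# segmentation hard.

#' Phantom configuration
#'
#' Parameters of the synthetic dental phantom. Defaults describe a
#' 128 x 128 x 64 voxel lower-jaw scene with 14 teeth and a 150 HU
#' tooth-over-socket contrast gap under 20 HU Gaussian noise.
#'
#' The tooth interior model has two zones inside an elliptical shell: a pulp
#' kernel at `intensity_pulp`, and (with `pulp_profile = "ramp"`, the
#' default) a circumpulpal dentin mantle whose intensity rises linearly from
#' `intensity_socket` at the pulp boundary to `intensity_tooth` at the core
#' boundary, mimicking the density gradation of real dentin toward the pulp
#' chamber. `pulp_profile = "flat"` makes the whole core uniform at
#' `intensity_pulp`, giving a piecewise-constant phantom convenient for
#' exact-arithmetic tests.
#'
#' @param shape Volume dimensions (nx, ny, nz) in voxels.
#' @param n_teeth Number of teeth placed along the arch.
#' @param arch_radius_vox Radius of the jaw arch centreline, voxels.
#' @param arch_span_deg Angular span of the dentition along the arch.
#' @param tooth_radius_vox Mean tooth cross-section radius at the reference
#'   slice, voxels (geometric mean of the ellipse semi-axes).
#' @param tooth_aspect Ratio of radial to tangential ellipse semi-axis.
#' @param taper Fractional radius change per slice away from the reference
#'   slice (shape drift), in `[0, 1)`.
#' @param tilt_vox_per_slice Radial drift of each tooth centre per slice,
#'   voxels; models non-vertical tooth axes.
#' @param tooth_length_frac Fraction of the z extent each tooth spans,
#'   centred on the reference slice; 1 means full height.
#' @param core_frac Core (pulp + circumpulpal dentin) fraction of the tooth
#'   semi-axes.
#' @param pulp_frac Pulp-kernel fraction of the core semi-axes.
#' @param pulp_profile `"ramp"` (graded dentin mantle, default) or `"flat"`.
#' @param intensity_background,intensity_tissue,intensity_socket Air, soft
#'   tissue and socket-bone intensities (HU); must be strictly increasing.
#' @param intensity_tooth Tooth shell intensity (HU); defaults to
#'   `intensity_socket + contrast_gap`.
#' @param intensity_pulp Pulp intensity (HU); must be below
#'   `intensity_socket`.
#' @param contrast_gap Tooth-over-socket contrast (HU), > 0.
#' @param bone_margin_vox Socket bone padding around the teeth, voxels.
#' @param noise_sigma Additive Gaussian noise standard deviation (HU).
#' @param rng_seed Integer seed; the phantom is a pure function of the
#'   configuration.
#' @return An object of class `phantom_config`.
#' @seealso [generate_phantom()]
#' @export
phantom_config <- function(shape = c(128L, 128L, 64L),
                           n_teeth = 14L,
                           arch_radius_vox = 45,
                           arch_span_deg = 165,
                           tooth_radius_vox = 5.6,
                           tooth_aspect = 1.8,
                           taper = 0.004,
                           tilt_vox_per_slice = 0,
                           tooth_length_frac = 1,
                           core_frac = 0.5,
                           pulp_frac = 0.45,
                           pulp_profile = c("ramp", "flat"),
                           intensity_background = -1000,
                           intensity_tissue = 200,
                           intensity_socket = 1300,
                           intensity_tooth = NULL,
                           intensity_pulp = 600,
                           contrast_gap = 150,
                           bone_margin_vox = 3,
                           noise_sigma = 20,
                           rng_seed = 42L) {
  pulp_profile <- match.arg(pulp_profile)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("shape must be three dimensions of at least 8 voxels", call. = FALSE)
  if (is.null(intensity_tooth)) intensity_tooth <- intensity_socket + contrast_gap
  if (abs(intensity_tooth - intensity_socket - contrast_gap) > 1e-9)
    stop("contrast_gap must equal intensity_tooth - intensity_socket",
         call. = FALSE)
  if (!(intensity_background < intensity_tissue &&
        intensity_tissue < intensity_socket &&
        intensity_socket < intensity_tooth))
    stop("intensities must satisfy background < tissue < socket < tooth",
         call. = FALSE)
  if (intensity_pulp >= intensity_socket)
    stop("intensity_pulp must be below intensity_socket", call. = FALSE)
  if (contrast_gap <= 0) stop("contrast_gap must be positive", call. = FALSE)
  if (taper < 0 || taper >= 1) stop("taper must be in [0, 1)", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative", call. = FALSE)
  if (n_teeth < 1L) stop("need at least one tooth", call. = FALSE)
  if (core_frac <= 0 || core_frac >= 1 || pulp_frac <= 0 || pulp_frac >= 1)
    stop("core_frac and pulp_frac must be in (0, 1)", call. = FALSE)
  if (tooth_length_frac <= 0 || tooth_length_frac > 1)
    stop("tooth_length_frac must be in (0, 1]", call. = FALSE)
  structure(list(
    shape = shape, n_teeth = as.integer(n_teeth),
    arch_radius_vox = arch_radius_vox, arch_span_deg = arch_span_deg,
    tooth_radius_vox = tooth_radius_vox, tooth_aspect = tooth_aspect,
    taper = taper, tilt_vox_per_slice = tilt_vox_per_slice,
    tooth_length_frac = tooth_length_frac,
    core_frac = core_frac, pulp_frac = pulp_frac,
    pulp_profile = pulp_profile,
    intensity_background = intensity_background,
    intensity_tissue = intensity_tissue,
    intensity_socket = intensity_socket,
    intensity_tooth = intensity_tooth,
    intensity_pulp = intensity_pulp,
    contrast_gap = contrast_gap,
    bone_margin_vox = bone_margin_vox,
    noise_sigma = noise_sigma,
    rng_seed = as.integer(rng_seed)), class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<phantom_config> %s voxels, %d teeth, gap %g HU, noise %g HU, seed %d\n"),
    paste(x$shape, collapse = "x"), x$n_teeth, x$contrast_gap,
    x$noise_sigma, x$rng_seed))
  invisible(x)
}

#' Material intensities of a phantom configuration
#'
#' The distinct noiseless intensities present in a phantom built from `cfg`.
#' With the flat pulp profile this is a finite set (air, tissue, socket,
#' tooth, pulp); with the graded profile the dentin mantle spans
#' `[intensity_socket, intensity_tooth]` continuously and only the constant
#' materials are listed.
#'
#' @param cfg A [phantom_config()].
#' @return Named numeric vector of constant material intensities.
#' @export
phantom_materials <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  c(background = cfg$intensity_background,
    tissue = cfg$intensity_tissue,
    socket = cfg$intensity_socket,
    tooth = cfg$intensity_tooth,
    pulp = cfg$intensity_pulp)
}

# Tooth centre/orientation layout along the arch on the reference slice.
phantom_layout <- function(cfg) {
  nx <- cfg$shape[1]; ny <- cfg$shape[2]
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2 - 0.17 * ny          # arch centre sits below mid-plane
  span <- cfg$arch_span_deg * pi / 180
  th <- if (cfg$n_teeth == 1L) pi / 2
  else seq(pi / 2 - span / 2, pi / 2 + span / 2, length.out = cfg$n_teeth)
  a <- cfg$tooth_radius_vox * sqrt(cfg$tooth_aspect)   # radial semi-axis
  b <- cfg$tooth_radius_vox / sqrt(cfg$tooth_aspect)   # tangential semi-axis
  list(cx = cx, cy = cy, R = cfg$arch_radius_vox, theta = th, a = a, b = b,
       centers = cbind(x = cx + cfg$arch_radius_vox * cos(th),
                       y = cy + cfg$arch_radius_vox * sin(th)))
}

#' Generate a synthetic dental phantom
#'
#' Builds the phantom volume, its ground-truth per-tooth label volume and a
#' ready-to-use seed set (one seed per tooth on the middle reference slice,
#' placed in the dentin shell, plus a bounding box enclosing the dentition).
#' Same configuration, same output, bit for bit.
#'
#' @param cfg A [phantom_config()].
#' @param spacing Voxel spacing in mm (isotropic 0.2 mm by default, matching
#'   typical dental CBCT).
#' @return A list with elements `volume` ([volume_image()]), `labels`
#'   ([label_volume()]), `seeds` ([tooth_seed_set()]) and `config`.
#' @examples
#' ph <- generate_phantom(phantom_config(shape = c(48, 48, 12), n_teeth = 4,
#'                                       arch_radius_vox = 14,
#'                                       tooth_radius_vox = 3.2,
#'                                       noise_sigma = 0))
#' ph$labels
#' @export
generate_phantom <- function(cfg, spacing = c(0.2, 0.2, 0.2)) {
  stopifnot(inherits(cfg, "phantom_config"))
  nx <- cfg$shape[1]; ny <- cfg$shape[2]; nz <- cfg$shape[3]
  lay <- phantom_layout(cfg)
  zref <- (nz + 1L) %/% 2L
  half_len <- cfg$tooth_length_frac * nz / 2

  # static background: air, soft tissue, bone arch band (constant over z)
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  dxm <- xs - lay$cx; dym <- ys - lay$cy
  rad <- sqrt(dxm^2 + dym^2)
  band <- abs(rad - lay$R)
  upper <- dym >= -(lay$a + cfg$bone_margin_vox)   # U opens downward in -y
  bone2d <- band <= (lay$a + cfg$bone_margin_vox) & upper
  tissue2d <- band <= (lay$a + cfg$bone_margin_vox + 8) & dym >= -(lay$a + 12)

  base_slice <- matrix(cfg$intensity_background, nx, ny)
  base_slice[tissue2d] <- cfg$intensity_tissue
  base_slice[bone2d] <- cfg$intensity_socket

  vol <- array(rep(base_slice, nz), dim = c(nx, ny, nz))
  lab <- array(0L, dim = c(nx, ny, nz))

  gap <- cfg$intensity_tooth - cfg$intensity_socket
  mantle_lo <- cfg$intensity_socket
  rho_pulp <- cfg$core_frac * cfg$pulp_frac

  for (z in seq_len(nz)) {
    dz <- z - zref
    if (abs(dz) > half_len) next
    s <- 1 - cfg$taper * abs(dz)
    if (s * lay$b < 1.0) next                      # past the root apex
    for (i in seq_len(cfg$n_teeth)) {
      th <- lay$theta[i]
      u <- c(cos(th), sin(th))                     # radial unit vector
      v <- c(-sin(th), cos(th))                    # tangential unit vector
      ctr <- lay$centers[i, ] + cfg$tilt_vox_per_slice * dz * u
      az <- lay$a * s; bz <- lay$b * s
      xr <- max(1L, floor(ctr[1] - az - 1)):min(nx, ceiling(ctr[1] + az + 1))
      yr <- max(1L, floor(ctr[2] - az - 1)):min(ny, ceiling(ctr[2] + az + 1))
      px <- matrix(xr, length(xr), length(yr)) - ctr[1]
      py <- matrix(yr, length(xr), length(yr), byrow = TRUE) - ctr[2]
      eu <- (px * u[1] + py * u[2]) / az
      ev <- (px * v[1] + py * v[2]) / bz
      rho <- sqrt(eu^2 + ev^2)
      inside <- rho <= 1
      if (!any(inside)) next
      sel <- which(inside, arr.ind = TRUE)
      gx <- xr[sel[, 1]]; gy <- yr[sel[, 2]]
      idx <- cbind(gx, gy, z)
      prev <- lab[idx]
      if (any(prev != 0L & prev != i))
        stop(sprintf("phantom teeth %d and %d overlap at slice %d; %s",
                     unique(prev[prev != 0L & prev != i])[1], i, z,
                     "reduce tooth_radius_vox or n_teeth, or enlarge the arch"),
             call. = FALSE)
      lab[idx] <- i
      rh <- rho[inside]
      val <- rep(cfg$intensity_tooth, length(rh))
      in_core <- rh <= cfg$core_frac
      if (cfg$pulp_profile == "flat") {
        val[in_core] <- cfg$intensity_pulp
      } else {
        in_pulp <- rh <= rho_pulp
        val[in_pulp] <- cfg$intensity_pulp
        mid <- in_core & !in_pulp
        frac <- (rh[mid] - rho_pulp) / (cfg$core_frac - rho_pulp)
        val[mid] <- mantle_lo + frac * gap
      }
      vol[idx] <- val
    }
  }

  if (cfg$noise_sigma > 0) {
    vol <- vol + with_seed(cfg$rng_seed, {
      array(rnorm(length(vol), sd = cfg$noise_sigma), dim = dim(vol))
    })
  }

  seeds <- phantom_seeds(lab, lay, cfg, zref)
  tooth_idx <- which(lab != 0L, arr.ind = TRUE)
  pad <- 5L
  bbox <- bounding_box(
    pmax(apply(tooth_idx, 2, min) - pad, 1L),
    pmin(apply(tooth_idx, 2, max) + pad, cfg$shape))
  list(volume = volume_image(vol, spacing),
       labels = label_volume(lab, spacing),
       seeds = tooth_seed_set(seeds, bbox, zref),
       config = cfg)
}

# One seed per tooth on the reference slice: the label centroid, pushed
# radially outward into the dentin shell if it lands inside the dark core.
phantom_seeds <- function(lab, lay, cfg, zref) {
  seeds <- list()
  for (i in seq_len(cfg$n_teeth)) {
    w <- which(lab[, , zref] == i, arr.ind = TRUE)
    if (nrow(w) == 0L)
      stop(sprintf("tooth %d has no voxels on the reference slice", i),
           call. = FALSE)
    ctr <- colMeans(w)
    th <- lay$theta[i]
    u <- c(cos(th), sin(th))
    # mid-shell target: halfway between core boundary and rim, radially
    target_rho <- (cfg$core_frac + 1) / 2
    cand <- round(ctr)
    if (lab[cand[1], cand[2], zref] != i ||
        in_core(cand, lay, cfg, i)) {
      cand <- round(c(lay$centers[i, 1] + target_rho * lay$a * u[1],
                      lay$centers[i, 2] + target_rho * lay$a * u[2]))
    }
    if (lab[cand[1], cand[2], zref] != i)
      stop(sprintf("could not place a shell seed for tooth %d", i),
           call. = FALSE)
    seeds[[as.character(i)]] <- matrix(as.integer(cand), ncol = 2)
  }
  seeds
}

in_core <- function(p, lay, cfg, i) {
  th <- lay$theta[i]
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  d <- as.numeric(p) - lay$centers[i, ]
  rho <- sqrt(((d[1] * u[1] + d[2] * u[2]) / lay$a)^2 +
              ((d[1] * v[1] + d[2] * v[2]) / lay$b)^2)
  rho <= cfg$core_frac
}

# Evaluate an expression with a fixed RNG seed, restoring the caller's RNG
# state afterwards so phantom generation never perturbs user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Intensity histogram of a volume
#'
#' Fixed-width binning over the full intensity range; the counts always sum
#' to the voxel count.
#'
#' @param vol A [volume_image()] or numeric array.
#' @param bin_width Bin width in HU, > 0.
#' @return An object of class `intensity_histogram` with fields `bin_edges`
#'   (length `nbin + 1`), `mids` and `counts`.
#' @export
intensity_histogram <- function(vol, bin_width = 10) {
  if (inherits(vol, "volume_image")) vol <- vol$data
  if (!is.numeric(vol)) stop("vol must be numeric", call. = FALSE)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be positive", call. = FALSE)
  lo <- min(vol); hi <- max(vol)
  nb <- max(1L, as.integer(ceiling((hi - lo) / bin_width + 1e-9)))
  edges <- lo + bin_width * (0:nb)
  bin <- pmin(floor((as.vector(vol) - lo) / bin_width) + 1L, nb)
  counts <- tabulate(bin, nbins = nb)
  structure(list(bin_edges = edges,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d bins over [%g, %g], %d voxels\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges),
              sum(x$counts)))
  invisible(x)
}
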