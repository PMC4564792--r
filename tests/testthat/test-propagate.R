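test_that("median denoising follows the textbook cases", {
  flat <- matrix(250, 8, 8)
  expect_identical(median_denoise(flat, 3L), flat)
  salty <- matrix(100, 9, 9)
  salty[5, 5] <- 3000
  den <- median_denoise(salty, 3L)
  expect_equal(den[5, 5], 100)
  expect_identical(den, matrix(100, 9, 9))
  img <- matrix(rnorm(64), 8, 8)
  expect_identical(median_denoise(img, 1L), img)
  expect_error(median_denoise(img, 4L), "odd")
})

test_that("remove_branches prunes leaks beyond the dilated previous mask", {
  prev <- matrix(FALSE, 40, 30)
  prev[10:14, 10:14] <- TRUE
  # current mask: same square plus a 20-px one-pixel arm leaking away
  cur <- prev
  cur[15:34, 12] <- TRUE
  seeds <- cbind(12L, 12L)
  out <- remove_branches(cur, prev, radius = 3, seeds)
  expect_true(all(out[prev]))
  expect_true(all(out[cur] | !out[cur]))  # out is a mask
  expect_true(all(!out[!cur]))            # output within cur
  dil <- oracle_dilate(prev, 3)
  expect_true(all(!out[!dil]))            # output within dilation oracle
  expect_false(any(out[20:34, 12]))       # distal arm removed
  expect_true(sum(out[15:34, 12]) <= 3)   # at most the first 3 arm pixels

  expect_identical(remove_branches(prev, prev, 3, seeds), prev)

  far <- matrix(FALSE, 40, 30); far[30:33, 25:28] <- TRUE
  expect_false(any(remove_branches(far, prev, 3, seeds)))
})

test_that("the size check classifies area ratios", {
  a <- matrix(FALSE, 10, 10); a[2:5, 2:5] <- TRUE
  expect_identical(check_segmentation(a, a, 0.3), "ok")
  b <- matrix(FALSE, 10, 10); b[1:8, 1:4] <- TRUE   # 32 px vs 16 px -> r = 2
  expect_identical(check_segmentation(b, a, 0.3), "over")
  expect_identical(check_segmentation(a & FALSE, a, 0.3), "under")
  expect_error(check_segmentation(a, a & FALSE), "nonempty")
})

test_that("propagation through identical slices is a fixed point", {
  cfg <- small_cfg()   # noiseless, taper drifts slowly
  ph <- generate_phantom(cfg)
  seg <- segment_teeth(ph$volume, ph$seeds, keep_trace = TRUE)
  ref <- seg$reference
  z <- ref$z
  # re-propagate onto a copy of the reference slice itself: shapes and
  # T-values must reproduce themselves
  once <- propagate_slice(ref, ph$volume$data[, , z], z = z + 1L)
  twice <- propagate_slice(once, ph$volume$data[, , z], z = z + 2L)
  for (id in names(ref$masks)) {
    expect_identical(twice$masks[[id]], once$masks[[id]])
    expect_identical(twice$t_values[[id]], once$t_values[[id]])
  }
})

test_that("a tapering tooth shrinks within bounds and stays active", {
  cfg <- phantom_config(shape = c(64L, 64L, 20L), n_teeth = 1L,
                        arch_radius_vox = 18, tooth_radius_vox = 6,
                        taper = 0.03, noise_sigma = 0)
  ph <- generate_phantom(cfg)
  seg <- segment_teeth(ph$volume, ph$seeds, keep_trace = TRUE)
  lg <- seg$log[order(seg$log$z), ]
  up <- lg[lg$z >= ph$seeds$reference_slice, ]
  r <- up$area[-1] / up$area[-nrow(up)]
  active <- up$status[-1] == "active"
  expect_true(all(r[active] >= 0.8 & r[active] <= 1.05))
})

test_that("propagation terminates past a root apex", {
  cfg <- phantom_config(shape = c(64L, 64L, 30L), n_teeth = 2L,
                        arch_radius_vox = 18, tooth_radius_vox = 5,
                        taper = 0.06, tooth_length_frac = 0.6,
                        noise_sigma = 0)
  ph <- generate_phantom(cfg)
  seg <- segment_teeth(ph$volume, ph$seeds)
  gt_z <- range(which(apply(ph$labels$data > 0, 3, any)))
  pred_z <- range(which(apply(seg$labels$data > 0, 3, any)))
  expect_true(any(seg$log$status == "terminated"))
  # prediction never extends more than one slice beyond the true extent
  expect_gte(pred_z[1], gt_z[1] - 1L)
  expect_lte(pred_z[2], gt_z[2] + 1L)
})

test_that("a single-slice volume yields the reference segmentation only", {
  cfg <- small_cfg()
  ph <- generate_phantom(cfg)
  z <- ph$seeds$reference_slice
  vol1 <- volume_image(ph$volume$data[, , z, drop = FALSE],
                       ph$volume$spacing)
  seeds1 <- tooth_seed_set(ph$seeds$seeds,
                           bounding_box(c(ph$seeds$bbox$lo[1:2], 1L),
                                        c(ph$seeds$bbox$hi[1:2], 1L)),
                           reference_slice = 1L)
  seg1 <- segment_teeth(vol1, seeds1)
  expect_identical(sort(unique(seg1$log$z)), 1L)
  full <- segment_teeth(ph$volume, ph$seeds)
  expect_identical(seg1$labels$data[, , 1], full$labels$data[, , z])
})

test_that("per-slice tooth masks are pairwise disjoint everywhere", {
  ph <- generate_phantom(small_cfg(noise_sigma = 20))
  seg <- segment_teeth(ph$volume, ph$seeds, keep_trace = TRUE)
  for (st in seg$trace) {
    acc <- Reduce(`+`, st$masks)
    expect_true(all(acc <= 1L), label = sprintf("slice %d", st$z))
  }
})

test_that("z-mirroring the volume mirrors the segmentation", {
  cfg <- phantom_config(shape = c(48L, 48L, 11L), n_teeth = 4L,
                        arch_radius_vox = 14, tooth_radius_vox = 3.4,
                        taper = 0.01, noise_sigma = 10)
  ph <- generate_phantom(cfg)
  nz <- dim(ph$volume$data)[3]
  segf <- segment_teeth(ph$volume, ph$seeds)
  volm <- volume_image(ph$volume$data[, , nz:1], ph$volume$spacing)
  bb <- ph$seeds$bbox
  seedsm <- tooth_seed_set(ph$seeds$seeds,
                           bounding_box(c(bb$lo[1:2], nz + 1L - bb$hi[3]),
                                        c(bb$hi[1:2], nz + 1L - bb$lo[3])),
                           nz + 1L - ph$seeds$reference_slice)
  segm <- segment_teeth(volm, seedsm)
  expect_identical(segm$labels$data, segf$labels$data[, , nz:1])
})

test_that("a reference-slice seed failure is a hard error naming the tooth", {
  ph <- generate_phantom(small_cfg())
  bad <- ph$seeds
  bad$seeds[["3"]] <- matrix(c(bad$bbox$lo[1], bad$bbox$lo[2]), ncol = 2)
  expect_error(segment_teeth(ph$volume, bad), "tooth 3")
})
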