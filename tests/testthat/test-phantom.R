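test_that("default phantom carries 14 disjoint teeth with per-tooth seeds", {
  ph <- generate_phantom(phantom_config())
  labs <- setdiff(sort(unique(as.vector(ph$labels$data))), 0L)
  expect_identical(labs, 1:14)
  expect_identical(dim(ph$labels$data), dim(ph$volume$data))
  expect_length(ph$seeds$seeds, 14L)
  zref <- ph$seeds$reference_slice
  for (id in names(ph$seeds$seeds)) {
    s <- ph$seeds$seeds[[id]]
    expect_identical(ph$labels$data[s[1, 1], s[1, 2], zref], as.integer(id))
  }
})

test_that("phantom generation is a pure function of its configuration", {
  cfg <- small_cfg(noise_sigma = 15)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$seeds, b$seeds)
  # and the caller's RNG state is untouched
  set.seed(99); before <- .Random.seed
  generate_phantom(cfg)
  expect_identical(.Random.seed, before)
})

test_that("noiseless construction puts exact material values in place", {
  cfg <- small_cfg(contrast_gap = 200, pulp_profile = "flat")
  ph <- generate_phantom(cfg)
  tooth_vox <- ph$volume$data[ph$labels$data > 0]
  expect_true(all(tooth_vox %in% c(cfg$intensity_tooth, cfg$intensity_pulp)))
  # every tooth voxel outside the pulp core is exactly the shell intensity
  expect_true(all(tooth_vox[tooth_vox != cfg$intensity_pulp] ==
                    cfg$intensity_tooth))
  # graded profile keeps the shell flat and the core within [pulp, tooth]
  phr <- generate_phantom(small_cfg(contrast_gap = 200))
  core <- phr$volume$data[phr$labels$data > 0]
  expect_true(all(core >= phr$config$intensity_pulp &
                    core <= phr$config$intensity_tooth))
})

test_that("global mid-gap threshold recovers teeth minus pulp at high contrast", {
  cfg <- small_cfg(contrast_gap = 300, pulp_profile = "flat")
  ph <- generate_phantom(cfg)
  thr <- (cfg$intensity_socket + cfg$intensity_tooth) / 2
  recovered <- ph$volume$data >= thr
  expected <- ph$labels$data > 0 & ph$volume$data == cfg$intensity_tooth
  expect_identical(recovered & ph$labels$data > 0, expected)
  # nothing outside the teeth passes the mid-gap threshold
  expect_false(any(recovered & ph$labels$data == 0))
})

test_that("tooth cross-sections drift gradually between adjacent slices", {
  cfg <- phantom_config(shape = c(64L, 64L, 24L), n_teeth = 1L,
                        arch_radius_vox = 18, tooth_radius_vox = 6,
                        taper = 0.01, noise_sigma = 0)
  ph <- generate_phantom(cfg)
  areas <- apply(ph$labels$data == 1L, 3, sum)
  areas <- areas[areas > 0]
  radii <- sqrt(areas)
  rel <- abs(diff(radii)) / radii[-length(radii)]
  # per-slice radius drift stays at the configured taper up to rasterisation
  expect_lt(max(rel), cfg$taper + 0.035)
  expect_lt(abs(mean(rel) - cfg$taper), cfg$taper)
})

test_that("overlapping tooth layouts are rejected, never merged", {
  expect_error(generate_phantom(small_cfg(tooth_radius_vox = 8)), "overlap")
})

test_that("intensity histogram counts every voxel exactly once", {
  v <- volume_image(array(500, c(6, 6, 2)))
  h <- intensity_histogram(v, bin_width = 10)
  expect_equal(sum(h$counts), 72)
  expect_equal(sum(h$counts > 0), 1L)

  ph <- generate_phantom(small_cfg(pulp_profile = "flat"))
  h2 <- intensity_histogram(ph$volume, bin_width = 5)
  expect_equal(sum(h2$counts), prod(dim(ph$volume$data)))
  mats <- phantom_materials(ph$config)
  present <- mats[vapply(mats, function(m)
    any(abs(ph$volume$data - m) < 1e-9), TRUE)]
  expect_equal(sum(h2$counts > 0), length(unique(present)))

  noisy <- generate_phantom(small_cfg(noise_sigma = 25))
  h3 <- intensity_histogram(noisy$volume, bin_width = 17)
  expect_equal(sum(h3$counts), prod(dim(noisy$volume$data)))
})

test_that("configuration invariants are enforced", {
  expect_error(phantom_config(intensity_pulp = 1400), "pulp")
  expect_error(phantom_config(contrast_gap = -5), "contrast_gap|satisfy")
  expect_error(phantom_config(taper = 1), "taper")
  expect_error(phantom_config(noise_sigma = -1), "noise")
  expect_error(phantom_config(intensity_tooth = 2000, contrast_gap = 150),
               "contrast_gap")
  expect_error(phantom_config(intensity_tissue = -2000), "satisfy")
})
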