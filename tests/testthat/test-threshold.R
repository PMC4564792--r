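test_that("initial T-value splits two spike modes at the gap midpoint", {
  vals <- c(rep(100, 500), rep(1000, 500))
  h <- intensity_histogram(array(vals, c(10, 10, 10)), bin_width = 10)
  t0 <- initial_t_value(h)
  expect_lt(abs(t0 - 550), 10 + 1e-9)
})

test_that("initial T-value lands between tissue and bone on the phantom", {
  ph <- generate_phantom(phantom_config(noise_sigma = 0))
  h <- intensity_histogram(ph$volume, bin_width = 10)
  t0 <- initial_t_value(h)
  expect_gt(t0, ph$config$intensity_tissue)
  expect_lt(t0, ph$config$intensity_socket)
  # and with the default noise level too
  ph2 <- generate_phantom(phantom_config())
  t02 <- initial_t_value(intensity_histogram(ph2$volume, 10))
  expect_gt(t02, ph2$config$intensity_tissue)
  expect_lt(t02, ph2$config$intensity_socket)
})

test_that("degenerate histograms raise an error instead of guessing", {
  h1 <- intensity_histogram(array(700, c(5, 5, 5)), bin_width = 10)
  expect_error(initial_t_value(h1), "degenerate")
})

test_that("optimal threshold keeps a noiseless square at full area", {
  img <- matrix(1300, 30, 30)
  img[10:19, 10:19] <- 1500
  prev <- matrix(FALSE, 30, 30)
  prev[10:19, 10:19] <- TRUE
  seeds <- cbind(14:15, 14:15)
  tp <- threshold_params(t_min = 1000, t_max = 3000, area_tolerance = 0.1)
  t_star <- optimal_slice_threshold(img, prev, t_init = 1350, seeds, tp)
  expect_gt(t_star, 1300)
  expect_lte(t_star, 1500)
  a <- toothprop:::cpp_threshold_component_area(
    img, dim(img), seeds, t_star, 4L, c(1L, 1L), dim(img))
  expect_equal(a, 100)
  # globally constant slice: the greatest feasible threshold is the constant
  flat <- matrix(1500, 20, 20)
  t_flat <- optimal_slice_threshold(flat, prev[6:25, 6:25], 1200,
                                    cbind(10L, 10L),
                                    threshold_params(t_min = 1000,
                                                     t_max = 2000))
  expect_equal(t_flat, 1500)
})

test_that("an unsatisfiable area constraint raises a threshold failure", {
  img <- matrix(500, 20, 20)   # everything below t_min
  prev <- matrix(FALSE, 20, 20); prev[8:12, 8:12] <- TRUE
  expect_error(
    optimal_slice_threshold(img, prev, 1200, cbind(10L, 10L),
                            threshold_params(t_min = 1000, t_max = 2000)),
    class = "toothprop_threshold_failure")
})

test_that("bisection equals the exhaustive integer scan on phantom slices", {
  ph <- generate_phantom(phantom_config(shape = c(96L, 96L, 20L), n_teeth = 8L,
                                        arch_radius_vox = 32,
                                        tooth_radius_vox = 5,
                                        noise_sigma = 20, rng_seed = 7L))
  den_cache <- list()
  tp <- threshold_params(t_min = 1000, t_max = 1600)
  set.seed(11)
  cases <- 0L
  while (cases < 50L) {
    z <- sample(6:15, 1)
    id <- sample(1:8, 1)
    key <- sprintf("%d", z)
    if (is.null(den_cache[[key]]))
      den_cache[[key]] <- median_denoise(ph$volume$data[, , z], 3L)
    den <- den_cache[[key]]
    gt <- ph$labels$data[, , z] == id
    if (!any(gt)) next
    shell <- gt & den > 1400
    if (sum(shell) < 4) next
    seeds <- which(shell, arr.ind = TRUE)[1:3, , drop = FALSE]
    t_bis <- tryCatch(
      optimal_slice_threshold(den, gt, t_init = 1200, seeds, tp),
      toothprop_threshold_failure = function(e) NA_real_)
    t_scan <- oracle_scan_threshold(den, gt, seeds, 1000L, 1600L, 0.10)
    if (is.na(t_bis)) {
      expect_true(is.na(t_scan))
    } else {
      expect_equal(t_bis, t_scan, tolerance = 0,
                   label = sprintf("z=%d tooth=%d", z, id))
    }
    cases <- cases + 1L
  }
})

test_that("seed-component area is monotone non-increasing in the threshold", {
  ph <- generate_phantom(small_cfg(noise_sigma = 30))
  set.seed(3)
  for (i in 1:8) {
    z <- sample(3:10, 1)
    sl <- ph$volume$data[, , z]
    id <- sample(1:4, 1)
    gt <- ph$labels$data[, , z] == id
    if (!any(gt)) next
    seeds <- which(gt, arr.ind = TRUE)[1, , drop = FALSE]
    ts <- sort(sample(800:1600, 25))
    areas <- vapply(ts, function(t) toothprop:::cpp_threshold_component_area(
      sl, dim(sl), seeds, t, 4L, c(1L, 1L), dim(sl)), 1L)
    expect_true(all(diff(areas) <= 0))
  }
})

test_that("the warm start affects speed only, never the result", {
  ph <- generate_phantom(small_cfg(noise_sigma = 20))
  z <- 6L
  den <- median_denoise(ph$volume$data[, , z], 3L)
  gt <- ph$labels$data[, , z] == 2L
  seeds <- which(gt & den > 1400, arr.ind = TRUE)[1:2, , drop = FALSE]
  tp <- threshold_params(t_min = 1000, t_max = 2000)
  res <- vapply(c(1001, 1200, 1450, 1717, 1999), function(w)
    optimal_slice_threshold(den, gt, w, seeds, tp), 1)
  expect_length(unique(res), 1L)
})
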