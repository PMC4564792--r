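test_that("growing a uniform field floods it completely", {
  img <- matrix(500, 5, 5)
  m <- grow(img, cbind(3L, 3L), threshold = 0, grow_params(delta = 10))
  expect_true(all(m))
})

test_that("the delta criterion stops growth at an intensity step", {
  # two columns of 100-valued pixels next to a 300-valued column
  img <- matrix(c(100, 100, 100, 100, 300, 300), 2, 3)
  m <- grow(img, cbind(1L, 1L), threshold = 0, grow_params(delta = 50))
  expect_identical(as.vector(m), c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("grow preconditions are enforced", {
  img <- matrix(100, 4, 4)
  expect_error(grow(img, cbind(2L, 2L), threshold = 200, grow_params(60)),
               "below threshold")
  expect_error(grow(img, matrix(integer(), 0, 2), 0, grow_params(60)),
               "nonempty")
  expect_error(grow(img, cbind(9L, 1L), 0, grow_params(60)), "outside")
  expect_error(grow_params(delta = 0), "delta")
  expect_error(grow_params(connectivity = 5), "connectivity")
})

test_that("grow matches the naive relaxation oracle on random instances", {
  set.seed(42)
  for (i in 1:30) {
    img <- matrix(sample(0:300, 144, replace = TRUE), 12, 12)
    conn <- sample(c(4L, 8L), 1)
    thr <- sample(0:150, 1)
    delta <- sample(c(40, 90, 250), 1)
    ok <- which(img >= thr, arr.ind = TRUE)
    if (nrow(ok) == 0) next
    seeds <- ok[sample(nrow(ok), sample(1:3, 1)), , drop = FALSE]
    got <- grow(img, seeds, thr, grow_params(delta, conn))
    want <- oracle_grow(img, seeds, thr, delta, conn)
    expect_identical(got, want)
  }
  for (i in 1:10) {
    img <- array(sample(0:200, 360, replace = TRUE), c(10, 6, 6))
    conn <- sample(c(6L, 26L), 1)
    thr <- sample(0:100, 1)
    ok <- which(img >= thr, arr.ind = TRUE)
    seeds <- ok[sample(nrow(ok), 2), , drop = FALSE]
    got <- grow(img, seeds, thr, grow_params(80, conn))
    want <- oracle_grow(img, seeds, thr, 80, conn)
    expect_identical(got, want)
  }
})

test_that("grow output is connected and respects threshold and bbox", {
  set.seed(7)
  for (i in 1:10) {
    img <- matrix(sample(0:200, 196, replace = TRUE), 14, 14)
    ok <- which(img >= 80, arr.ind = TRUE)
    ok <- ok[ok[, 1] >= 2 & ok[, 1] <= 13 & ok[, 2] >= 2 & ok[, 2] <= 13, ,
             drop = FALSE]
    seeds <- ok[sample(nrow(ok), 1), , drop = FALSE]
    bb <- bounding_box(c(2, 2), c(13, 13))
    m <- grow(img, seeds, 80, grow_params(150), bbox = bb)
    expect_true(all(img[m] >= 80))
    expect_false(any(m[1, ]) || any(m[14, ]) || any(m[, 1]) || any(m[, 14]))
    comp <- toothprop:::cpp_mask_component(m, dim(m), seeds, 4L)
    expect_identical(comp, m)
  }
})

test_that("a noiseless phantom slice grows to the tooth minus its dark core", {
  cfg <- small_cfg(pulp_profile = "flat")
  ph <- generate_phantom(cfg)
  z <- ph$seeds$reference_slice
  sl <- ph$volume$data[, , z]
  id <- "2"
  s <- ph$seeds$seeds[[id]]
  thr <- (cfg$intensity_socket + cfg$intensity_tooth) / 2
  m <- grow(sl, s, thr, grow_params(delta = 1e6))
  gt <- ph$labels$data[, , z] == as.integer(id)
  expect_identical(m, gt & sl == cfg$intensity_tooth)
})

test_that("fill_holes recovers enclosed cavities and is idempotent", {
  ring <- matrix(FALSE, 9, 9)
  ring[2:8, 2:8] <- TRUE
  ring[3:7, 3:7] <- FALSE
  filled <- fill_holes(ring)
  want <- matrix(FALSE, 9, 9); want[2:8, 2:8] <- TRUE
  expect_identical(filled, want)
  expect_identical(fill_holes(filled), filled)
  # a mask with no holes is a fixed point
  blob <- matrix(FALSE, 7, 7); blob[2:4, 3:5] <- TRUE
  expect_identical(fill_holes(blob), blob)
  # output always contains input
  expect_true(all(filled[ring]))
})

test_that("fill_holes on a phantom tooth slice restores the full section", {
  cfg <- small_cfg()   # graded core, noiseless
  ph <- generate_phantom(cfg)
  z <- ph$seeds$reference_slice
  sl <- ph$volume$data[, , z]
  for (id in 1:4) {
    gt <- ph$labels$data[, , z] == id
    shell <- gt & sl >= 1400
    ext <- toothprop:::mask_extent(shell, pad = 1L)
    expect_identical(fill_holes(shell, bbox = ext), gt)
  }
})

test_that("a mask covering the box boundary fills the whole box", {
  m <- matrix(TRUE, 5, 5); m[3, 3] <- FALSE
  expect_message(out <- fill_holes(m), "boundary")
  expect_true(all(out))
})

test_that("scatter_seeds partitions losslessly and preserves grow results", {
  set.seed(5)
  seeds <- unique(cbind(sample(2:11, 8, TRUE), sample(2:11, 8, TRUE)))
  parts <- scatter_seeds(seeds, 1L)
  expect_identical(nrow(parts[[1]]), nrow(seeds))
  parts2 <- scatter_seeds(seeds, 2L)
  expect_identical(length(parts2), 2L)
  joined <- do.call(rbind, parts2)
  expect_identical(nrow(joined), nrow(seeds))
  expect_identical(dim(unique(rbind(joined, seeds))), dim(seeds))
  # empty groups allowed when n_parts exceeds the seed count
  many <- scatter_seeds(seeds[1:2, , drop = FALSE], 5L)
  expect_identical(sum(vapply(many, nrow, 1L)), 2L)

  # determinism contract: joint growth from scattered parts equals growth
  # from the full seed set, for any partition count
  img <- matrix(sample(0:200, 400, replace = TRUE), 20, 20)
  img[seeds] <- 200
  full <- grow(img, seeds, 50, grow_params(120))
  for (np in c(2L, 3L, 5L)) {
    rejoined <- do.call(rbind, scatter_seeds(seeds, np))
    expect_identical(grow(img, rejoined, 50, grow_params(120)), full)
  }
})

test_that("running-mean mode is deterministic and grows uniform fields", {
  img <- matrix(500, 6, 6)
  gp <- grow_params(delta = 10, mean_mode = "running")
  m1 <- grow(img, cbind(2L, 2L), 0, gp)
  expect_true(all(m1))
  ramp <- matrix(seq(100, 160, length.out = 36), 6, 6)
  a <- grow(ramp, cbind(1L, 1L), 0, grow_params(25, mean_mode = "running"))
  b <- grow(ramp, cbind(1L, 1L), 0, grow_params(25, mean_mode = "running"))
  expect_identical(a, b)
})
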