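test_that("ROI masking thresholds and closes as specified", {
  cfg <- preprocess_config()
  z <- matrix(0, 15, 15)
  expect_true(all(make_roi_mask(slice_image(z), cfg) == 0))
  u <- matrix(255, 15, 15)
  expect_true(all(make_roi_mask(slice_image(u), cfg) == 1))
  # 3x3 dark hole in a bright 21x21 slice is filled by the 9x9 closure
  holed <- matrix(200, 21, 21)
  holed[10:12, 10:12] <- 0
  expect_true(all(make_roi_mask(slice_image(holed), cfg) == 1))
  # threshold boundary: pixels exactly at the threshold are kept
  edge <- matrix(10, 3, 3)
  expect_true(all(make_roi_mask(slice_image(edge),
                                preprocess_config(closure_kernel = 1L)) == 1))
})

test_that("a threshold outside the declared intensity range warns but masks", {
  img <- slice_image(matrix(stats::runif(64), 8, 8), range = c(0, 1))
  expect_warning(m <- make_roi_mask(img, preprocess_config()), "outside")
  expect_true(all(m %in% c(0L, 1L)))
})

test_that("morphological closure matches the brute-force dilate-erode oracle", {
  set.seed(41)
  cfg <- preprocess_config(threshold = 0.5, closure_kernel = 9L)
  for (t in 1:30) {
    m <- matrix(stats::rbinom(15 * 17, 1, stats::runif(1, 0.2, 0.6)), 15, 17)
    got <- make_roi_mask(slice_image(m, c(0, 1)), cfg)
    expect_identical(unname(got + 0), bf_closure(m, 9))
  }
})

test_that("mask multiplication is elementwise and shape-checked", {
  img <- matrix(c(5, 2, 7, 9), 2, 2)
  mask <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(unclass(apply_mask(img, mask)), matrix(c(5, 0, 0, 9), 2, 2))
  expect_equal(unclass(apply_mask(img, matrix(1, 2, 2))), img)
  expect_true(all(apply_mask(img, matrix(0, 2, 2)) == 0))
  expect_error(apply_mask(img, matrix(1, 3, 2)), "shapes differ")
})

test_that("resizing keeps constants constant and masks binary", {
  for (n in c(3L, 8L, 13L)) {
    cst <- matrix(0.7, n, n)
    expect_equal(max(abs(resize_slice(cst, 5L) - 0.7)), 0, tolerance = 1e-12)
    expect_equal(max(abs(resize_slice(cst, 2L * n) - 0.7)), 0, tolerance = 1e-12)
  }
  set.seed(2)
  m <- matrix(stats::rbinom(100, 1, 0.5), 10, 10)
  out <- resize_slice(m, 7L, is_mask = TRUE)
  expect_true(all(out %in% c(0, 1)))
})

test_that("nearest-neighbour downsizing follows the top-left index mapping", {
  cb <- matrix(0, 4, 4)
  cb[cbind(rep(1:4, 4), rep(1:4, each = 4))] <-
    (rep(1:4, 4) + rep(1:4, each = 4)) %% 2
  got <- resize_slice(cb, 2L, is_mask = TRUE)
  # source pixel for output (i, j) is (floor((i-1)*4/2)+1, ...) = (2i-1, 2j-1)
  expect_equal(unname(got), cb[c(1, 3), c(1, 3)])
  # upscale by 2 equals pixel replication
  small <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(unname(resize_slice(small, 4L, is_mask = TRUE)),
               kronecker(small, matrix(1, 2, 2)))
})

test_that("CLAHE redistributes contrast and reduces to global equalization", {
  cfg <- preprocess_config(clahe_enabled = TRUE)
  cst <- slice_image(matrix(0.5, 32, 32), c(0, 1))
  out <- clahe_enhance(cst, cfg)
  expect_equal(stats::sd(out), 0)
  # low-contrast ramp: the equalized CDF dominates the input CDF at the
  # low-intensity end (mass is pushed toward low intensities there)
  r <- slice_image(matrix(rep(seq(0.4, 0.6, length.out = 64), each = 64), 64, 64),
                   c(0, 1))
  ge_r <- clahe_enhance(r, preprocess_config(clahe_tiles = 1L, clahe_clip = Inf))
  f_in <- stats::ecdf(unclass(r)); f_out <- stats::ecdf(unclass(ge_r))
  w <- seq(0.05, 0.5, by = 0.05)
  expect_true(all(f_out(w) >= f_in(w)))
  expect_gt(sum(f_out(w) > f_in(w)), 5)
  # tiled CLAHE stretches the ramp's dynamic range
  ce <- clahe_enhance(r, preprocess_config(clahe_tiles = 4L, clahe_clip = 4))
  expect_gt(diff(range(ce)), diff(range(unclass(r))))
  # single tile + unbounded clip is exactly global histogram equalization
  set.seed(6)
  x <- matrix(stats::runif(32 * 32)^2, 32, 32)
  ge <- clahe_enhance(slice_image(x, c(0, 1)),
                      preprocess_config(clahe_tiles = 1L, clahe_clip = Inf))
  expect_equal(unclass(ge), bf_global_equalize(x), tolerance = 1e-12,
               ignore_attr = TRUE)
  # tiled path with identical periodic tiles converges to the same limit
  q <- matrix(stats::runif(16 * 16)^2, 16, 16)
  per <- rbind(cbind(q, q), cbind(q, q))
  ce2 <- clahe_enhance(slice_image(per, c(0, 1)),
                       preprocess_config(clahe_tiles = 2L, clahe_clip = 1e6))
  expect_equal(unclass(ce2), bf_global_equalize(per), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("network normalization is the declared affine map and inverts", {
  s <- slice_image(matrix(c(0, 127.5, 255, 40), 2, 2), c(0, 255))
  n <- normalize_for_network(s)
  expect_equal(n[1, 1], -1)     # raw 0 maps to the lower endpoint
  expect_equal(n[1, 2], 1)      # raw 255 maps to the upper endpoint
  expect_equal(n[2, 1], 0)      # raw midpoint 127.5 maps to 0
  back <- denormalize_from_network(n)
  expect_equal(unclass(back), unclass(s), tolerance = 1e-12)
  expect_error(normalize_for_network(s, from_range = c(3, 3)), "degenerate")
})

test_that("re-masking a masked slice keeps every surviving pixel", {
  set.seed(17)
  cfg <- preprocess_config(threshold = 60, closure_kernel = 5L)
  for (t in 1:10) {
    img <- slice_image(matrix(stats::runif(30 * 30, 0, 255), 30, 30), c(0, 255))
    m1 <- make_roi_mask(img, cfg)
    masked <- apply_mask(img, m1)
    m2 <- make_roi_mask(masked, cfg)
    surviving <- m1 == 1 & unclass(masked) >= cfg$threshold
    expect_true(all(m2[surviving] == 1))
    # thresholded pixels stay zero in the masked image
    expect_true(all(masked[unclass(img) < cfg$threshold & m1 == 0] == 0))
  }
})

test_that("whole-volume preprocessing lands in the network range", {
  vols <- micro_volumes(1L, seed = 30L)
  x <- preprocess_volume(unclass(vols[[1]]$image), micro_pre_cfg())
  expect_identical(dim(x), c(16L, 16L, 2L))
  expect_true(all(x >= -1 & x <= 1))
  y <- preprocess_volume(unclass(vols[[1]]$mask), micro_pre_cfg(), is_mask = TRUE)
  expect_true(all(y %in% c(-1, 1)))
})
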