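test_that("bin-count rules reproduce their defining formulas", {
  # Sturges
  expect_identical(bins_sturges(64), 7L)
  expect_identical(bins_sturges(1), 1L)
  expect_identical(bins_sturges(26), 6L)
  expect_error(bins_sturges(0), class = "pdff_domain_error")
  # Scott: 0..63 has s = 18.62, h = 16.25, ceil(63 / 16.25) = 4
  expect_identical(bins_scott(0:63), 4L)
  expect_identical(bins_scott(rep(3, 10)), 1L)
  expect_error(bins_scott(1), class = "pdff_domain_error")
  # Freedman-Diaconis: type-7 IQR of 0..63 is 31.5, h = 15.75
  expect_identical(bins_freedman_diaconis(0:63), 4L)
  expect_identical(bins_freedman_diaconis(rep(2, 5)), 1L)
  # zero IQR, positive range: falls back to Sturges(5) = 4
  expect_identical(bins_freedman_diaconis(c(0, 0, 0, 0, 100)), 4L)
  # median of three
  expect_identical(select_bin_count(0:63), 4L)
  expect_identical(select_bin_count(rep(1, 8)), 1L)
})

test_that("bin-count selection is invariant to shift (and Scott to scale)", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(10:500, 1), sd = runif(1, 0.5, 20))
    expect_identical(select_bin_count(x + 123.4), select_bin_count(x))
    expect_identical(bins_scott(x * 7.7), bins_scott(x))
  }
})

test_that("histograms partition the range with unit total probability", {
  h <- build_histogram(c(0, 0, 10, 10), k = 2)
  expect_equal(h$probabilities, c(0.5, 0.5))
  expect_equal(h$bin_centers, c(2.5, 7.5))

  hc <- build_histogram(rep(4.2, 9), k = 5)
  expect_equal(sum(hc$probabilities == 1), 1)

  set.seed(9)
  for (i in 1:15) {
    x <- runif(sample(2:200, 1), -5, 40)
    h <- build_histogram(x)
    expect_equal(sum(h$probabilities), 1, tolerance = 1e-12)
    expect_true(all(diff(h$bin_edges) > 0))
  }
  expect_error(build_histogram(numeric(0)), class = "pdff_empty_roi_error")
})

test_that("quantization maps ROI extrema to the level range ends", {
  v <- volume_grid(array(c(0, 25, 50, 75, 100, 0, 0, 0), c(2, 2, 2)),
                   c(1, 1, 1))
  m <- roi_mask(array(c(1, 1, 1, 1, 1, 0, 0, 0), c(2, 2, 2)))
  q <- quantize(v, m, ng = 4)
  expect_identical(as.integer(q$levels[m$values == 1]), c(1L, 2L, 3L, 4L, 4L))
  expect_identical(as.integer(q$levels[m$values == 0]), rep(0L, 3))

  vc <- volume_grid(array(8, c(2, 2, 2)), c(1, 1, 1))
  mc <- roi_mask(array(1, c(2, 2, 2)))
  expect_true(all(quantize(vc, mc, ng = 200)$levels == 1))
})

test_that("quantization is invariant under increasing affine maps", {
  set.seed(3)
  for (i in 1:10) {
    vals <- array(runif(64, 0, 100), c(4, 4, 4))
    m <- roi_mask(array(rbinom(64, 1, 0.8), c(4, 4, 4)))
    if (sum(m$values) < 2) next
    q1 <- quantize(volume_grid(vals, c(1, 1, 1)), m, ng = 32)
    q2 <- quantize(volume_grid(vals * 3.7 + 11, c(1, 1, 1)), m, ng = 32)
    expect_identical(q1$levels, q2$levels)
    inmask <- q1$levels[m$values == 1]
    expect_identical(range(inmask), c(1L, 32L))
  }
})

test_that("isotropic resampling targets the minimum voxel edge", {
  set.seed(21)
  v <- volume_grid(array(runif(13 * 17 * 12, 0, 30), c(13, 17, 12)),
                   spacing = c(3.2, 2.0, 4.0))
  m <- roi_mask(array(1, c(13, 17, 12)), spacing = c(3.2, 2.0, 4.0))
  iso <- resample_isotropic(v, m)
  expect_equal(iso$volume$spacing, c(2, 2, 2))
  expect_equal(iso$mask$spacing, c(2, 2, 2))
})

test_that("resampling a constant volume yields the same constant", {
  v <- volume_grid(array(12.5, c(6, 8, 5)), spacing = c(3.2, 2.0, 4.0))
  m <- roi_mask(array(1, c(6, 8, 5)), spacing = c(3.2, 2.0, 4.0))
  iso <- resample_isotropic(v, m)
  expect_equal(range(iso$volume$values), c(12.5, 12.5))
})

test_that("already-isotropic input is returned unchanged", {
  set.seed(2)
  v <- volume_grid(array(runif(27), c(3, 3, 3)), spacing = c(2, 2, 2))
  m <- roi_mask(array(1, c(3, 3, 3)), spacing = c(2, 2, 2))
  iso <- resample_isotropic(v, m)
  expect_equal(iso$volume$values, v$values, tolerance = 1e-12)
})

test_that("mask physical volume is approximately preserved by resampling", {
  ph <- generate_phantom(phantom_config(seed = 31))
  before <- sum(ph$mask$values) * voxel_volume(ph$mask)
  iso <- resample_isotropic(ph$volume, ph$mask)
  after <- sum(iso$mask$values) * voxel_volume(iso$mask)
  expect_lt(abs(after - before) / before, 0.15)
})
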