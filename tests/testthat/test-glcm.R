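test_that("the direction set covers all 26 neighbours without duplication", {
  d <- glcm_directions()
  expect_identical(nrow(d), 13L)
  all26 <- unique(rbind(d, -d))
  expect_identical(nrow(all26), 26L)
  expect_false(any(rowSums(abs(all26)) == 0))
  # no two representatives are parallel
  for (a in 1:12) for (b in (a + 1):13) {
    expect_false(all(d[a, ] == d[b, ]) || all(d[a, ] == -d[b, ]))
  }
})

test_that("a 3-voxel line yields the antidiagonal two-level GLCM", {
  q <- quantize(volume_grid(array(c(1, 2, 1), c(1, 1, 3)), c(1, 1, 1)),
                roi_mask(array(1, c(1, 1, 3))), ng = 2)
  g <- build_glcm(q, c(0, 0, 1))
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_identical(g$pair_count, 2L)

  # constant ROI: all mass at (1, 1)
  qc <- quantize(volume_grid(array(5, c(2, 2, 2)), c(1, 1, 1)),
                 roi_mask(array(1, c(2, 2, 2))), ng = 200)
  gc <- build_glcm(qc, c(1, 0, 0))
  expect_equal(gc$p[1, 1], 1)
  expect_equal(sum(gc$p), 1)
})

test_that("GLCMs match the brute-force pair enumeration on random grids", {
  set.seed(77)
  dirs <- glcm_directions()
  for (i in 1:12) {
    q <- random_quantized_roi(sample(2:6, 3, replace = TRUE),
                              ng = sample(2:5, 1))
    for (r in seq_len(nrow(dirs))) {
      g <- build_glcm(q, dirs[r, ])
      ref <- brute_glcm(q$levels, q$ng, dirs[r, ])
      expect_equal(g$p, ref$p, tolerance = 1e-14)
      expect_identical(g$pair_count, ref$pair_count)
      expect_equal(g$p, t(g$p))  # symmetry
    }
  }
})

test_that("point-mass and antidiagonal GLCMs give the closed-form features", {
  pm <- structure(list(p = matrix(c(1, 0, 0, 0), 2, 2), offset = c(1, 0, 0),
                       pair_count = 4L, ng = 2L, skipped = FALSE),
                  class = "glcm")
  f <- glcm_features(pm)
  expect_equal(f$energy, 1)
  expect_equal(f$entropy, 0)
  expect_equal(f$contrast, 0)
  expect_equal(f$homogeneity, 1)
  expect_equal(f$dissimilarity, 0)
  expect_equal(f$sum_average, 2)
  expect_equal(f$variance, 0)
  expect_equal(f$correlation, 0)
  expect_true(f$degenerate)

  ad <- structure(list(p = matrix(c(0, 0.5, 0.5, 0), 2, 2),
                       offset = c(0, 0, 1), pair_count = 2L, ng = 2L,
                       skipped = FALSE), class = "glcm")
  f2 <- glcm_features(ad)
  expect_equal(f2$energy, 0.5)
  expect_equal(f2$entropy, 1)      # 1 bit
  expect_equal(f2$contrast, 1)
  expect_equal(f2$homogeneity, 0.5)
  expect_equal(f2$dissimilarity, 1)
  expect_equal(f2$sum_average, 3)
  expect_equal(f2$variance, 0.25)
  expect_equal(f2$correlation, -1)
})

test_that("feature inequalities and level-reversal symmetries hold", {
  set.seed(13)
  for (i in 1:10) {
    ng <- sample(3:6, 1)
    q <- random_quantized_roi(c(5, 5, 5), ng = ng)
    g <- build_glcm(q, c(1, 0, 0))
    if (g$skipped) next
    f <- glcm_features(g)
    expect_lte(f$dissimilarity^2, f$contrast + 1e-12)  # Cauchy-Schwarz
    expect_gte(f$correlation, -1 - 1e-12)
    expect_lte(f$correlation, 1 + 1e-12)

    # reverse the level axis: i -> ng + 1 - i
    grev <- g
    grev$p <- g$p[ng:1, ng:1]
    frev <- glcm_features(grev)
    for (nm in c("energy", "entropy", "contrast", "homogeneity",
                 "correlation", "variance", "dissimilarity")) {
      expect_equal(frev[[nm]], f[[nm]], tolerance = 1e-12)
    }
    expect_equal(frev$sum_average, 2 * (ng + 1) - f$sum_average,
                 tolerance = 1e-12)
  }
})

test_that("direction averaging is the arithmetic mean of the kept rows", {
  row <- function(contrast) {
    tibble::tibble(energy = 0.5, entropy = 1, contrast = contrast,
                   homogeneity = 0.5, correlation = 0, variance = 1,
                   sum_average = 3, dissimilarity = 1, degenerate = FALSE)
  }
  avg <- average_over_directions(list(row(1), row(3)))
  expect_equal(avg$contrast, 2)
  expect_equal(avg$energy, 0.5)
  expect_identical(avg$n_skipped, 0L)

  one <- average_over_directions(list(row(2), NULL, NULL))
  expect_equal(one$contrast, 2)
  expect_identical(one$n_skipped, 2L)
  expect_error(average_over_directions(list(NULL, NULL)),
               class = "pdff_degenerate_roi_error")
})

test_that("direction-averaged features are invariant under axis swaps", {
  set.seed(99)
  lv <- array(sample.int(5, 6^3, replace = TRUE), c(6, 6, 6))
  features_of <- function(levels) {
    q <- structure(list(levels = levels, ng = 5L,
                        mask = roi_mask((levels > 0) * 1,
                                        spacing = c(1, 1, 1)),
                        spacing = c(1, 1, 1)), class = "quantized_roi")
    dirs <- glcm_directions()
    rows <- lapply(seq_len(nrow(dirs)), function(r) {
      g <- build_glcm(q, dirs[r, ])
      if (g$skipped) NULL else glcm_features(g)
    })
    average_over_directions(rows)
  }
  base <- features_of(lv)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2), c(2, 3, 1))) {
    rot <- features_of(aperm(lv, perm))
    for (nm in c("energy", "entropy", "contrast", "homogeneity",
                 "correlation", "variance", "sum_average",
                 "dissimilarity")) {
      expect_equal(rot[[nm]], base[[nm]], tolerance = 1e-12)
    }
  }
})
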