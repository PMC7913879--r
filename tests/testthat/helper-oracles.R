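# Independent oracles and fixture builders, deliberately written as plain
# enumeration so they share no code with the implementation paths they check.

# Brute-force GLCM: explicit loop over every voxel and its displaced
# partner; symmetrise, normalise.
brute_glcm <- function(levels, ng, offset) {
  d <- dim(levels)
  counts <- matrix(0, ng, ng)
  pairs <- 0L
  for (x in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      for (z in seq_len(d[3])) {
        a <- levels[x, y, z]
        if (a == 0) next
        x2 <- x + offset[1]; y2 <- y + offset[2]; z2 <- z + offset[3]
        if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
            z2 < 1 || z2 > d[3]) next
        b <- levels[x2, y2, z2]
        if (b == 0) next
        counts[a, b] <- counts[a, b] + 1
        pairs <- pairs + 1L
      }
    }
  }
  sym <- counts + t(counts)
  list(p = if (pairs > 0) sym / sum(sym) else sym, pair_count = pairs)
}

# Brute-force Haralick features from a normalised symmetric matrix by
# explicit double loop over entries.
brute_glcm_features <- function(p) {
  ng <- nrow(p)
  energy <- 0; entropy <- 0; contrast <- 0; homog <- 0; dissim <- 0
  mu <- 0; sum_avg <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    v <- p[i, j]
    energy <- energy + v^2
    if (v > 0) entropy <- entropy - v * log2(v)
    contrast <- contrast + (i - j)^2 * v
    homog <- homog + v / (1 + abs(i - j))
    dissim <- dissim + abs(i - j) * v
    mu <- mu + i * v
    sum_avg <- sum_avg + (i + j) * v
  }
  sigma2 <- 0; corr_num <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    sigma2 <- sigma2 + (i - mu)^2 * p[i, j]
    corr_num <- corr_num + (i - mu) * (j - mu) * p[i, j]
  }
  c(energy = energy, entropy = entropy, contrast = contrast,
    homogeneity = homog,
    correlation = if (sigma2 > 0) corr_num / sigma2 else 0,
    variance = sigma2, sum_average = sum_avg, dissimilarity = dissim)
}

# Random quantized ROI built directly (bypasses quantize()) for oracle
# comparisons on arbitrary masked integer grids.
random_quantized_roi <- function(shape, ng, p_fg = 0.7) {
  n <- prod(shape)
  lv <- array(sample.int(ng, n, replace = TRUE) *
                rbinom(n, 1, p_fg), shape)
  mask <- roi_mask((lv > 0) * 1, spacing = c(1, 1, 1))
  structure(list(levels = lv, ng = as.integer(ng), mask = mask,
                 spacing = c(1, 1, 1)),
            class = "quantized_roi")
}

# One-row feature tibble with every numeric column set to `value`, for
# aggregation arithmetic tests.
fake_feature_row <- function(muscle, side, value, volume) {
  row <- tibble::tibble(muscle = muscle, side = side, voxel_count = 10L,
                        volume_mm3 = volume, mean_pdff = value)
  for (f in feature_names()) row[[f]] <- value
  row$degenerate <- FALSE
  row$n_skipped_directions <- 0L
  row
}

# Minimal subject record around fake bilateral features.
fake_record <- function(id, value = 5, sex = "female") {
  feats <- dplyr::bind_rows(
    fake_feature_row("ES", "right", value, 100),
    fake_feature_row("ES", "left", value, 110),
    fake_feature_row("PS", "right", value / 2, 50),
    fake_feature_row("PS", "left", value / 2, 55))
  list(subject_id = id, sex = sex, age = 30, bmi = 25, features = feats,
       mvic_ext = 200, mvic_flex = 150)
}
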