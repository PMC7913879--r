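#' The 13 canonical 3D co-occurrence directions
#'
#' The 26 neighbours of a voxel fall into 13 direction pairs under sign
#' inversion; co-occurrence matrices are symmetric, so one representative
#' per pair suffices. Representatives follow the first-nonzero-positive
#' convention, ordered axes first, then face diagonals, then space
#' diagonals.
#'
#' @return A 13 x 3 integer matrix of voxel displacements `(dx, dy, dz)`.
#' @examples
#' nrow(glcm_directions())  # 13
#' @export
glcm_directions <- function() {
  m <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, c("dx", "dy", "dz"))
  m
}

#' Gray-level co-occurrence matrix for one offset
#'
#' Counts ordered voxel pairs `(v, v + offset)` with both voxels inside the
#' mask, symmetrises by adding the transpose, and normalises to a joint
#' probability matrix. If the offset admits no in-mask pair the matrix is
#' returned as all zeros with `skipped = TRUE` so direction averaging can
#' drop it.
#'
#' @param q A [quantize()] result.
#' @param offset Integer displacement triple, one of [glcm_directions()]
#'   (any integer offset is accepted).
#' @return A `glcm`: list with `p` (ng x ng, symmetric, sums to 1),
#'   `offset`, `pair_count` (ordered pairs before symmetrisation), `ng`,
#'   `skipped`.
#' @export
build_glcm <- function(q, offset) {
  offset <- as.integer(offset)
  if (length(offset) != 3L || anyNA(offset)) {
    stop_pdff("`offset` must be an integer displacement triple.",
              "pdff_domain_error")
  }
  lv <- q$levels
  d <- dim(lv)
  ng <- q$ng
  rng <- lapply(1:3, function(a) {
    seq.int(max(1L, 1L - offset[a]), min(d[a], d[a] - offset[a]))
  })
  p <- matrix(0, ng, ng)
  pair_count <- 0L
  if (all(lengths(rng) > 0)) {
    from <- lv[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    to <- lv[rng[[1]] + offset[1], rng[[2]] + offset[2], rng[[3]] + offset[3],
             drop = FALSE]
    keep <- from > 0L & to > 0L
    pair_count <- sum(keep)
    if (pair_count > 0L) {
      idx <- from[keep] + (to[keep] - 1L) * ng
      counts <- matrix(tabulate(idx, nbins = ng * ng), ng, ng)
      counts <- counts + t(counts)
      p <- counts / sum(counts)
    }
  }
  structure(list(p = p, offset = offset, pair_count = pair_count, ng = ng,
                 skipped = pair_count == 0L),
            class = "glcm")
}

#' Second-order texture features of one GLCM
#'
#' Haralick-style features of a symmetric, normalised co-occurrence matrix
#' `p(i, j)` with marginal mean `mu` and variance `sigma^2` (row marginal;
#' identical to the column marginal by symmetry):
#' energy `sum p^2`; entropy `-sum p log_base p` over positive entries
#' (base 2 by default, i.e. bits); contrast `sum (i - j)^2 p`; homogeneity
#' `sum p / (1 + |i - j|)`; correlation
#' `sum (i - mu)(j - mu) p / sigma^2`, defined as 0 (and flagged) when
#' `sigma^2 = 0`; variance `sum (i - mu)^2 p`; sum average
#' `sum_k k p_{x+y}(k) = sum (i + j) p`; dissimilarity `sum |i - j| p`.
#'
#' @param g A [build_glcm()] result with `pair_count > 0`.
#' @param entropy_log_base Base of the entropy logarithm (default 2).
#' @return One-row tibble with the 8 features and `degenerate` (TRUE when
#'   the marginal variance is 0).
#' @examples
#' q <- quantize(volume_grid(array(c(1, 2, 1), c(1, 1, 3)), c(1, 1, 1)),
#'               roi_mask(array(1, c(1, 1, 3))), ng = 2)
#' g <- build_glcm(q, c(0, 0, 1))
#' glcm_features(g)$correlation  # -1
#' @export
glcm_features <- function(g, entropy_log_base = 2) {
  v <- glcm_features_num(g, entropy_log_base)
  out <- as_tibble(as.list(v[glcm_feature_names()]))
  out$degenerate <- v[["degenerate"]] > 0
  out
}

glcm_feature_names <- function() {
  c("energy", "entropy", "contrast", "homogeneity", "correlation",
    "variance", "sum_average", "dissimilarity")
}

# Numeric-vector core of glcm_features(); kept tibble-free because it runs
# 13 times per muscle inside the cohort generator.
glcm_features_num <- function(g, entropy_log_base = 2) {
  if (g$skipped || g$pair_count == 0L) {
    stop_pdff("GLCM has no voxel pairs; features are undefined.",
              "pdff_contract_violation")
  }
  if (abs(sum(g$p) - 1) > 1e-8) {
    stop_pdff("GLCM must be normalised to sum 1.", "pdff_contract_violation")
  }
  ng <- g$ng
  nz <- which(g$p > 0)
  pv <- g$p[nz]
  i <- ((nz - 1L) %% ng) + 1L
  j <- ((nz - 1L) %/% ng) + 1L
  dij <- i - j
  adij <- abs(dij)
  mu <- sum(i * pv)            # symmetric marginal mean
  sigma2 <- sum((i - mu)^2 * pv)
  degenerate <- sigma2 <= 0
  correlation <- if (degenerate) 0 else
    sum((i - mu) * (j - mu) * pv) / sigma2
  c(energy = sum(pv^2),
    entropy = -sum(pv * log(pv, base = entropy_log_base)),
    contrast = sum(dij^2 * pv),
    homogeneity = sum(pv / (1 + adij)),
    correlation = correlation,
    variance = sigma2,
    sum_average = sum((i + j) * pv),
    dissimilarity = sum(adij * pv),
    degenerate = as.numeric(degenerate))
}

#' Rotation-invariant averaging of per-direction features
#'
#' The unweighted arithmetic mean of each feature over the non-skipped
#' directions; averaging over all 13 directions is what makes the feature
#' set rotation invariant on the voxel lattice.
#'
#' @param per_direction A list of [glcm_features()] rows (one-row tibbles),
#'   or `NULL` entries for skipped directions.
#' @return One-row tibble of averaged features plus `n_skipped`.
#' @export
average_over_directions <- function(per_direction) {
  kept <- per_direction[!vapply(per_direction, is.null, logical(1))]
  if (length(kept) == 0L) {
    stop_pdff("all directions were skipped; ROI too small for GLCM.",
              "pdff_degenerate_roi_error")
  }
  all_rows <- dplyr::bind_rows(kept)
  out <- dplyr::summarise(all_rows, dplyr::across(
    c("energy", "entropy", "contrast", "homogeneity", "correlation",
      "variance", "sum_average", "dissimilarity"), mean))
  out$degenerate <- any(all_rows$degenerate)
  out$n_skipped <- length(per_direction) - length(kept)
  out
}
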