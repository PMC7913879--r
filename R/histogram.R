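#' Histogram bin-count rules
#'
#' Three classical rules for the number of equal-width histogram bins, and
#' the median-of-three selector used for first-order (global) feature
#' extraction. `bins_sturges()` is `ceiling(log2(n)) + 1`. `bins_scott()`
#' uses bin width `3.49 * s * n^(-1/3)` with `s` the sample standard
#' deviation (n - 1 denominator). `bins_freedman_diaconis()` uses width
#' `2 * IQR * n^(-1/3)` with quartiles by linear interpolation
#' (`stats::quantile()` type 7). Degenerate samples: zero range gives one
#' bin; zero IQR (but positive range) falls back to the Sturges count.
#'
#' @param n Sample size, `>= 1`.
#' @param values Numeric sample of at least two values.
#' @return Integer bin count, `>= 1`.
#' @examples
#' bins_sturges(64)                 # 7
#' bins_scott(0:63)                 # 4
#' bins_freedman_diaconis(0:63)     # 4
#' select_bin_count(0:63)           # median(7, 4, 4) = 4
#' @export
bins_sturges <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop_pdff("`n` must be a single sample size >= 1.", "pdff_domain_error")
  }
  as.integer(ceiling(log2(n)) + 1)
}

check_sample2 <- function(values) {
  if (length(values) < 2L || anyNA(values)) {
    stop_pdff("need at least 2 non-missing values.", "pdff_domain_error")
  }
  invisible(TRUE)
}

#' @rdname bins_sturges
#' @export
bins_scott <- function(values) {
  check_sample2(values)
  rng <- diff(range(values))
  s <- sd(values)
  if (rng == 0 || s == 0) return(1L)
  h <- 3.49 * s * length(values)^(-1 / 3)
  max(1L, as.integer(ceiling(rng / h)))
}

#' @rdname bins_sturges
#' @export
bins_freedman_diaconis <- function(values) {
  check_sample2(values)
  rng <- diff(range(values))
  if (rng == 0) return(1L)
  iqr <- diff(unname(quantile(values, c(0.25, 0.75), type = 7)))
  if (iqr == 0) return(bins_sturges(length(values)))
  h <- 2 * iqr * length(values)^(-1 / 3)
  max(1L, as.integer(ceiling(rng / h)))
}

#' @rdname bins_sturges
#' @export
select_bin_count <- function(values) {
  counts <- c(bins_sturges(length(values)), bins_scott(values),
              bins_freedman_diaconis(values))
  sort(counts)[2]
}

#' Equal-width probability histogram
#'
#' Builds `k` equal-width bins spanning the sample range, final bin
#' right-closed, with probabilities `counts / n`. A zero-range sample is
#' histogrammed over a unit-width window centred on its value, so exactly
#' one bin carries probability 1 whatever `k`.
#'
#' @param values Non-empty numeric sample.
#' @param k Number of bins, `>= 1`; defaults to [select_bin_count()].
#' @return A `pdff_histogram`: list with `bin_edges` (k + 1), `bin_centers`
#'   (k), `probabilities` (k, summing to 1) and `n`.
#' @examples
#' h <- build_histogram(c(0, 0, 10, 10), k = 2)
#' h$probabilities  # 0.5 0.5
#' h$bin_centers    # 2.5 7.5
#' @export
build_histogram <- function(values, k = NULL) {
  if (length(values) == 0L || anyNA(values)) {
    stop_pdff("cannot histogram an empty sample.", "pdff_empty_roi_error")
  }
  k <- k %||% if (length(values) >= 2L) select_bin_count(values) else 1L
  if (length(k) != 1L || is.na(k) || k < 1) {
    stop_pdff("`k` must be a single bin count >= 1.", "pdff_domain_error")
  }
  k <- as.integer(k)
  mn <- min(values)
  mx <- max(values)
  if (mx == mn) {
    edges <- seq(mn - 0.5, mn + 0.5, length.out = k + 1)
    mn_e <- mn - 0.5
  } else {
    edges <- seq(mn, mx, length.out = k + 1)
    mn_e <- mn
  }
  w <- edges[2] - edges[1]
  idx <- pmin(floor((values - mn_e) / w) + 1, k)
  counts <- tabulate(idx, nbins = k)
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-(k + 1)]) / 2,
                 probabilities = counts / length(values),
                 n = length(values)),
            class = "pdff_histogram")
}

#' First-order (global) texture features from a histogram
#'
#' Moments of the binned distribution about its probability-weighted mean of
#' bin centres: `variance_global` is the second central moment (percent^2 on
#' PDFF input), `skewness_global` the standardised third moment and
#' `kurtosis_global` the standardised fourth moment in its non-excess form
#' (a normal distribution gives 3). A zero-variance histogram yields
#' skewness and kurtosis 0 with `degenerate = TRUE`.
#'
#' @param h A [build_histogram()] result (probabilities summing to 1).
#' @return A one-row tibble: `variance_global`, `skewness_global`,
#'   `kurtosis_global`, `degenerate`.
#' @examples
#' h <- build_histogram(c(0, 0, 10, 10), k = 2)
#' global_features(h)  # variance 25, skewness 0, kurtosis 1
#' @export
global_features <- function(h) {
  p <- h$probabilities
  if (abs(sum(p) - 1) > 1e-8) {
    stop_pdff("histogram probabilities must sum to 1.",
              "pdff_contract_violation")
  }
  cen <- h$bin_centers
  mu <- sum(p * cen)
  d <- cen - mu
  m2 <- sum(p * d^2)
  if (m2 <= 0) {
    return(tibble(variance_global = 0, skewness_global = 0,
                  kurtosis_global = 0, degenerate = TRUE))
  }
  m3 <- sum(p * d^3)
  m4 <- sum(p * d^4)
  tibble(variance_global = m2,
         skewness_global = m3 / m2^1.5,
         kurtosis_global = m4 / m2^2,
         degenerate = FALSE)
}
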