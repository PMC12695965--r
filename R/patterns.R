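#' Geometric range-bin edges at 5% relative resolution
#'
#' 51 edges for 50 bins with constant 1.05 width ratio (matching the
#' instrument's ~5% relative range accuracy), anchored at the near limit:
#' `edge_k = near_limit * 1.05^k`, `k = 0..50`.
#'
#' @param near_limit anchor, m.
#' @param n_bins number of bins.
#' @param ratio width ratio between consecutive bins.
#' @return numeric vector of `n_bins + 1` edges.
#' @export
geometric_range_edges <- function(near_limit = 40, n_bins = 50,
                                  ratio = 1.05) {
  near_limit * ratio^(0:n_bins)
}

# counts per [edge_k, edge_{k+1}) bin; last bin right-closed
.hist_counts <- function(x, edges) {
  b <- findInterval(x, edges, rightmost.closed = TRUE)
  tabulate(b[b >= 1 & b <= length(edges) - 1], nbins = length(edges) - 1)
}

#' Per-cluster range histograms on geometric bins
#'
#' @param labels integer cluster label per observation.
#' @param observations observation data frame with `range_m`.
#' @param near_limit anchor of the geometric bins, m.
#' @return matrix, clusters x 50 bins, rownames = cluster ids; an
#'   `overflow` attribute counts observations outside the binned window
#'   per cluster, and an `edges` attribute holds the bin edges.
#' @export
range_histograms <- function(labels, observations, near_limit = 40) {
  stopifnot(length(labels) == nrow(observations))
  edges <- geometric_range_edges(near_limit)
  ids <- sort(unique(labels[labels > 0]))
  h <- t(vapply(ids, function(cl) {
    .hist_counts(observations$range_m[labels == cl], edges)
  }, integer(length(edges) - 1)))
  rownames(h) <- ids
  overflow <- vapply(ids, function(cl) {
    r <- observations$range_m[labels == cl]
    sum(r < edges[1] | r > edges[length(edges)])
  }, integer(1))
  if (sum(overflow) > 0) {
    warning(sprintf("%d observation(s) outside the range window excluded",
                    sum(overflow)))
  }
  attr(h, "overflow") <- overflow
  attr(h, "edges") <- edges
  h
}

#' Per-cluster diel activity histograms
#'
#' Counts per 15-min bin of the 24 h cycle (96 bins); timestamps from
#' multi-day runs fold onto one diel cycle.
#'
#' @param labels integer cluster label per observation.
#' @param observations observation data frame with `t0_s` (seconds; folded
#'   modulo 86400).
#' @return matrix, clusters x 96 bins, rownames = cluster ids.
#' @export
time_histograms <- function(labels, observations) {
  stopifnot(length(labels) == nrow(observations))
  ids <- sort(unique(labels[labels > 0]))
  h <- t(vapply(ids, function(cl) {
    s <- observations$t0_s[labels == cl] %% 86400
    tabulate(floor(s / 900) + 1L, nbins = 96L)
  }, integer(96)))
  rownames(h) <- ids
  h
}

#' Count unique spatial or temporal patterns among clusters
#'
#' Applies the identical clustering criterion used for the modulation
#' spectra — log-normalized features, Ward linkage, power-law
#' compensation, median-plus-IQR count — to the per-cluster range or
#' diel-activity distributions, yielding the number of distinguishable
#' patterns. Distributions are normalized to unit sum first so cluster
#' size does not drive the dissimilarity. By construction of the
#' median-referenced count, the result can never exceed half the number
#' of input distributions.
#'
#' @param histograms clusters x bins count matrix ([range_histograms()] or
#'   [time_histograms()]).
#' @param eps numerical floor for the log transform.
#' @return integer number of unique patterns.
#' @export
unique_pattern_count <- function(histograms, eps = 1e-12) {
  stopifnot(is.matrix(histograms))
  tot <- rowSums(histograms)
  if (any(tot == 0)) {
    warning(sprintf("%d empty histogram(s) excluded", sum(tot == 0)))
    histograms <- histograms[tot > 0, , drop = FALSE]
  }
  if (nrow(histograms) < 2) return(0L)
  res <- tryCatch(cluster_spectra(histograms, eps = eps),
                  error = function(e) NULL)
  if (is.null(res)) return(0L)
  res$noc
}
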