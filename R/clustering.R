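#' Log auto-normalized feature vector of a power spectrum
#'
#' `v_f = log(P_f / sum(P) + eps)`. Auto-normalization removes absolute
#' magnitude (which varies strongly with range and beam position) so only
#' spectral shape is compared; the log makes the Euclidean distance act as
#' a fuzzy logical AND across bins — all harmonic content of two
#' observations must match for the pair to be close. The floor `eps`
#' guards zero-power bins from short windows.
#'
#' @param power non-negative spectrum vector, or an N x bins matrix
#'   (rows transformed independently).
#' @param eps numerical floor added before the log.
#' @return feature vector/matrix of the same shape.
#' @export
log_normalize <- function(power, eps = 1e-12) {
  if (is.matrix(power)) {
    tot <- rowSums(power)
    if (any(tot <= 0)) {
      stop(sprintf("%d all-zero spectrum/spectra cannot be normalized",
                   sum(tot <= 0)), call. = FALSE)
    }
    log(power / tot + eps)
  } else {
    tot <- sum(power)
    if (tot <= 0) stop("all-zero spectrum cannot be normalized",
                       call. = FALSE)
    log(power / tot + eps)
  }
}

#' Euclidean distance between two feature vectors
#'
#' The pairwise spectral dissimilarity: the Euclidean norm of the
#' difference of two log-normalized spectra.
#'
#' @param a,b feature vectors on the same axis.
#' @return scalar distance.
#' @export
pairwise_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("feature vectors live on different axes", call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}

#' Memory-saving Ward linkage on feature vectors
#'
#' Agglomerates N feature vectors under Ward's minimum-variance criterion
#' using the nearest-neighbour-chain algorithm computed directly on the
#' vectors: working memory is O(N x bins), and the N x N distance matrix
#' is never materialized (at field scale it would not fit in memory).
#' Merge heights follow the `ward.D2` convention — the merge of two
#' singletons sits at their Euclidean distance — and agree with the
#' full-matrix Lance–Williams recurrence.
#'
#' @param features numeric matrix, N observations x bins.
#' @return an object of class `hclust` (so [stats::cutree()] applies).
#' @export
ward_linkage <- function(features) {
  stopifnot(is.matrix(features))
  n <- nrow(features)
  if (n < 2) stop("need at least 2 observations to cluster", call. = FALSE)
  res <- .ward_nnchain_cpp(features)
  hc <- list(merge = res$merge,
             height = as.numeric(res$height),
             order = .leaf_order(res$merge),
             labels = rownames(features),
             method = "ward.D2",
             call = match.call(),
             dist.method = "euclidean")
  class(hc) <- "hclust"
  hc
}

# dendrogram leaf order by iterative traversal of the merge matrix
.leaf_order <- function(merge) {
  n <- nrow(merge) + 1L
  stack <- nrow(merge)  # root
  ord <- integer(0)
  out <- integer(n)
  k <- 0L
  stack <- c(nrow(merge))
  while (length(stack)) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (node < 0) {
      k <- k + 1L
      out[k] <- -node
    } else {
      # push right then left so left is expanded first
      stack <- c(stack, merge[node, 2], merge[node, 1])
    }
  }
  out
}

#' Sorted branch linkages of a hierarchy
#'
#' @param hc an `hclust` object.
#' @return linkage heights sorted in descending order (branch index
#'   `p = 1` is the most dissimilar split). Ties keep the original merge
#'   order (stable sort).
#' @export
sorted_linkages <- function(hc) {
  sort(hc$height, decreasing = TRUE, method = "radix")
}

#' Power-law compensation of sorted linkages
#'
#' The descending linkage curve of any large ensemble — signal or noise —
#' decays steadily with branch index `p`. The decay is removed by a power
#' law with exponent `beta`, the median absolute log–log slope between
#' consecutive branches, leaving featureless (noise) ensembles on a flat
#' plateau: `Z_comp(p) = (p/(N-1))^beta * Z(p)`. A pure power law
#' `Z(p) = C p^-beta` is flattened exactly. Zero or non-finite linkages
#' are excluded from the slope estimate (their log is undefined).
#'
#' @param z linkage heights sorted in descending order.
#' @return list with `z_comp` (compensated linkages) and `beta`.
#' @export
compensate_linkage <- function(z) {
  n1 <- length(z)
  if (n1 < 2) stop("need at least 2 linkages to compensate", call. = FALSE)
  if (is.unsorted(rev(z))) {
    stop("linkages must be sorted in descending order", call. = FALSE)
  }
  p <- seq_len(n1)
  pos <- is.finite(z) & z > 0
  if (sum(pos) < 2) {
    stop("need at least 2 positive linkages to estimate the slope",
         call. = FALSE)
  }
  lz <- log(z[pos])
  lp <- log(p[pos])
  beta <- .median7(abs(diff(lz) / diff(lp)))
  list(z_comp = (p / n1)^beta * z, beta = beta)
}

#' Parameter-free cluster count from compensated linkages
#'
#' The number of compensated linkages strictly exceeding their own median
#' plus one IQR (linear-interpolation quantiles). Self-referencing: no
#' tunable threshold exists — a flat (noise) linkage curve yields 0.
#'
#' @param z_comp compensated linkages.
#' @return integer cluster count.
#' @export
count_clusters <- function(z_comp) {
  .stopifnot_finite(z_comp, "compensated linkages")
  thr <- .median7(z_comp) + .iqr7(z_comp)
  sum(z_comp > thr)
}

#' Flat cluster labels at a given cluster count
#'
#' Cuts the hierarchy so exactly `noc` flat clusters result (the cut sits
#' above the `noc - 1` highest merges). With `noc = 0` every observation
#' is labelled 0 ("unclassified").
#'
#' @param hc `hclust` object from [ward_linkage()].
#' @param noc number of clusters.
#' @return integer label per observation (0 when `noc = 0`).
#' @export
flat_clusters <- function(hc, noc) {
  n <- length(hc$height) + 1L
  if (noc == 0) return(rep(0L, n))
  stopifnot(noc >= 1, noc <= n)
  unname(cutree(hc, k = noc))
}

#' Per-cluster centroid spectra
#'
#' The centroid of each flat cluster: per-bin median of the member
#' normalized spectra, with the per-bin IQR as a spread band. Clusters
#' are ordered by descending membership.
#'
#' @param labels integer cluster label per observation.
#' @param norm_spectra matrix of normalized spectra (rows match `labels`);
#'   typically `power / rowSums(power)`.
#' @return list of centroids: each has `cluster_id`, `median_spectrum`,
#'   `iqr_band`, `n_members`.
#' @export
cluster_centroids <- function(labels, norm_spectra) {
  stopifnot(length(labels) == nrow(norm_spectra))
  ids <- sort(unique(labels[labels > 0]))
  cents <- lapply(ids, function(cl) {
    m <- norm_spectra[labels == cl, , drop = FALSE]
    list(cluster_id = cl,
         median_spectrum = apply(m, 2, .median7),
         iqr_band = apply(m, 2, .iqr7),
         n_members = nrow(m))
  })
  sizes <- vapply(cents, `[[`, 0, "n_members")
  cents[order(-sizes, ids)]
}

#' Display order of clusters minimizing neighbour dissimilarity
#'
#' Orders cluster centroids for reporting (dendrogram-style): centroids
#' are agglomerated by Ward linkage and, at every internal node, the two
#' subtrees are oriented to minimize the distance between the adjacent
#' boundary centroids (greedy flip, deterministic with ties broken by
#' cluster id). Ordering permutes display only; labels, memberships and
#' cluster counts are untouched.
#'
#' @param centroids list from [cluster_centroids()].
#' @return integer vector of cluster ids in display order.
#' @export
order_leaves <- function(centroids) {
  k <- length(centroids)
  ids <- vapply(centroids, `[[`, 0, "cluster_id")
  if (k <= 2) return(ids[order(ids)][seq_len(k)])
  M <- do.call(rbind, lapply(centroids, `[[`, "median_spectrum"))
  hc <- ward_linkage(M)
  dmat <- as.matrix(dist(M))
  # recursively orient subtrees: choose among 4 orientations of the two
  # child sequences the one with minimal boundary distance
  seq_of <- function(node) {
    if (node < 0) return(-node)
    a <- seq_of(hc$merge[node, 1])
    b <- seq_of(hc$merge[node, 2])
    best <- NULL; bestd <- Inf
    for (ar in list(a, rev(a))) {
      for (br in list(b, rev(b))) {
        d <- dmat[ar[length(ar)], br[1]]
        cand <- c(ar, br)
        if (d < bestd ||
            (d == bestd && !is.null(best) &&
             ids[cand[1]] < ids[best[1]])) {
          best <- cand; bestd <- d
        }
      }
    }
    best
  }
  ids[seq_of(nrow(hc$merge))]
}

#' Full spectral clustering with noise-referenced cluster count
#'
#' The complete diversity-clustering path: log-normalized features, Ward
#' linkage (memory-saving), descending-sorted branch linkages, power-law
#' compensation, the median-plus-IQR cluster count, flat labels and
#' centroid spectra.
#'
#' Each linkage exceeding the threshold is one distinguishable split of
#' the tree, so `noc` splits separate `noc + 1` flat groups; both counts
#' are reported (`noc` is the diversity index, `n_groups` the number of
#' flat clusters actually labelled). With `noc = 0` no split is
#' distinguishable from noise and every observation is unclassified.
#'
#' @param power N x bins power-spectrum matrix.
#' @param eps numerical floor for [log_normalize()].
#' @return object of class `linkage_result`: `n`, `z` (sorted linkages),
#'   `z_comp`, `beta`, `noc`, `n_groups`, `labels`, `centroids`,
#'   `hclust`.
#' @export
cluster_spectra <- function(power, eps = 1e-12) {
  stopifnot(is.matrix(power), nrow(power) >= 2)
  feats <- log_normalize(power, eps = eps)
  hc <- ward_linkage(feats)
  z <- sorted_linkages(hc)
  comp <- compensate_linkage(z)
  noc <- count_clusters(comp$z_comp)
  n_groups <- if (noc >= 1) min(noc + 1L, nrow(power)) else 0L
  labels <- flat_clusters(hc, n_groups)
  norm <- power / rowSums(power)
  centroids <- if (noc >= 1) cluster_centroids(labels, norm) else list()
  structure(list(n = nrow(power), z = z, z_comp = comp$z_comp,
                 beta = comp$beta, noc = noc, n_groups = n_groups,
                 labels = labels, centroids = centroids, hclust = hc),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf(
    "Spectral clustering of %d observations: NoC = %d, %d flat group(s) (beta = %.3f)\n",
    x$n, x$noc, x$n_groups, x$beta))
  invisible(x)
}

#' Noise negative control
#'
#' Runs the identical clustering pipeline on the paired instrument-noise
#' spectra. A healthy control shows no diversity: the compensated noise
#' linkages plateau flat and the cluster count is 0. The plateau slope is
#' the log–log regression slope of the compensated curve over the central
#' branches (2%–80% of `N - 1`), excluding the numerical-precision drop
#' where `p` approaches `N`.
#'
#' @param noise_power noise-spectra matrix (rows = fragments).
#' @param eps numerical floor for [log_normalize()].
#' @return list with `noc_noise`, `beta`, `z_comp`, `plateau_slope`.
#' @export
noise_control <- function(noise_power, eps = 1e-12) {
  res <- cluster_spectra(noise_power, eps = eps)
  n1 <- length(res$z_comp)
  p <- seq_len(n1)
  sel <- p >= max(2, round(0.02 * n1)) & p <= round(0.8 * n1) &
    res$z_comp > 0
  slope <- if (sum(sel) >= 3) {
    unname(coef(lm(log(res$z_comp[sel]) ~ log(p[sel])))[2])
  } else {
    NA_real_
  }
  list(noc_noise = res$noc, beta = res$beta, z_comp = res$z_comp,
       plateau_slope = slope)
}
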