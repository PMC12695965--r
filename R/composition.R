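#' Observation counts per cluster in descending abundance rank
#'
#' @param labels integer cluster label per observation (0 =
#'   unclassified, excluded).
#' @return integer vector of counts sorted descending; ties broken by
#'   cluster id (stable). The `cluster_id` attribute gives the cluster
#'   behind each rank.
#' @export
sort_cluster_counts <- function(labels) {
  labels <- labels[labels > 0]
  if (length(labels) == 0) {
    return(structure(integer(0), cluster_id = integer(0)))
  }
  tab <- table(labels)
  ids <- as.integer(names(tab))
  counts <- as.integer(tab)
  o <- order(-counts, ids)
  structure(counts[o], cluster_id = ids[o])
}

# adjusted R^2 with p fitted parameters
.r2_adj <- function(obs, fit, n_par = 2) {
  n <- length(obs)
  ss_res <- sum((obs - fit)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
  1 - (ss_res / (n - n_par)) / (ss_tot / (n - 1))
}

# bounded least squares via Levenberg-Marquardt on the residual function;
# robust when the optimum sits on a bound (where nls-style model objects
# declare a singular gradient). Returns estimates, fitted values and a
# large-sample covariance from a finite-difference Jacobian.
.lm_fit <- function(predict_fn, y, start, lower, upper, sqrt_w = NULL) {
  if (is.null(sqrt_w)) sqrt_w <- rep(1, length(y))
  resid_fn <- function(par) sqrt_w * (y - predict_fn(par))
  res <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500))
  if (res$info %in% c(0, 9)) {
    stop(sprintf("least-squares fit failed to converge (%s)",
                 res$message), call. = FALSE)
  }
  par <- res$par
  fitted_vals <- predict_fn(par)
  # finite-difference Jacobian at the solution
  np <- length(par)
  J <- matrix(0, length(y), np)
  for (j in seq_len(np)) {
    h <- max(1e-6, abs(par[[j]]) * 1e-6)
    pu <- par; pu[[j]] <- pu[[j]] + h
    pl <- par; pl[[j]] <- pl[[j]] - h
    J[, j] <- (predict_fn(pu) - predict_fn(pl)) / (2 * h)
  }
  dof <- max(1, length(y) - np)
  sigma2 <- sum((sqrt_w * (y - fitted_vals))^2) / dof
  vc <- tryCatch(sigma2 * solve(crossprod(sqrt_w * J)),
                 error = function(e) matrix(NA_real_, np, np))
  list(par = par, fitted = fitted_vals, vcov = vc)
}

#' Fit the rank-abundance composition model
#'
#' Nonlinear least squares of `A(c) = A0 * (1 - c/(NoC+1))^gamma` to the
#' descending cluster counts, in linear count space, with `gamma` bounded
#' below at 0. Reports large-sample Wald confidence intervals, the
#' adjusted R-squared (2 fitted parameters) and the derived median
#' cluster count `A_half = A0 * 2^-gamma` (the model value at the median
#' rank).
#'
#' @param counts descending counts from [sort_cluster_counts()].
#' @param noc number of ranks; defaults to `length(counts)`.
#' @param weights optional fit weights; `"poisson"` uses inverse-variance
#'   weights `1/max(count, 1)`.
#' @param conf_level confidence level for the intervals.
#' @return object of class `composition_fit`: `a0`, `gamma`, `a_half`,
#'   `r2adj`, `ci` (2 x 2 matrix), `noc_used`, `fitted`.
#' @export
fit_composition <- function(counts, noc = length(counts), weights = NULL,
                            conf_level = 0.95) {
  .stopifnot_finite(counts, "counts")
  if (noc < 3) stop("need at least 3 ranks to fit the composition model",
                    call. = FALSE)
  cc <- seq_along(counts)
  a <- as.numeric(counts)
  sqrt_w <- if (identical(weights, "poisson")) 1 / sqrt(pmax(a, 1)) else
    NULL
  start <- list(a0 = max(a), gamma = 0.5)
  fit <- tryCatch(
    .lm_fit(function(p) rank_abundance_model(cc, p[["a0"]],
                                             p[["gamma"]], noc),
            y = a, start = start,
            lower = c(a0 = 0, gamma = 0),
            upper = c(a0 = Inf, gamma = Inf), sqrt_w = sqrt_w),
    error = function(e) {
      stop(sprintf(
        "composition fit failed to converge (%s); start a0=%g gamma=%g on %d ranks, count range [%g, %g]",
        conditionMessage(e), start$a0, start$gamma, noc,
        min(a), max(a)), call. = FALSE)
    })
  est <- unlist(fit$par)
  se <- sqrt(diag(fit$vcov))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- cbind(lower = est - zq * se, upper = est + zq * se)
  structure(list(a0 = est[["a0"]],
                 gamma = est[["gamma"]],
                 a_half = est[["a0"]] * 2^(-est[["gamma"]]),
                 r2adj = .r2_adj(a, fit$fitted),
                 ci = ci,
                 noc_used = noc,
                 fitted = fit$fitted),
            class = "composition_fit")
}

#' @export
print.composition_fit <- function(x, ...) {
  cat(sprintf(
    "Rank-abundance fit over %d ranks: A0 = %.4g, gamma = %.4g (A_half = %.4g, R2adj = %.4f)\n",
    x$noc_used, x$a0, x$gamma, x$a_half, x$r2adj))
  invisible(x)
}

#' Detection-range profile of the count-vs-range density
#'
#' `A(r) = A * (1 - (r/r_det)^alpha)^(1/alpha)` on `[0, r_det]`, zero
#' beyond the detection limit `r_det`; `alpha = 2` is spherical
#' attenuation (quarter-ellipse profile).
#'
#' @param r range(s), m.
#' @param a amplitude.
#' @param r_det detection-range limit, m.
#' @param alpha attenuation exponent.
#' @return predicted density, zero at and beyond `r_det`.
#' @export
range_profile_model <- function(r, a, r_det, alpha) {
  x <- pmax(0, 1 - (pmin(r, r_det) / r_det)^alpha)
  a * x^(1 / alpha)
}

#' Fit the detection-range model
#'
#' `fit_range_histogram()` fits the detection-range profile to binned
#' counts by nonlinear least squares (bin counts modelled as density at
#' the bin mid-point times bin width). `fit_range_profile()` is the
#' observation-level wrapper: it histograms one cluster's ranges on the
#' 50 geometric bins (5% relative width) anchored at the near limit and
#' fits those counts.
#'
#' @param counts counts per bin.
#' @param edges bin edges (`length(counts) + 1`).
#' @param r_det_min lower bound for the detection-range estimate, m.
#' @return object of class `range_fit`: `r_det`, `alpha`, `a`, `r2adj`,
#'   `fit_window`, `edges`, `counts`, `fitted`.
#' @export
fit_range_histogram <- function(counts, edges,
                                r_det_min = max(edges[-length(edges)][
                                  counts > 0])) {
  stopifnot(length(edges) == length(counts) + 1)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  width <- diff(edges)
  start <- list(a = max(counts / width), r_det = r_det_min * 1.05,
                alpha = 2)
  fit <- tryCatch(
    .lm_fit(function(p) range_profile_model(mid, p[["a"]], p[["r_det"]],
                                            p[["alpha"]]) * width,
            y = as.numeric(counts), start = start,
            lower = c(a = 0, r_det = r_det_min, alpha = 0.2),
            upper = c(a = Inf, r_det = Inf, alpha = 20)),
    error = function(e) {
      stop(sprintf("range-profile fit failed to converge (%s)",
                   conditionMessage(e)), call. = FALSE)
    })
  est <- unlist(fit$par)
  structure(list(r_det = est[["r_det"]],
                 alpha = est[["alpha"]],
                 a = est[["a"]],
                 r2adj = .r2_adj(as.numeric(counts), fit$fitted,
                                 n_par = 3),
                 fit_window = c(edges[1], edges[length(edges)]),
                 edges = edges, counts = counts, fitted = fit$fitted),
            class = "range_fit")
}

#' @rdname fit_range_histogram
#' @param ranges observation ranges of one cluster, m.
#' @param near_limit near-field limit anchoring the bins, m.
#' @param min_n minimum number of observations required.
#' @export
fit_range_profile <- function(ranges, near_limit = 40, min_n = 30) {
  ranges <- ranges[is.finite(ranges)]
  if (length(ranges) < min_n) {
    stop(sprintf("need at least %d observations (got %d)", min_n,
                 length(ranges)), call. = FALSE)
  }
  if (diff(range(ranges)) < near_limit * 0.05) {
    stop("degenerate range spread; cannot fit a range profile",
         call. = FALSE)
  }
  edges <- geometric_range_edges(near_limit)
  h <- .hist_counts(ranges, edges)
  fit_range_histogram(h, edges, r_det_min = max(ranges))
}

#' @export
print.range_fit <- function(x, ...) {
  cat(sprintf(
    "Detection-range fit: r_det = %.1f m, alpha = %.3g (R2adj = %.4f)\n",
    x$r_det, x$alpha, x$r2adj))
  invisible(x)
}

#' Center-of-mass frequency of a centroid spectrum
#'
#' The first statistical moment of the spectrum over the frequency axis:
#' `f_CoM = sum(f * P(f)) / sum(P(f))`. Reduces a centroid to one scalar
#' summary of its frequency content; always within the axis bounds.
#'
#' @param power spectrum values on `axis`.
#' @param axis frequency axis, Hz.
#' @return frequency in Hz.
#' @export
center_of_mass_frequency <- function(power, axis = modulation_axis()) {
  stopifnot(length(power) == length(axis))
  tot <- sum(power)
  if (tot <= 0) stop("zero total power has no center of mass",
                     call. = FALSE)
  sum(axis * power) / tot
}

#' Per-cluster summary table
#'
#' One row per cluster: membership, mean range, mean transit time,
#' center-of-mass frequency of the centroid, and descending-abundance
#' rank.
#'
#' @param labels integer cluster label per observation.
#' @param observations observation data frame (`obs_id`, `range_m`,
#'   `transit_ms`), rows matching `labels`.
#' @param centroids list from [cluster_centroids()].
#' @param axis frequency axis for `f_com`.
#' @return data frame with `cluster_id`, `rank`, `n_obs`, `mean_range`,
#'   `mean_transit`, `f_com`.
#' @export
cluster_summaries <- function(labels, observations, centroids,
                              axis = modulation_axis()) {
  stopifnot(length(labels) == nrow(observations))
  counts <- sort_cluster_counts(labels)
  ids <- attr(counts, "cluster_id")
  cent_by_id <- setNames(centroids,
                         vapply(centroids, `[[`, 0, "cluster_id"))
  rows <- lapply(seq_along(ids), function(k) {
    cl <- ids[k]
    sel <- labels == cl
    cent <- cent_by_id[[as.character(cl)]]
    data.frame(cluster_id = cl,
               rank = k,
               n_obs = sum(sel),
               mean_range = mean(observations$range_m[sel]),
               mean_transit = mean(observations$transit_ms[sel]),
               f_com = center_of_mass_frequency(cent$median_spectrum,
                                                axis))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlations between cluster rank summaries
#'
#' Correlation coefficients with two-sided p-values for the bias checks:
#' cluster size vs mean detection range, cluster size vs mean transit
#' time, and centroid frequency content vs mean range.
#'
#' @param summaries data frame from [cluster_summaries()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data frame with `pair`, `estimate`, `p_value`, `n`.
#' @export
rank_correlations <- function(summaries,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(summaries) < 5) {
    stop("need at least 5 clusters for rank correlations", call. = FALSE)
  }
  pairs <- list(c("n_obs", "mean_range"),
                c("n_obs", "mean_transit"),
                c("f_com", "mean_range"))
  rows <- lapply(pairs, function(p) {
    x <- summaries[[p[1]]]; y <- summaries[[p[2]]]
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      return(data.frame(pair = paste(p, collapse = " vs "),
                        estimate = NA_real_, p_value = NA_real_,
                        n = nrow(summaries)))
    }
    ct <- suppressWarnings(cor.test(x, y, method = method))
    data.frame(pair = paste(p, collapse = " vs "),
               estimate = unname(ct$estimate),
               p_value = ct$p.value,
               n = nrow(summaries))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
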