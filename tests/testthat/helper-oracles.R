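# Independent oracles and shared fixtures, coded separately from the
# package internals they check.

# Direct Welch estimator: explicit DFT by matrix multiplication (no
# stats::fft), same definition (Gaussian window, 50% overlap, per-segment
# mean removal, zero-padding, linear interpolation onto the axis).
direct_welch_oracle <- function(x, fs = 1750, axis = entolidar::modulation_axis(),
                                L = 40, fwhm = 20, nfft = 256) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  k <- 0:(L - 1)
  w <- exp(-((k - (L - 1) / 2)^2) / (2 * sigma^2))
  starts <- seq(1, length(x) - L + 1, by = L %/% 2)
  nh <- nfft %/% 2 + 1
  # DFT matrix rows: frequencies 0..nfft/2
  n_idx <- 0:(nfft - 1)
  acc <- numeric(nh)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    seg <- (seg - sum(seg) / L) * w
    padded <- c(seg, rep(0, nfft - L))
    for (f in seq_len(nh)) {
      ang <- -2 * pi * (f - 1) * n_idx / nfft
      re <- sum(padded * cos(ang))
      im <- sum(padded * sin(ang))
      acc[f] <- acc[f] + re^2 + im^2
    }
  }
  acc <- acc / (length(starts) * fs * sum(w^2))
  fgrid <- (0:(nfft / 2)) * fs / nfft
  pmax(approx(fgrid, acc, xout = axis)$y, 0)
}

# Brute-force Ward agglomeration via the Lance-Williams recurrence on the
# full squared-distance matrix (quadratic memory, cubic time). Returns the
# multiset of merge heights in the ward.D2 convention.
lw_ward_heights_oracle <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  size <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (m in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    for (i in which(active)) {
      for (j in which(active)) {
        if (j <= i) next
        if (d2[i, j] < best) { best <- d2[i, j]; bi <- i; bj <- j }
      }
    }
    heights[m] <- sqrt(best)
    ni <- size[bi]; nj <- size[bj]
    for (k in which(active)) {
      if (k == bi || k == bj) next
      nk <- size[k]
      d2new <- ((ni + nk) * d2[bi, k] + (nj + nk) * d2[bj, k] -
                  nk * d2[bi, bj]) / (ni + nj + nk)
      d2[bi, k] <- d2[k, bi] <- d2new
    }
    size[bi] <- ni + nj
    active[bj] <- FALSE
    d2[bj, ] <- d2[, bj] <- Inf
  }
  sort(heights)
}

# Synthetic instrument-noise fragment spectra: i.i.d. Gaussian waveforms
# with realistic (log-normal) mask durations, passed through the package's
# own Welch front end.
make_noise_spectra <- function(n, seed, sd = 5, len_meanlog = log(43),
                               len_sdlog = 0.3) {
  set.seed(seed)
  t(vapply(seq_len(n), function(i) {
    len <- max(40, round(rlnorm(1, len_meanlog, len_sdlog)))
    entolidar::welch_spectrum(rnorm(len, 0, sd))
  }, numeric(40)))
}

# Spectra ensemble for K well-separated species via the generator defaults.
make_species_run <- function(k, seed, n_total = 5000, gamma = 0.5) {
  a0 <- round(n_total / sum((1 - seq_len(k) / (k + 1))^gamma))
  cfg <- entolidar::run_config(label = sprintf("K%d", k), seed = seed,
                               n_species = k, a0_true = a0,
                               gamma_true = gamma)
  entolidar::run_all(cfg)
}

centroid_argmax_bins <- function(centroids,
                                 axis = entolidar::modulation_axis()) {
  sort(vapply(centroids, function(cc) axis[which.max(cc$median_spectrum)],
              numeric(1)))
}

template_wbf_bins <- function(templates,
                              axis = entolidar::modulation_axis()) {
  sort(vapply(templates, function(t) axis[which.min(abs(axis - t$wbf))],
              numeric(1)))
}
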