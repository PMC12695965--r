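#' Fixed modulation-frequency axis
#'
#' The common axis all modulation power spectra are sampled on: 40 bins at
#' 20 Hz spacing starting at the minimum resolvable frequency of a 25 ms
#' transit (40 Hz), i.e. 40, 60, ..., 820 Hz. The bin count and spacing
#' are the binding constraints; the native Welch resolution with 40-sample
#' windows at 1750 Hz is 43.75 Hz, and the 20 Hz sampling grid comes from
#' interpolating the zero-padded periodogram (denser sampling, not added
#' resolution).
#'
#' @param n_bins number of bins.
#' @param f0 first bin centre, Hz.
#' @param spacing bin spacing, Hz.
#' @return numeric vector of bin-centre frequencies.
#' @export
modulation_axis <- function(n_bins = 40, f0 = 40, spacing = 20) {
  f0 + spacing * (seq_len(n_bins) - 1)
}

#' Filter observations by transit time
#'
#' Retains records whose transit duration is at least `min_ms` (boundary
#' inclusive), preserving order. Short transits carry too few wingbeat
#' periods for a meaningful modulation spectrum.
#'
#' @param observations data frame with a `transit_ms` column.
#' @param min_ms minimum transit duration, ms.
#' @return the surviving subset, same columns and order.
#' @export
transit_filter <- function(observations, min_ms = 25) {
  stopifnot(is.data.frame(observations),
            "transit_ms" %in% names(observations))
  observations[observations$transit_ms >= min_ms, , drop = FALSE]
}

# Gaussian window of given length and FWHM (in samples)
.gauss_window <- function(len = 40, fwhm = 20) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  k <- seq_len(len) - 1
  exp(-0.5 * ((k - (len - 1) / 2) / sigma)^2)
}

#' Welch modulation power spectrum of one transit waveform
#'
#' Welch average over 50%-overlapping segments of 40 samples, each
#' mean-removed and weighted by a Gaussian window of FWHM 20 samples,
#' zero-padded to `nfft` points (FFT bin spacing well below 20 Hz), then
#' sampled onto the fixed 40-bin modulation axis by linear interpolation
#' of the averaged periodogram.
#'
#' @param waveform intensity vector; must be at least one window long.
#' @param fs effective sample rate, Hz.
#' @param axis frequency axis from [modulation_axis()].
#' @param window_len,window_fwhm Gaussian window length and FWHM, samples.
#' @param nfft zero-padded FFT length.
#' @return numeric vector of non-negative power values on `axis`.
#' @export
welch_spectrum <- function(waveform, fs = 1750, axis = modulation_axis(),
                           window_len = 40, window_fwhm = 20, nfft = 256) {
  n <- length(waveform)
  if (n < window_len) {
    stop(sprintf(
      "waveform has %d samples but one Welch window needs %d; apply the transit filter first",
      n, window_len), call. = FALSE)
  }
  w <- .gauss_window(window_len, window_fwhm)
  hop <- window_len %/% 2
  starts <- seq(1, n - window_len + 1, by = hop)
  nhalf <- nfft %/% 2 + 1L
  acc <- numeric(nhalf)
  for (s in starts) {
    seg <- waveform[s:(s + window_len - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- fft(c(seg, numeric(nfft - window_len)))
    acc <- acc + Mod(sp[seq_len(nhalf)])^2
  }
  acc <- acc / (length(starts) * fs * sum(w^2))
  fgrid <- (seq_len(nhalf) - 1) * fs / nfft
  p <- approx(fgrid, acc, xout = axis)$y
  pmax(p, 0)
}

#' Build the spectra ensemble for clustering
#'
#' Computes the modulation power spectrum of every observation waveform
#' and of every available paired noise fragment on one identical frequency
#' axis. The ensemble matrix (observations x 40 bins) is the clustering
#' input; the noise matrix feeds the negative control.
#'
#' @param observations transit-filtered observation data frame.
#' @param waveforms list of intensity vectors keyed by `obs_id`.
#' @param noise_waveforms list of paired noise vectors keyed by `obs_id`
#'   (may cover only part of the observations).
#' @param fs effective sample rate, Hz.
#' @param axis shared frequency axis.
#' @return list of class `spectra_ensemble`: `power` (N x 40 matrix,
#'   rownames = obs ids), `noise_power` (matrix over observations with
#'   fragments), `freq_axis`, `fs`.
#' @export
build_ensemble <- function(observations, waveforms,
                           noise_waveforms = list(), fs = 1750,
                           axis = modulation_axis()) {
  stopifnot(is.data.frame(observations))
  ids <- observations$obs_id
  if (length(ids) == 0) {
    warning("no surviving observations; empty ensemble")
    return(structure(list(power = matrix(numeric(0), 0, length(axis)),
                          noise_power = matrix(numeric(0), 0, length(axis)),
                          freq_axis = axis, fs = fs),
                     class = "spectra_ensemble"))
  }
  if (!all(ids %in% names(waveforms))) {
    stop("every observation needs a waveform", call. = FALSE)
  }
  power <- t(vapply(ids, function(id)
    welch_spectrum(waveforms[[id]], fs = fs, axis = axis),
    numeric(length(axis))))
  rownames(power) <- ids
  nids <- intersect(ids, names(noise_waveforms))
  noise_power <- if (length(nids)) {
    np <- t(vapply(nids, function(id)
      welch_spectrum(noise_waveforms[[id]], fs = fs, axis = axis),
      numeric(length(axis))))
    rownames(np) <- nids
    np
  } else {
    matrix(numeric(0), 0, length(axis))
  }
  structure(list(power = power, noise_power = noise_power,
                 freq_axis = axis, fs = fs),
            class = "spectra_ensemble")
}
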