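#' Boolean time-range threshold map
#'
#' Marks every pixel whose backscatter strictly exceeds its own range bin's
#' median plus two interquartile ranges, with both statistics computed per
#' range bin over all exposures of the block. A constant range bin has zero
#' IQR and, by strictness, produces no marked pixels.
#'
#' @param block numeric or integer matrix, range bins x exposures.
#' @return logical matrix of the same shape.
#' @export
threshold_map <- function(block) {
  stopifnot(is.matrix(block))
  if (ncol(block) < 100) {
    stop("block must have at least 100 exposures for per-bin statistics",
         call. = FALSE)
  }
  med <- apply(block, 1, .median7)
  q <- apply(block, 1, .quantile7, probs = c(0.25, 0.75))
  thr <- med + 2 * (q[2, ] - q[1, ])
  block > thr   # recycles thr down columns (per-row threshold)
}

#' Extract insect observations as connected islands
#'
#' Labels 8-connected components of the Boolean map (diagonal adjacency
#' joins, since transits drift across range bins between exposures) and
#' crops one observation record per island: the waveform is the intensity
#' summed over the island's range bins for each exposure in the island's
#' span, the range is the intensity-weighted mean over island pixels, the
#' timestamp is the first exposure's time. Islands touching the block edge
#' are flagged (their truncated envelopes distort spectra) and can be
#' excluded downstream.
#'
#' @param boolmap logical matrix from [threshold_map()].
#' @param block the intensity matrix the map was computed from.
#' @param range_axis range in metres per range bin.
#' @param t_axis time in seconds per exposure.
#' @param fs effective sample rate, Hz.
#' @param id_prefix prefix for generated observation ids.
#' @param min_pixels smallest island kept. Isolated suprathreshold noise
#'   pixels (a ~0.3% per-pixel event under the 2-IQR rule) form tiny
#'   islands no insect transit could produce; anything spanning fewer
#'   pixels than this is discarded as a noise flicker.
#' @return data frame with one row per island: `obs_id`, `range_m`,
#'   `t0_s`, `transit_ms`, `n_bins`, `n_exposures`, `edge`, plus a
#'   `waveforms` attribute (list of intensity vectors named by `obs_id`)
#'   and a `masks` attribute (per island: rows, exposure span) used for
#'   noise-fragment pairing.
#' @export
extract_islands <- function(boolmap, block, range_axis = NULL,
                            t_axis = NULL, fs = NULL, id_prefix = "obs",
                            min_pixels = 8) {
  stopifnot(is.matrix(boolmap), identical(dim(boolmap), dim(block)))
  nr <- nrow(block); ne <- ncol(block)
  if (is.null(range_axis)) range_axis <- seq_len(nr)
  if (is.null(fs)) fs <- ne  # default: one block per second
  if (is.null(t_axis)) t_axis <- (seq_len(ne) - 1) / fs
  lab <- .label8_cpp(boolmap)
  if (max(lab) > 0 && min_pixels > 1) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_pixels)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      keep <- sort(unique(lab[lab > 0]))
      lab[] <- match(lab, keep, nomatch = 0L)  # compact relabel, 0 stays 0
    }
  }
  k <- max(lab)
  empty <- data.frame(obs_id = character(0), range_m = numeric(0),
                      t0_s = numeric(0), transit_ms = numeric(0),
                      n_bins = integer(0), n_exposures = integer(0),
                      edge = logical(0))
  if (k == 0) {
    attr(empty, "waveforms") <- list()
    attr(empty, "masks") <- list()
    return(empty)
  }
  recs <- vector("list", k)
  waves <- vector("list", k)
  masks <- vector("list", k)
  px <- which(lab > 0)
  comp <- lab[px]
  rows <- (px - 1L) %% nr + 1L
  cols <- (px - 1L) %/% nr + 1L
  for (i in seq_len(k)) {
    sel <- comp == i
    ri <- rows[sel]; ci <- cols[sel]
    r0 <- min(ri); r1 <- max(ri)
    c0 <- min(ci); c1 <- max(ci)
    inten <- block[cbind(ri, ci)]
    wsum <- sum(inten)
    range_m <- if (wsum > 0) sum(inten * range_axis[ri]) / wsum
               else mean(range_axis[ri])
    span <- c0:c1
    ur <- sort(unique(ri))
    wav <- if (length(ur) == 1) as.numeric(block[ur, span])
           else colSums(block[ur, span, drop = FALSE])
    recs[[i]] <- data.frame(
      obs_id = sprintf("%s%05d", id_prefix, i),
      range_m = range_m,
      t0_s = t_axis[c0],
      transit_ms = length(span) / fs * 1000,
      n_bins = length(ur),
      n_exposures = length(span),
      edge = (r0 == 1L || r1 == nr || c0 == 1L || c1 == ne))
    waves[[i]] <- wav
    masks[[i]] <- list(rows = ur, exp_start = c0, exp_end = c1)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  names(waves) <- out$obs_id
  names(masks) <- out$obs_id
  attr(out, "waveforms") <- waves
  attr(out, "masks") <- masks
  out
}

#' Sample a paired noise fragment for one observation
#'
#' Cuts an empty stretch of instrument noise with the observation's own
#' mask (same range bins, same width) at a uniformly drawn exposure offset
#' whose window is disjoint from every detected island, so the fragment
#' shares acquisition conditions (mask size, range, background) with its
#' observation.
#'
#' @param block intensity matrix.
#' @param mask island mask (`rows`, `exp_start`, `exp_end`) as produced by
#'   [extract_islands()].
#' @param all_masks list of all island masks in the block; candidate
#'   windows must not overlap any of their exposure spans.
#' @return list with `waveform` and `exp_start`, or `NULL` (with a warning)
#'   when no disjoint window exists.
#' @export
sample_noise_fragment <- function(block, mask, all_masks = list(mask)) {
  ne <- ncol(block)
  w <- mask$exp_end - mask$exp_start + 1L
  occupied <- rep(FALSE, ne)
  for (m in all_masks) occupied[m$exp_start:m$exp_end] <- TRUE
  # candidate start s: window [s, s+w-1] fully clear
  free <- !occupied
  cs <- cumsum(free)
  starts <- seq_len(ne - w + 1L)
  clear <- cs[starts + w - 1L] - c(0, cs)[starts] == w
  if (!any(clear)) {
    warning("no disjoint noise window available; fragment omitted")
    return(NULL)
  }
  s <- sample(starts[clear], 1)
  span <- s:(s + w - 1L)
  ur <- mask$rows
  wav <- if (length(ur) == 1) as.numeric(block[ur, span])
         else colSums(block[ur, span, drop = FALSE])
  list(waveform = wav, exp_start = s)
}

#' Extract observations and paired noise from a list of blocks
#'
#' Convenience driver: threshold, island extraction and noise-fragment
#' pairing over a list of raw blocks, concatenating records across blocks.
#'
#' @param blocks list of intensity matrices.
#' @param range_axis,fs axes shared by all blocks.
#' @param noise_fragments logical; also crop paired noise fragments.
#' @param drop_edge logical; drop islands touching a block edge.
#' @return list with `observations` (data frame), `waveforms` and
#'   `noise_waveforms` (lists keyed by `obs_id`).
#' @export
extract_blocks <- function(blocks, range_axis = NULL, fs = NULL,
                           noise_fragments = TRUE, drop_edge = TRUE) {
  all_obs <- list(); all_w <- list(); all_nw <- list()
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    bm <- threshold_map(blk)
    rec <- extract_islands(bm, blk, range_axis = range_axis, fs = fs,
                           id_prefix = sprintf("b%03d_obs", b))
    waves <- attr(rec, "waveforms")
    masks <- attr(rec, "masks")
    if (nrow(rec) == 0) next
    if (drop_edge && any(rec$edge)) {
      keep <- !rec$edge
      waves <- waves[keep]
      masks <- masks[keep]
      rec <- rec[keep, , drop = FALSE]
    }
    if (nrow(rec) == 0) next
    if (noise_fragments) {
      for (id in rec$obs_id) {
        fr <- sample_noise_fragment(blk, masks[[id]], masks)
        if (!is.null(fr)) all_nw[[id]] <- fr$waveform
      }
    }
    all_obs[[length(all_obs) + 1L]] <- rec
    all_w <- c(all_w, waves)
  }
  obs <- if (length(all_obs)) do.call(rbind, all_obs) else
    data.frame(obs_id = character(0), range_m = numeric(0),
               t0_s = numeric(0), transit_ms = numeric(0),
               n_bins = integer(0), n_exposures = integer(0),
               edge = logical(0))
  rownames(obs) <- NULL
  list(observations = obs, waveforms = all_w, noise_waveforms = all_nw)
}
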