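test_that("composition counts follow the rank-abundance law", {
  cfg0 <- scene_config(n_species = 10, gamma_true = 0, a0_true = 100)
  expect_identical(draw_composition(cfg0), rep(100L, 10))

  # single rank: A0 * (1/2)^gamma at c = 1, NoC = 1
  cfg1 <- scene_config(n_species = 1, gamma_true = 1.7, a0_true = 640)
  expect_equal(draw_composition(cfg1), as.integer(round(640 * 0.5^1.7)))

  # brute-force evaluation of the formula at c = 1..20
  direct <- round(1000 * (1 - (1:20) / 21)^1.5)
  cfg <- scene_config(n_species = 20, gamma_true = 1.5, a0_true = 1000)
  counts <- draw_composition(cfg)
  expect_equal(as.numeric(counts), as.numeric(direct))
  expect_true(all(diff(counts) <= 0))

  expect_error(scene_config(gamma_true = NaN), "finite")
})

test_that("range draws respect the detection-range density", {
  tpl <- species_template("a", wbf = 200, r_det = 300, alpha_range = 2)
  expect_identical(draw_ranges(tpl, 0), numeric(0))

  set.seed(11)
  r <- draw_ranges(tpl, 5e4, near_limit = 40)
  expect_true(all(r >= 40 & r <= 300))

  # chi-square GOF against bin probabilities from numerical integration
  edges <- seq(40, 300, length.out = 21)
  dens <- function(x) sqrt(pmax(0, 1 - (x / 300)^2))
  probs <- vapply(seq_len(20), function(i)
    integrate(dens, edges[i], edges[i + 1])$value, numeric(1))
  probs <- probs / sum(probs)
  h <- hist(r, breaks = edges, plot = FALSE)$counts
  gof <- chisq.test(h, p = probs)
  expect_gt(gof$p.value, 0.01)

  bad <- species_template("b", wbf = 100, alpha_range = 1)
  bad$alpha_range <- -1
  expect_error(draw_ranges(bad, 5), "alpha")
  expect_error(draw_ranges(species_template("c", wbf = 100, r_det = 40),
                           5, near_limit = 40), "near limit")
})

test_that("diel timestamp draws follow the activity profile", {
  uni <- species_template("u", wbf = 100)
  expect_identical(draw_times(uni, 0), numeric(0))
  set.seed(4)
  t1 <- draw_times(uni, 5e4)
  expect_true(all(t1 >= 0 & t1 < 86400))
  h <- tabulate(floor(t1 / 900) + 1, 96)
  # flat within sampling error: every 15-min bin close to n/96
  expect_true(max(abs(h - 5e4 / 96)) < 5 * sqrt(5e4 / 96))

  crep <- species_template("c", wbf = 100,
                           activity_profile = data.frame(hour = 18.5,
                                                         sd_h = 1 / 3,
                                                         weight = 1))
  t2 <- draw_times(crep, 5e4)
  within_1h <- mean(abs(t2 - 18.5 * 3600) <= 3600)
  expect_gte(within_1h, 0.95)   # 3 sigma of a 20-min-wide peak
})

test_that("synthetic waveforms have the documented length and spectrum", {
  tpl <- species_template("a", wbf = 200)
  expect_length(synth_waveform(tpl, 25, fs = 1750), 43L)
  expect_error(synth_waveform(tpl, 25, fs = -1), "fs")

  # pure envelope: no spectral peak above the envelope band
  set.seed(5)
  body <- species_template("b", wbf = 200, body_fraction = 1)
  spb <- welch_spectrum(synth_waveform(body, 40, noise_sd = 0))
  ax <- modulation_axis()
  expect_lt(max(spb[ax >= 120]), max(spb) * 0.1 + 1e-30)

  # noiseless tone peaks in the WBF bin
  osc <- species_template("o", wbf = 200, body_fraction = 0)
  spo <- welch_spectrum(synth_waveform(osc, 25, noise_sd = 0))
  expect_equal(ax[which.max(spo)], 200)
})

test_that("observation sets are reproducible and conserve the composition", {
  tpls <- default_templates(5)
  cfg <- scene_config(n_species = 5, gamma_true = 0, a0_true = 80,
                      seed = 9)
  s1 <- generate_observations(cfg, tpls)
  s2 <- generate_observations(cfg, tpls)
  expect_identical(s1$observations, s2$observations)
  expect_identical(s1$waveforms, s2$waveforms)

  counts <- table(s1$observations$species_true)
  expect_true(max(counts) - min(counts) <= 1)   # gamma = 0: even
  expect_identical(sum(draw_composition(cfg)),
                   as.integer(nrow(s1$observations)))

  # range support per template
  for (tpl in tpls) {
    r <- s1$observations$range_m[s1$observations$species_true ==
                                   tpl$species_id]
    expect_true(all(r >= cfg$near_limit & r <= tpl$r_det))
  }
})

test_that("generated composition is recovered by the composition fit", {
  tpls <- default_templates(8)
  cfg <- scene_config(n_species = 8, gamma_true = 1.2, a0_true = 1500,
                      seed = 21)
  sim <- generate_observations(cfg, tpls)
  lab <- as.integer(factor(sim$observations$species_true))
  counts <- sort_cluster_counts(lab)
  fit <- fit_composition(counts)
  expect_lt(abs(fit$gamma - 1.2), 0.1)
  expect_gt(fit$r2adj, 0.99)
})

test_that("frame blocks embed events at ledgered positions", {
  cfg <- scene_config(n_species = 1, a0_true = 10, seed = 13,
                      n_range_bins = 128, n_exposures = 3000,
                      noise_sd = 5, r_max = 300)
  tpl <- list(species_template("sp01", wbf = 200, brightness = 3000,
                               r_det = 250))
  geom <- frame_geometry(scene_config())
  expect_identical(geom$bytes, 2048 * 35000 * 2)

  ev <- data.frame(species = "sp01", block = 1L,
                   range_bin = c(20L, 60L, 100L),
                   exp_start = c(100L, 1000L, 2400L),
                   n_samples = c(60L, 50L, 70L))
  fr <- generate_frames(cfg, tpl, n_blocks = 1, events = ev)
  expect_identical(nrow(fr$ledger), 3L)
  blk <- fr$blocks[[1]]
  expect_true(is.integer(blk))
  expect_true(all(blk >= 0 & blk <= 65535))

  res <- extract_blocks(fr$blocks, range_axis = fr$range_axis, fs = fr$fs,
                        noise_fragments = FALSE)
  expect_identical(nrow(res$observations), 3L)

  # event exceeding the block boundary is rejected by default
  bad <- rbind(ev, data.frame(species = "sp01", block = 1L,
                              range_bin = 90L, exp_start = 2980L,
                              n_samples = 100L))
  expect_warning(fr2 <- generate_frames(cfg, tpl, n_blocks = 1,
                                        events = bad),
                 "boundary")
  expect_identical(nrow(fr2$ledger), 3L)
})
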