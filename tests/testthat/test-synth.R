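test_that("generation is a deterministic function of the config", {
  cfg <- tiny_config(seed = 11, sessions_per_day = 2L)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_length(a$recordings, (4 + 1) * 2)  # 4 postures + rest, 2 sessions
  for (i in seq_along(a$recordings)) {
    expect_identical(a$recordings[[i]]$samples, b$recordings[[i]]$samples)
  }
  expect_identical(a$ground_truth, b$ground_truth)
  # a different seed produces different samples
  c <- generate_dataset(tiny_config(seed = 12, sessions_per_day = 2L))
  expect_false(identical(a$recordings[[1]]$samples, c$recordings[[1]]$samples))
})

test_that("degenerate dispersion and silent channels behave as stated", {
  cfg <- tiny_config(seed = 3, sigma_trial = 0, crosstalk_lambda = 0,
                     sessions_per_day = 3L)
  sim <- generate_dataset(cfg)
  gt <- sim$ground_truth
  for (p in cfg$postures) {
    amps <- gt$amplitude[gt$posture == p, , drop = FALSE]
    expect_true(all(abs(sweep(amps, 2, amps[1, ])) == 0))
  }
  # zero activation with zero rest baseline produces numerically silent output
  amp0 <- matrix(0, 1, 2)
  cfg0 <- synth_config(n_channels = 2, postures = "rest",
                       amplitude_matrix = amp0, sigma_trial = 0,
                       rest_amplitude = 0, fs = 500, trial_s = 1,
                       sessions_per_day = 1L, seed = 4)
  sim0 <- generate_dataset(cfg0)
  expect_lt(max(vapply(sim0$recordings, function(r) max(abs(r$samples)),
                       numeric(1))), 1e-12)
})

test_that("realised trial RMS hits the amplitude target", {
  # long single-posture trial: measured RMS within 2% of the unit target
  cfg <- synth_config(n_channels = 1, postures = "spread",
                      amplitude_matrix = matrix(1, 1, 1),
                      spectral_centroid_matrix = matrix(120, 1, 1),
                      sigma_trial = 0, crosstalk_lambda = 0,
                      rest_amplitude = 0.01, fs = 1000, trial_s = 60,
                      sessions_per_day = 1L, seed = 6)
  sim <- generate_dataset(cfg)
  r <- Filter(function(x) x$posture == "spread", sim$recordings)[[1]]
  expect_lt(abs(rms(r$samples[1, ]) - 1), 0.02)
})

test_that("measured amplitudes are unbiased and recover the dispersion knob", {
  # 25 sessions x 4 postures x 2 channels = 200 posture trials
  cfg <- tiny_config(seed = 13, n_channels = 2L, sigma_trial = 0.3,
                     sessions_per_day = 25L, crosstalk_lambda = 0,
                     fs = 500, trial_s = 1)
  sim <- generate_dataset(cfg)
  gt <- sim$ground_truth
  post <- gt$posture != "rest-calibration"
  measured <- t(vapply(sim$recordings[post],
                       function(r) apply(r$samples, 1, rms), numeric(2)))
  expect_lt(max(abs(measured / gt$amplitude[post, ] - 1)), 1e-9)
  # per-posture log-amplitude spread recovers sigma within 15% at n = 100
  lr <- log(measured / rep(cfg$amplitude_matrix[gt$posture[post], 1:2], 1))
  expect_lt(abs(sd(as.numeric(lr)) / 0.3 - 1), 0.15)
})

test_that("crosstalk mixing matches its defining matrix", {
  x <- rbind(rnorm(100), 0)
  out <- apply_crosstalk(x, 0.2)
  expect_equal(out[1, ], 0.8 * x[1, ])
  expect_equal(out[2, ], 0.2 * x[1, ])
  expect_identical(apply_crosstalk(x, 0), x)
  cst <- matrix(rep(rnorm(50), each = 3), 3)
  expect_equal(apply_crosstalk(cst, 0.3), cst)  # rows sum to 1
  expect_error(apply_crosstalk(x, 0.5), "\\[0, 0.5\\)")
  expect_error(apply_crosstalk(x, -0.1), "\\[0, 0.5\\)")
})

test_that("amputee mode removes channels and preserves the identity case", {
  cfg <- healthy_fixture_config(seed = 1)
  amp <- amputee_mode(cfg, c("EDM", "EP"))
  expect_identical(amp$n_channels, 7L)
  expect_false(any(c("EDM", "EP") %in% amp$channel_names))
  expect_identical(dim(amp$amplitude_matrix), c(12L, 7L))
  expect_equal(max(amp$amplitude_matrix), max(cfg$amplitude_matrix))
  same <- amputee_mode(cfg, integer(0))
  expect_equal(same$amplitude_matrix, cfg$amplitude_matrix)
  expect_identical(same$channel_names, cfg$channel_names)
  expect_error(amputee_mode(cfg, 1:9), "all channels")
  expect_error(amputee_mode(cfg, "nonexistent"), "existing channels")
})

test_that("configs validate their invariants and round-trip through JSON", {
  expect_error(synth_config(postures = character(0)), "nonempty")
  expect_error(synth_config(postures = c("rest", "fist")), "unknown postures")
  expect_error(synth_config(crosstalk_lambda = 0.6), "crosstalk_lambda")
  expect_error(synth_config(sigma_trial = -0.1), "sigma_trial")
  expect_error(synth_config(amplitude_matrix =
                              -default_amplitude_matrix()), "nonnegative")
  cfg <- tiny_config(seed = 8)
  p <- file.path(tempdir(), "cfg.json")
  write_synth_config(cfg, p)
  back <- read_synth_config(p)
  expect_equal(back$amplitude_matrix, cfg$amplitude_matrix)
  expect_identical(back$postures, cfg$postures)
  expect_identical(back$seed, cfg$seed)
  sim1 <- generate_dataset(cfg)
  sim2 <- generate_dataset(back)
  expect_identical(sim1$recordings[[1]]$samples, sim2$recordings[[1]]$samples)
  unlink(p)
})

test_that("shipped fixture files match their constructors", {
  hp <- system.file("extdata", "healthy_9ch.json", package = "semgkit")
  ap <- system.file("extdata", "amputee_8ch.json", package = "semgkit")
  h <- read_synth_config(hp)
  a <- read_synth_config(ap)
  expect_equal(h$amplitude_matrix, healthy_fixture_config()$amplitude_matrix)
  expect_identical(h$sigma_trial, c(0.5, 0.25, 0.1))
  expect_identical(a$n_channels, 8L)
  expect_identical(a$channel_names,
                   c("BR", "FCR", "ECR", "ED", "ECU", "FDP", "FDS", "FCU"))
  expect_equal(a$amplitude_matrix,
               amputee_fixture_config()$amplitude_matrix)
  expect_length(a$sigma_trial, 5L)
})
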