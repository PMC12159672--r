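# Synthetic soundscape generator: call spectra, activity cycles, ground
# truth, schedules and corpus reproducibility.

test_that("synthesized calls confine their energy to the template band", {
  tpl <- sonotype_template("t", "narrowband_trill", 5000, 400,
                           pulse_rate = 8, duty_cycle = 0.5, level_db = -12)
  w <- synthesize_call(tpl, 2, FIX_SR, seed = 3)
  pow <- Mod(stats::fft(w))^2
  half <- floor(length(w) / 2)
  f <- (seq_len(half) - 1) / length(w) * FIX_SR
  inband <- sum(pow[seq_len(half)][f >= 4800 - 60 & f <= 5200 + 60])
  expect_gt(inband / sum(pow[seq_len(half)]), 0.9)
  expect_equal(max(abs(w)), 10^(-12 / 20), tolerance = 1e-9)
})

test_that("unmodulated templates produce a steady envelope", {
  tpl <- sonotype_template("t", "tonal_whine", 6000, 100, pulse_rate = 0,
                           duty_cycle = 1, level_db = -10)
  w <- synthesize_call(tpl, 1, FIX_SR, seed = 1)
  env <- amplitude_envelope(audio_clip(w, FIX_SR))
  body <- env[500:(length(env) - 500)]
  expect_lt(stats::sd(body) / mean(body), 0.05)
})

test_that("call synthesis is bit-reproducible under a fixed seed", {
  tpl <- sonotype_template("t", "broadband_burst", 7000, 1200,
                           pulse_rate = 2, duty_cycle = 0.4, level_db = -20)
  expect_identical(synthesize_call(tpl, 1, FIX_SR, seed = 99),
                   synthesize_call(tpl, 1, FIX_SR, seed = 99))
})

test_that("template invariants are enforced", {
  expect_error(sonotype_template("x", "tonal_whine", 9900, 400), "insect band")
  expect_error(sonotype_template("x", "tonal_whine", 5000, 100,
                                 duty_cycle = 0), "duty_cycle")
  expect_error(sonotype_template("x", "tonal_whine", 5000, 100,
                                 level_db = 3), "level_db")
  expect_error(synthesize_call(sonotype_template("x", "tonal_whine", 9000,
                                                 100), 1, 8000), "Nyquist")
})

test_that("activation probability is periodic in hour and day of year", {
  am <- default_activity_model(6)
  expect_equal(activity_prob(am, 23, 250), activity_prob(am, 23 + 24, 250))
  expect_equal(activity_prob(am, 5, 10), activity_prob(am, 5, 10 + 365))
  expect_true(all(activity_prob(am, 13.5, 100) >= 0 &
                    activity_prob(am, 13.5, 100) <= 1))
})

test_that("silent activity gives empty truth; forced activity counts all", {
  dt <- as.POSIXct("2018-06-01 23:00:00", tz = "UTC")
  lib <- default_sonotype_library(6)
  off <- activity_model(baseline = -Inf, n_sonotypes = 6)
  sim <- simulate_clip(dt, "T1", lib, off, seed = 5, duration = 2,
                       sample_rate = FIX_SR)
  expect_equal(sim$truth$coverage, 0)
  expect_equal(sim$truth$n_sonotypes_15s, 0)

  lib20 <- default_sonotype_library(20)
  on <- activity_model(baseline = 50, hour_amplitude = 0, doy_amplitude = 0,
                       n_sonotypes = 20)
  sim2 <- simulate_clip(dt, "T1", lib20, on, seed = 5, duration = 2,
                        sample_rate = FIX_SR)
  expect_equal(sim2$truth$n_sonotypes_15s, 20)
  expect_gt(sim2$truth$coverage, 0)
})

test_that("nocturnal activity yields higher truth coverage at night", {
  lib <- default_sonotype_library(8)
  act <- default_activity_model(8)
  cov_at <- function(hour, seeds) {
    vapply(seeds, function(s) {
      dt <- as.POSIXct(sprintf("2018-09-01 %02d:00:00", hour), tz = "UTC")
      simulate_clip(dt, "T1", lib, act, seed = s, duration = 1,
                    sample_rate = FIX_SR)$truth$coverage
    }, numeric(1))
  }
  night <- cov_at(23, 1:60)
  noon <- cov_at(12, 1:60)
  expect_gt(mean(night), mean(noon))
})

test_that("truth labels are monotone in the number of activated templates", {
  dt <- as.POSIXct("2018-09-01 23:00:00", tz = "UTC")
  on <- function(n) activity_model(baseline = 50, hour_amplitude = 0,
                                   doy_amplitude = 0, n_sonotypes = n)
  lib <- default_sonotype_library(8)
  cov_k <- vapply(c(2, 4, 8), function(k) {
    simulate_clip(dt, "T1", lib[seq_len(k)], on(k), seed = 7, duration = 1,
                  sample_rate = FIX_SR)$truth$coverage
  }, numeric(1))
  expect_true(all(diff(cov_k) >= 0))
})

test_that("coverage is quantized to 0.05 and sonotype counts are bounded", {
  lib <- default_sonotype_library(10)
  act <- default_activity_model(10)
  for (s in 1:10) {
    sim <- simulate_clip(as.POSIXct("2018-08-15 22:00:00", tz = "UTC"), "T2",
                         lib, act, seed = s, duration = 1,
                         sample_rate = FIX_SR)
    expect_lt(abs(sim$truth$coverage / 0.05 -
                    round(sim$truth$coverage / 0.05)), 1e-9)
    expect_lte(sim$truth$n_sonotypes_15s, 10)
  }
})

test_that("schedule arithmetic matches the field deployment design", {
  # full design: 3 sites x 730 days x 144 clips/day
  full <- recording_schedule()
  expect_equal(planned_clip_count(full), 315360)
  expect_equal(planned_clip_count(full), 144 * 730 * 3)
  one <- recording_schedule(sites = "T1", start_date = "2018-05-01",
                            end_date = "2018-05-01")
  expect_equal(planned_clip_count(one), 144)
  pc <- planned_clips(one)
  expect_equal(nrow(pc), 144)
  expect_equal(as.integer(diff(pc$datetime[1:2]), units = "mins"), 10)
  expect_error(recording_schedule(missing_fraction = 1), "missing_fraction")
})

test_that("missing fraction and contamination rates are honoured", {
  sch <- recording_schedule(sites = "T1", start_date = "2018-06-01",
                            end_date = "2018-06-02", cadence_minutes = 30,
                            missing_fraction = 0.25)
  res <- simulate_corpus(sch, library = default_sonotype_library(4),
                         activity = default_activity_model(4),
                         rain_rate = 0.2, seed = 21, duration = 0.5,
                         sample_rate = FIX_SR)
  expect_equal(nrow(res$truth), round(96 * 0.75))
  n_rain <- sum(res$truth$rain_flag)
  p <- 0.2; n <- nrow(res$truth)
  expect_lt(abs(n_rain - n * p), 4 * sqrt(n * p * (1 - p)))
})

test_that("corpus generation is fully reproducible under a fixed seed", {
  sch <- recording_schedule(sites = "T1", start_date = "2018-07-01",
                            end_date = "2018-07-01", cadence_minutes = 240,
                            missing_fraction = 0.1)
  a <- simulate_corpus(sch, library = default_sonotype_library(4),
                       rain_rate = 0.2, fault_rate = 0.2, seed = 31,
                       duration = 0.5, sample_rate = FIX_SR,
                       keep_audio = TRUE)
  b <- simulate_corpus(sch, library = default_sonotype_library(4),
                       rain_rate = 0.2, fault_rate = 0.2, seed = 31,
                       duration = 0.5, sample_rate = FIX_SR,
                       keep_audio = TRUE)
  expect_identical(a$truth, b$truth)
  for (j in seq_along(a$clips)) {
    expect_identical(a$clips[[j]]$samples, b$clips[[j]]$samples)
  }
})

test_that("corpus WAV output follows the naming convention", {
  dir <- file.path(tempdir(), "corpus_naming")
  sch <- recording_schedule(sites = "S1", start_date = "2019-02-03",
                            end_date = "2019-02-03", cadence_minutes = 720)
  res <- simulate_corpus(sch, library = default_sonotype_library(3),
                         seed = 41, duration = 0.5, sample_rate = FIX_SR,
                         output_dir = dir)
  files <- list.files(dir, pattern = "\\.wav$")
  expect_setequal(files, c("S1_20190203_000000.wav", "S1_20190203_120000.wav"))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  clip <- read_wav(file.path(dir, files[1]))
  expect_equal(clip$site, "S1")
})

test_that("fault clips carry empty labels; rain clips keep insect labels", {
  dt <- as.POSIXct("2018-09-01 23:00:00", tz = "UTC")
  lib <- default_sonotype_library(8)
  on <- activity_model(baseline = 50, n_sonotypes = 8)
  f <- simulate_clip(dt, "T1", lib, on, seed = 9, duration = 1,
                     sample_rate = FIX_SR, fault = TRUE)
  expect_equal(f$truth$n_sonotypes_15s, 0)
  expect_true(f$truth$fault_flag)
  r <- simulate_clip(dt, "T1", lib, on, seed = 9, duration = 1,
                     sample_rate = FIX_SR, rain = TRUE)
  expect_equal(r$truth$n_sonotypes_15s, 8)
  expect_true(r$truth$rain_flag)
})
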