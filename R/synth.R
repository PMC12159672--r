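# Synthetic soundscape generator: sonotype templates, diel/seasonal activity
# models, per-clip simulation with deterministic ground-truth labels, and
# corpus generation on a recorder schedule with missing files, rain and
# recorder faults. This is the validation substrate for the whole pipeline:
# it produces audio whose true insect activity is known.

#' Define an insect sonotype template
#'
#' A sonotype is an acoustically distinct call class confined to the insect
#' band. Three stylized classes are supported: `narrowband_trill` (pulsed
#' narrow noise band, cricket-like), `broadband_burst` (pulsed wide noise
#' band, katydid/cicada-like) and `tonal_whine` (sustained pure tone).
#'
#' @param id Template identifier.
#' @param call_class One of `"narrowband_trill"`, `"broadband_burst"`,
#'   `"tonal_whine"`.
#' @param center_freq Centre frequency in Hz; `center_freq +- bandwidth / 2`
#'   must stay within \[3000, 10000\].
#' @param bandwidth Bandwidth in Hz (> 0).
#' @param pulse_rate Pulse repetition rate in Hz (>= 0; 0 means unmodulated).
#' @param duty_cycle Fraction of each pulse period with sound, in (0, 1\].
#' @param level_db Peak level in dB relative to full scale (<= 0).
#' @return A `sonotype_template`.
#' @export
sonotype_template <- function(id, call_class = c("narrowband_trill",
                                                 "broadband_burst",
                                                 "tonal_whine"),
                              center_freq, bandwidth, pulse_rate = 0,
                              duty_cycle = 1, level_db = -20) {
  call_class <- match.arg(call_class)
  if (bandwidth <= 0) stop("sonotype_template: bandwidth must be > 0")
  if (center_freq - bandwidth / 2 < 3000 ||
      center_freq + bandwidth / 2 > 10000) {
    stop("sonotype_template: band [", center_freq - bandwidth / 2, ", ",
         center_freq + bandwidth / 2, "] Hz leaves the 3-10 kHz insect band")
  }
  if (duty_cycle <= 0 || duty_cycle > 1) {
    stop("sonotype_template: duty_cycle must be in (0, 1]")
  }
  if (pulse_rate < 0) stop("sonotype_template: pulse_rate must be >= 0")
  if (level_db > 0) stop("sonotype_template: level_db must be <= 0")
  structure(list(id = id, call_class = call_class, center_freq = center_freq,
                 bandwidth = bandwidth, pulse_rate = pulse_rate,
                 duty_cycle = duty_cycle, level_db = level_db),
            class = "sonotype_template")
}

#' Default sonotype library
#'
#' A deterministic library spanning the 3-10 kHz insect band with alternating
#' call classes, pulse structures and levels, emulating a cricket- and
#' katydid-dominated tropical assemblage.
#'
#' @param n Number of templates (default 12).
#' @return List of `sonotype_template` objects.
#' @export
default_sonotype_library <- function(n = 12) {
  centers <- seq(3700, 9300, length.out = n)
  classes <- rep(c("narrowband_trill", "broadband_burst", "tonal_whine"),
                 length.out = n)
  lapply(seq_len(n), function(i) {
    cls <- classes[i]
    sonotype_template(
      id = sprintf("S%02d", i),
      call_class = cls,
      center_freq = centers[i],
      bandwidth = switch(cls, narrowband_trill = 350, broadband_burst = 1200,
                         tonal_whine = 120),
      pulse_rate = switch(cls, narrowband_trill = 8, broadband_burst = 2,
                          tonal_whine = 0),
      duty_cycle = switch(cls, narrowband_trill = 0.5, broadband_burst = 0.35,
                          tonal_whine = 1),
      level_db = -32 + 14 * (i - 1) / max(1, n - 1)
    )
  })
}

#' Define a diel/seasonal activity model
#'
#' Each sonotype is active in a clip independently with probability
#' `plogis(baseline + hour_amplitude * cos(2*pi*(hour - hour_peak)/24) +
#' doy_amplitude * cos(2*pi*(doy - doy_peak)/365))`, giving smooth 24 h and
#' 365 d periodic activity cycles. Parameters are recycled across sonotypes.
#'
#' @param baseline Logit-scale baseline activity.
#' @param hour_peak Hour of peak activity in \[0, 24).
#' @param hour_amplitude Logit-scale diel amplitude (>= 0).
#' @param doy_peak Day-of-year of peak activity in \[1, 365\].
#' @param doy_amplitude Logit-scale seasonal amplitude (>= 0).
#' @param n_sonotypes Number of sonotypes the model covers.
#' @return An `activity_model`.
#' @export
activity_model <- function(baseline = 0, hour_peak = 23, hour_amplitude = 2,
                           doy_peak = 255, doy_amplitude = 1,
                           n_sonotypes = 12) {
  if (any(hour_amplitude < 0) || any(doy_amplitude < 0)) {
    stop("activity_model: amplitudes must be >= 0")
  }
  structure(list(
    baseline = rep_len(baseline, n_sonotypes),
    hour_peak = rep_len(hour_peak, n_sonotypes),
    hour_amplitude = rep_len(hour_amplitude, n_sonotypes),
    doy_peak = rep_len(doy_peak, n_sonotypes),
    doy_amplitude = rep_len(doy_amplitude, n_sonotypes),
    n_sonotypes = n_sonotypes
  ), class = "activity_model")
}

#' Default activity model: nocturnal, dry-season peaking
#'
#' Activity peaks at night (peak hours staggered between 21.00 and 01.00) and
#' during the dry season (peak days staggered through August-October),
#' emulating the diel and seasonal periodicity of Amazonian insect biophony.
#'
#' @param n_sonotypes Number of sonotypes (default 12).
#' @return An `activity_model`.
#' @export
default_activity_model <- function(n_sonotypes = 12) {
  i <- seq_len(n_sonotypes)
  activity_model(
    baseline = 0,
    hour_peak = (21 + (i * 7) %% 5) %% 24,
    hour_amplitude = 2,
    doy_peak = 225 + (i * 13) %% 60,
    doy_amplitude = 1,
    n_sonotypes = n_sonotypes
  )
}

#' Per-sonotype activation probability
#'
#' @param model An `activity_model`.
#' @param hour Decimal hour of day (any real; periodic with period 24).
#' @param doy Day of year (any real; periodic with period 365).
#' @return Vector of probabilities, one per sonotype.
#' @export
activity_prob <- function(model, hour, doy) {
  stopifnot(inherits(model, "activity_model"))
  inv_logit(model$baseline +
              model$hour_amplitude * cos(2 * pi * (hour - model$hour_peak) / 24) +
              model$doy_amplitude * cos(2 * pi * (doy - model$doy_peak) / 365))
}

# Band-limited Gaussian noise, unit peak: complex Gaussian spectrum on the
# in-band bins only, Hermitian-symmetrized, one inverse FFT.
band_noise <- function(n, sample_rate, f_lo, f_hi) {
  half <- (n - 1L) %/% 2L                    # strictly positive, non-Nyquist
  sel <- max(1L, ceiling(f_lo * n / sample_rate)):
    min(half, floor(f_hi * n / sample_rate))
  spec <- complex(real = stats::rnorm(length(sel)),
                  imaginary = stats::rnorm(length(sel)))
  s <- complex(n)
  s[1L + sel] <- spec
  s[n + 1L - sel] <- Conj(spec)
  y <- Re(stats::fft(s, inverse = TRUE))
  y / max(abs(y))
}

#' Synthesize one sonotype call
#'
#' Produces a waveform whose spectral energy is confined to
#' `center_freq +- bandwidth / 2`, amplitude-modulated at `pulse_rate` with
#' the template's duty cycle (2 ms raised-cosine pulse edges), peak-scaled to
#' `level_db`.
#'
#' @param template A `sonotype_template`.
#' @param duration Call duration in seconds.
#' @param sample_rate Sampling rate in Hz; must be at least twice the upper
#'   band edge.
#' @param seed Integer seed (stochastic classes are reproducible given it).
#' @return Numeric waveform of `round(duration * sample_rate)` samples.
#' @export
synthesize_call <- function(template, duration, sample_rate, seed = 1L) {
  stopifnot(inherits(template, "sonotype_template"))
  if (duration <= 0) stop("synthesize_call: duration must be > 0")
  f_hi <- template$center_freq + template$bandwidth / 2
  if (sample_rate < 2 * f_hi) {
    stop("synthesize_call: sample_rate ", sample_rate,
         " below Nyquist requirement ", 2 * f_hi)
  }
  set.seed(seed)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  carrier <- switch(template$call_class,
    tonal_whine = sin(2 * pi * template$center_freq * t +
                        stats::runif(1, 0, 2 * pi)),
    band_noise(n, sample_rate, template$center_freq - template$bandwidth / 2,
               template$center_freq + template$bandwidth / 2)
  )
  if (template$pulse_rate > 0 && template$duty_cycle < 1) {
    phase <- (t * template$pulse_rate) %% 1
    duty <- template$duty_cycle
    ramp <- min(0.002 * template$pulse_rate, duty / 4)
    up <- pmax(0, pmin(1, phase / ramp))
    down <- pmax(0, pmin(1, (duty - phase) / ramp))
    carrier <- carrier * (0.5 * (1 - cospi(up))) * (0.5 * (1 - cospi(down)))
  }
  carrier / max(abs(carrier)) * db_to_amp(template$level_db)
}

# Coverage label: fraction of spectrogram cells (3-10 kHz, first 15 s) where
# the insect signal exceeds the realized background by margin_db, rounded to
# the nearest 0.05 -- the computable analogue of a "nearest 5%" visual
# estimate.
truth_coverage <- function(signal, noise, sample_rate, margin_db = 6,
                           f_min = 3000, f_max = 10000,
                           window_length = 512) {
  n15 <- min(length(signal), round(15 * sample_rate))
  sp_s <- compute_spectrogram(audio_clip(signal[seq_len(n15)] /
                                           max(1, max(abs(signal))),
                                         sample_rate),
                              window_length = window_length)
  # un-normalize: audio_clip() requires [-1,1]; rescale amplitudes back
  scale_back <- max(1, max(abs(signal)))
  sp_n <- compute_spectrogram(audio_clip(noise[seq_len(n15)] /
                                           max(1, max(abs(noise))),
                                         sample_rate),
                              window_length = window_length)
  rows <- sp_s$freq_axis >= f_min & sp_s$freq_axis <= f_max
  occ <- sp_s$amplitude[rows, , drop = FALSE] * scale_back >
    sp_n$amplitude[rows, , drop = FALSE] * max(1, max(abs(noise))) *
      db_to_amp(margin_db)
  round(mean(occ) / 0.05) * 0.05
}

#' Simulate one 1-min recording and its ground truth
#'
#' Each sonotype in the library is activated independently with its
#' diel/seasonal probability; active calls are synthesized over the full clip
#' and summed with Gaussian background noise. Ground truth for the first 15 s
#' window comprises the audible sonotype count and the quantized spectrogram
#' coverage. Optionally superimposes rain noise or replaces the content with a
#' recorder-fault signature.
#'
#' @param datetime `POSIXct` recording start.
#' @param site Site id.
#' @param library List of `sonotype_template`.
#' @param activity An `activity_model` covering the library.
#' @param noise_floor_db Background noise RMS in dBFS (default -60).
#' @param seed Integer seed.
#' @param duration Clip length in seconds (default 60).
#' @param sample_rate Hz (default 44100).
#' @param margin_db Audibility margin above background for ground truth
#'   (default 6 dB).
#' @param rain,fault Logical contamination flags.
#' @param clip_policy `"rescale"` (rescale mixtures that would clip to
#'   -1 dBFS, with a warning) or `"error"`.
#' @param call_cache Optional list of pre-synthesized call waveforms (one per
#'   template, as produced by [synthesize_call()] for the same duration and
#'   rate). When supplied, active calls are drawn from the cache with a
#'   random circular time shift instead of being re-synthesized, which makes
#'   large corpora tractable.
#' @return List with `clip` (`audio_clip`) and `truth` (one-row data frame:
#'   clip_id, site, datetime_iso, hour, doy, year, n_sonotypes_15s, coverage,
#'   rain_flag, fault_flag).
#' @export
simulate_clip <- function(datetime, site, library = default_sonotype_library(),
                          activity = default_activity_model(length(library)),
                          noise_floor_db = -60, seed = 1L, duration = 60,
                          sample_rate = 44100, margin_db = 6, rain = FALSE,
                          fault = FALSE,
                          clip_policy = c("rescale", "error"),
                          call_cache = NULL) {
  clip_policy <- match.arg(clip_policy)
  if (length(library) == 0L) stop("simulate_clip: empty sonotype library")
  lt <- as.POSIXlt(datetime)
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  doy <- min(lt$yday + 1L, 365L)       # non-leap calendar, domain 1-365
  year <- lt$year + 1900L
  clip_id <- sprintf("%s_%s", site, format(datetime, "%Y%m%d_%H%M%S"))

  set.seed(derive_seed(seed, clip_id, "activate"))
  p <- activity_prob(activity, hour, doy)
  active <- stats::runif(length(library)) < p

  n <- round(duration * sample_rate)
  signal <- numeric(n)
  for (i in which(active)) {
    if (is.null(call_cache)) {
      signal <- signal + synthesize_call(library[[i]], duration, sample_rate,
                                         seed = derive_seed(seed, clip_id, i))
    } else {
      set.seed(derive_seed(seed, clip_id, i))
      shift <- sample.int(n, 1L) - 1L
      w <- call_cache[[i]]
      signal <- signal + if (shift == 0L) w else c(w[(shift + 1L):n],
                                                   w[seq_len(shift)])
    }
  }
  set.seed(derive_seed(seed, clip_id, "noise"))
  sigma <- db_to_amp(noise_floor_db)
  noise <- stats::rnorm(n, sd = sigma)

  # ground truth from the pre-contamination mixture
  audible <- active &
    vapply(library, function(tp) tp$level_db >= noise_floor_db + margin_db,
           logical(1)) &
    vapply(library, function(tp) {
      duty <- if (tp$pulse_rate > 0) tp$duty_cycle else 1
      duty * 15 >= 1
    }, logical(1))
  cover <- if (any(active)) {
    truth_coverage(signal, noise, sample_rate, margin_db = margin_db)
  } else 0

  x <- signal + noise
  if (fault) {
    set.seed(derive_seed(seed, clip_id, "fault"))
    x <- if (stats::runif(1) < 0.5) {
      stats::rnorm(n, sd = db_to_amp(-90))              # near-silent
    } else {
      0.5 * sin(2 * pi * 5000 * (seq_len(n) - 1) / sample_rate)  # stuck tone
    }
    audible[] <- FALSE
    cover <- 0
  } else if (rain) {
    set.seed(derive_seed(seed, clip_id, "rain"))
    freqs <- (seq_len(n) - 1) / n * sample_rate
    freqs <- pmin(freqs, sample_rate - freqs)
    shape <- 1 / sqrt(1 + (freqs / 1200)^2) + 0.15
    r <- Re(stats::fft(stats::fft(stats::rnorm(n)) * shape, inverse = TRUE)) / n
    x <- x + r / stats::sd(r) * db_to_amp(-22)
  }
  peak <- max(abs(x))
  if (peak > 1) {
    if (clip_policy == "error") stop("simulate_clip: mixture clips (peak ",
                                     round(peak, 3), ")")
    warning("simulate_clip: mixture clipped; rescaled to -1 dBFS (", clip_id,
            ")")
    x <- x / peak * db_to_amp(-1)
  }
  truth <- data.frame(
    clip_id = clip_id, site = site,
    datetime_iso = format(datetime, "%Y-%m-%dT%H:%M:%S"),
    hour = floor(hour) + 1, doy = doy, year = year,
    n_sonotypes_15s = sum(audible), coverage = cover,
    rain_flag = rain, fault_flag = fault, stringsAsFactors = FALSE
  )
  list(clip = audio_clip(x, sample_rate, clip_id = clip_id, site = site,
                         timestamp = as.POSIXct(datetime)),
       truth = truth)
}

#' Define a recording schedule
#'
#' The field deployment records 1 min every `cadence_minutes` (default 10:
#' "1 min on, 9 min off") at each site, so a full day plans
#' `1440 / cadence_minutes` clips per site.
#'
#' @param sites Character vector of site ids (default 3 transects).
#' @param start_date,end_date Calendar dates (inclusive).
#' @param missing_fraction Fraction of planned clips lost to recorder failure,
#'   in \[0, 1).
#' @param cadence_minutes Minutes between recording starts (default 10).
#' @param day_step Sample every `day_step`-th calendar day (default 1 = every
#'   day; larger values thin the schedule for desk-scale corpora while
#'   keeping full diel and annual coverage).
#' @return A `recording_schedule`.
#' @export
recording_schedule <- function(sites = c("T1", "T2", "T3"),
                               start_date = "2018-01-01",
                               end_date = "2019-12-31",
                               missing_fraction = 0,
                               cadence_minutes = 10,
                               day_step = 1) {
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("recording_schedule: missing_fraction must be in [0, 1)")
  }
  structure(list(sites = sites, start_date = as.Date(start_date),
                 end_date = as.Date(end_date),
                 missing_fraction = missing_fraction,
                 cadence_minutes = cadence_minutes,
                 day_step = day_step),
            class = "recording_schedule")
}

schedule_days <- function(schedule) {
  seq(schedule$start_date, schedule$end_date, by = paste(schedule$day_step,
                                                         "days"))
}

#' Planned clip count of a schedule
#' @param schedule A `recording_schedule`.
#' @return Integer: scheduled days x clips-per-day x sites.
#' @export
planned_clip_count <- function(schedule) {
  length(schedule_days(schedule)) *
    as.integer(1440 / schedule$cadence_minutes) * length(schedule$sites)
}

#' Expand a schedule into planned clip start times
#' @param schedule A `recording_schedule`.
#' @return Data frame with `site` and `datetime` (POSIXct, UTC).
#' @export
planned_clips <- function(schedule) {
  days <- schedule_days(schedule)
  mins <- seq(0, 1439, by = schedule$cadence_minutes)
  dt <- as.POSIXct(outer(as.numeric(as.POSIXct(days, tz = "UTC")), mins * 60,
                         "+"),
                   origin = "1970-01-01", tz = "UTC")
  grid <- expand.grid(datetime = sort(dt), site = schedule$sites,
                      stringsAsFactors = FALSE)
  grid[order(grid$site, grid$datetime), c("site", "datetime")]
}

#' Simulate a recording corpus
#'
#' Expands the schedule, drops the scheduled missing fraction, draws rain and
#' fault contamination at the given rates, simulates every realized clip and
#' returns the ground-truth table. Audio can be written as
#' `<site>_<YYYYMMDD>_<HHMMSS>.wav` files, kept in memory, or streamed to a
#' callback (for corpora too large to hold).
#'
#' @param schedule A `recording_schedule`.
#' @param library Sonotype library.
#' @param activity An `activity_model`.
#' @param rain_rate,fault_rate Contamination probabilities in \[0, 1).
#' @param seed Integer seed; the corpus (truth table and audio bytes) is fully
#'   reproducible given it.
#' @param output_dir If non-NULL, WAV files and `truth.csv` are written here.
#' @param duration,sample_rate,noise_floor_db,margin_db Passed to
#'   [simulate_clip()].
#' @param keep_audio If TRUE, return the clips in memory (small corpora only).
#' @param on_clip Optional `function(clip, truth_row)`; non-NULL return values
#'   are collected and returned as `processed`.
#' @return List with `truth` (data frame), `clips` (list or NULL) and
#'   `processed` (list of callback results or NULL).
#' @export
simulate_corpus <- function(schedule, library = default_sonotype_library(),
                            activity = default_activity_model(length(library)),
                            rain_rate = 0, fault_rate = 0, seed = 1L,
                            output_dir = NULL, duration = 60,
                            sample_rate = 44100, noise_floor_db = -60,
                            margin_db = 6, keep_audio = FALSE,
                            on_clip = NULL) {
  if (rain_rate < 0 || rain_rate >= 1 || fault_rate < 0 || fault_rate >= 1) {
    stop("simulate_corpus: rates must be in [0, 1)")
  }
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    if (!dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)) {
      stop("simulate_corpus: cannot create output directory ", output_dir)
    }
  }
  plan <- planned_clips(schedule)
  n_plan <- nrow(plan)
  set.seed(derive_seed(seed, "schedule"))
  n_keep <- round(n_plan * (1 - schedule$missing_fraction))
  realized <- sort(sample.int(n_plan, n_keep))
  plan <- plan[realized, , drop = FALSE]
  set.seed(derive_seed(seed, "contamination"))
  fault <- stats::runif(n_keep) < fault_rate
  rain <- !fault & stats::runif(n_keep) < rain_rate

  # synthesize each template once; clips reuse the waveform with a random
  # circular shift (cuts corpus cost by an order of magnitude)
  call_cache <- lapply(seq_along(library), function(i) {
    synthesize_call(library[[i]], duration, sample_rate,
                    seed = derive_seed(seed, "call_cache", i))
  })

  truth <- vector("list", n_keep)
  clips <- if (keep_audio) vector("list", n_keep) else NULL
  processed <- if (!is.null(on_clip)) vector("list", n_keep) else NULL
  for (j in seq_len(n_keep)) {
    sim <- simulate_clip(plan$datetime[j], plan$site[j], library, activity,
                         noise_floor_db = noise_floor_db, seed = seed,
                         duration = duration, sample_rate = sample_rate,
                         margin_db = margin_db, rain = rain[j],
                         fault = fault[j], call_cache = call_cache)
    truth[[j]] <- sim$truth
    if (!is.null(output_dir)) {
      write_wav(sim$clip, file.path(output_dir,
                                    paste0(sim$truth$clip_id, ".wav")))
    }
    if (keep_audio) clips[[j]] <- sim$clip
    if (!is.null(on_clip)) processed[[j]] <- on_clip(sim$clip, sim$truth)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  if (!is.null(output_dir)) {
    utils::write.csv(truth, file.path(output_dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(truth = truth, clips = clips, processed = processed)
}
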