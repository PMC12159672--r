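# Shared fixtures, generated in code. Small sample rates keep the suite fast
# while respecting the Nyquist requirement of the 3-10 kHz insect band.

FIX_SR <- 22050

tone_clip <- function(freq, duration = 1, sr = FIX_SR, amp = 0.5,
                      clip_id = NA_character_) {
  t <- (seq_len(round(duration * sr)) - 1) / sr
  audio_clip(amp * sin(2 * pi * freq * t), sr, clip_id = clip_id)
}

noise_clip <- function(duration = 1, sr = FIX_SR, amp = 0.1, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(round(duration * sr))
  audio_clip(amp * x / max(abs(x)), sr)
}

silent_clip <- function(duration = 1, sr = FIX_SR) {
  audio_clip(rep(0, round(duration * sr)), sr)
}

# hand-buildable spectrogram for index oracles
toy_spectrogram <- function(amplitude, sample_rate = 1024,
                            window_length = 64) {
  structure(list(
    amplitude = amplitude,
    freq_axis = (seq_len(nrow(amplitude)) - 1) * sample_rate / window_length,
    time_axis = (seq_len(ncol(amplitude)) - 0.5) * window_length /
      sample_rate,
    window_length = window_length, overlap = 0, sample_rate = sample_rate),
    class = "spectrogram")
}

# rain-like clip: broadband noise with low-frequency emphasis
rain_clip <- function(duration = 1, sr = FIX_SR, seed = 1) {
  set.seed(seed)
  n <- round(duration * sr)
  freqs <- (seq_len(n) - 1) / n * sr
  freqs <- pmin(freqs, sr - freqs)
  shape <- 1 / sqrt(1 + (freqs / 1200)^2) + 0.15
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * shape, inverse = TRUE)) / n
  audio_clip(0.4 * x / max(abs(x)), sr)
}

# small calibration dataset with BI-driven responses
make_calib_data <- function(n, seed = 1, beta0 = -2, beta1 = 4, sd = 0.08) {
  set.seed(seed)
  d <- data.frame(aci_s = runif(n), adi_s = runif(n), bi_s = runif(n),
                  h_s = runif(n), np_s = runif(n),
                  site = sample(c("T1", "T2", "T3"), n, TRUE),
                  year = sample(2018:2019, n, TRUE))
  raw <- plogis(beta0 + beta1 * d$bi_s) + rnorm(n, 0, sd)
  d$coverage <- squeeze_proportion(round(pmin(pmax(raw, 0), 1) / 0.05) * 0.05)
  d$sonotypes <- rpois(n, exp(0.5 + 2 * d$bi_s))
  d
}
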