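# The five acoustic indices, restricted to the insect band (3-10 kHz), and
# the min-max scaling used before calibration. ACI and BI work on a
# spectrogram with explicit band limits; ADI and H expect a clip that has
# already been band-pass filtered; NP selects its count band on the mean
# spectrum itself.

#' Acoustic complexity index (ACI)
#'
#' For each frequency bin inside the band and each temporal chunk, sums the
#' absolute amplitude differences between successive frames divided by the
#' total amplitude in the chunk, then sums over bins and chunks. Chunks with
#' zero total amplitude contribute 0.
#'
#' @param spec A `spectrogram`.
#' @param f_min,f_max Band limits in Hz (defaults 3000, 10000).
#' @param chunk_duration Temporal chunk length in seconds (default 5);
#'   trailing frames that do not fill a chunk are analysed as a final shorter
#'   chunk.
#' @return Nonnegative ACI value.
#' @export
compute_aci <- function(spec, f_min = 3000, f_max = 10000,
                        chunk_duration = 5) {
  stopifnot(inherits(spec, "spectrogram"))
  rows <- which(spec$freq_axis >= f_min & spec$freq_axis <= f_max)
  if (length(rows) == 0L) {
    stop("compute_aci: no frequency bins inside [", f_min, ", ", f_max, "] Hz")
  }
  a <- spec$amplitude[rows, , drop = FALSE]
  n_frames <- ncol(a)
  hop <- spec$window_length * (1 - spec$overlap)
  frames_per_chunk <- max(2L, floor(chunk_duration * spec$sample_rate / hop))
  chunk_id <- ceiling(seq_len(n_frames) / frames_per_chunk)
  total <- 0
  for (j in unique(chunk_id)) {
    aj <- a[, chunk_id == j, drop = FALSE]
    if (ncol(aj) < 2L) next
    d <- abs(aj[, -1L, drop = FALSE] - aj[, -ncol(aj), drop = FALSE])
    denom <- rowSums(aj)
    num <- rowSums(d)
    ok <- denom > 0
    total <- total + sum(num[ok] / denom[ok])
  }
  total
}

#' Acoustic diversity index (ADI)
#'
#' Shannon entropy (natural log) of the per-band occupancy proportions: the
#' fraction of spectrogram cells above a dB threshold, per 1 kHz band between
#' 0 Hz and `max_freq`. Spectrogram amplitudes are expressed in dB relative to
#' the clip's loudest cell, so the index is invariant under uniform gain.
#' Following the index recipe's stated order, the clip should be band-pass
#' filtered to 3-10 kHz first; the empty low bands this creates deflate ADI
#' and are retained deliberately.
#'
#' @param clip An `audio_clip` (already band-pass filtered in the pipeline).
#' @param max_freq Upper limit of the banded range in Hz (default 10000).
#' @param band_width Band width in Hz (default 1000).
#' @param db_threshold Occupancy threshold in dB relative to the clip maximum
#'   (default -50).
#' @param window_length FFT window (default 512).
#' @param spec Optional precomputed `spectrogram` of `clip`.
#' @return List with `adi` (nats) and `silent` flag.
#' @export
compute_adi <- function(clip, max_freq = 10000, band_width = 1000,
                        db_threshold = -50, window_length = 512,
                        spec = NULL) {
  sp <- if (is.null(spec)) {
    compute_spectrogram(clip, window_length = window_length)
  } else spec
  peak <- max(sp$amplitude)
  n_bands <- floor(max_freq / band_width)
  if (peak <= 0) return(list(adi = 0, silent = TRUE))
  db <- 20 * log10(pmax(sp$amplitude / peak, 1e-12))
  band <- floor(sp$freq_axis / band_width)
  occ <- vapply(seq_len(n_bands) - 1L, function(b) {
    rows <- which(band == b & sp$freq_axis < max_freq)
    if (length(rows) == 0L) return(0)
    mean(db[rows, , drop = FALSE] > db_threshold)
  }, numeric(1))
  if (sum(occ) <= 0) return(list(adi = 0, silent = TRUE))
  p <- occ / sum(occ)
  p <- p[p > 0]
  list(adi = -sum(p * log(p)), silent = FALSE)
}

#' Bioacoustic index (BI)
#'
#' Area of the band-limited mean dB spectrum above its quietest bin: convert
#' the time-averaged spectrum in \[`f_min`, `f_max`\] to dB, subtract the band
#' minimum, and sum weighted by bin width in kHz. Invariant under uniform
#' gain (a dB translation).
#'
#' @param spec A `spectrogram`.
#' @param f_min,f_max Band limits in Hz (defaults 3000, 10000).
#' @return List with `bi` (dB kHz) and `silent` flag.
#' @export
compute_bi <- function(spec, f_min = 3000, f_max = 10000) {
  stopifnot(inherits(spec, "spectrogram"))
  rows <- which(spec$freq_axis >= f_min & spec$freq_axis <= f_max)
  if (length(rows) == 0L) {
    stop("compute_bi: no frequency bins inside [", f_min, ", ", f_max, "] Hz")
  }
  m <- rowMeans(spec$amplitude[rows, , drop = FALSE])
  if (max(m) <= 0) return(list(bi = 0, silent = TRUE))
  db <- 20 * log10(pmax(m / max(m), 1e-12))
  bin_khz <- (spec$sample_rate / spec$window_length) / 1000
  list(bi = sum(db - min(db)) * bin_khz, silent = FALSE)
}

shannon_norm <- function(p) {
  # normalized Shannon entropy of a PMF; base-independent by construction
  p <- p[p > 0]
  if (length(p) <= 1L) return(0)
  -sum(p * log(p)) / log(length(p))
}

#' Acoustic entropy index (H)
#'
#' Product of the normalized spectral entropy (mean spectrum treated as a
#' probability mass function) and the normalized temporal entropy (amplitude
#' envelope PMF). Both factors lie in \[0, 1\], so H does too. Following the
#' index recipe's order, the clip should be band-pass filtered first.
#'
#' @param clip An `audio_clip` (already band-pass filtered in the pipeline).
#' @param window_length FFT window (default 512).
#' @param spec Optional precomputed `spectrogram` of `clip`.
#' @param envelope Optional precomputed amplitude envelope of `clip`.
#' @return List with `h`, `hf`, `ht` and `silent` flag (silence gives h = 0).
#' @export
compute_h <- function(clip, window_length = 512, spec = NULL,
                      envelope = NULL) {
  ms <- mean_spectrum(clip, window_length = window_length, spec = spec)
  if (ms$silent) return(list(h = 0, hf = 0, ht = 0, silent = TRUE))
  hf <- shannon_norm(ms$amplitude / sum(ms$amplitude))
  env <- if (is.null(envelope)) amplitude_envelope(clip) else envelope
  ht <- if (sum(env) > 0) shannon_norm(env / sum(env)) else 0
  list(h = hf * ht, hf = hf, ht = ht, silent = FALSE)
}

# Local maxima of y with prominence above `prominence`: height above the
# larger of the two flanking minima (walked outward from the peak).
find_peaks <- function(y, prominence) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- which(y[2:(n - 1L)] > y[1:(n - 2L)] &
                  y[2:(n - 1L)] >= y[3:n]) + 1L
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]
    l <- p
    while (l > 1L && y[l - 1L] <= y[l]) l <- l - 1L
    r <- p
    while (r < n && y[r + 1L] <= y[r]) r <- r + 1L
    keep[i] <- (y[p] - max(y[l], y[r])) >= prominence
  }
  cand[keep]
}

#' Number of frequency peaks (NP)
#'
#' Counts local maxima of the mean frequency spectrum. The spectrum is first
#' restricted to frequencies above `low_cut`; peaks must exceed a prominence
#' threshold (fraction of the spectrum maximum) and only peaks strictly inside
#' `count_band` are counted.
#'
#' @param clip An `audio_clip`.
#' @param low_cut Discard spectrum below this frequency in Hz (default 300).
#' @param count_band Two-element Hz vector; peaks are counted strictly inside
#'   it (default `c(3000, 10000)`).
#' @param peak_threshold Prominence threshold as a fraction of the maximum
#'   spectrum amplitude (default 0.01).
#' @param window_length FFT window (default 512).
#' @param spec Optional precomputed `spectrogram` of `clip`.
#' @return Integer peak count.
#' @export
compute_np <- function(clip, low_cut = 300, count_band = c(3000, 10000),
                       peak_threshold = 0.01, window_length = 512,
                       spec = NULL) {
  ms <- mean_spectrum(clip, window_length = window_length, spec = spec)
  if (ms$silent) return(0L)
  sel <- ms$freq > low_cut
  y <- ms$amplitude[sel]
  f <- ms$freq[sel]
  pk <- find_peaks(y, prominence = peak_threshold * max(y))
  sum(f[pk] > count_band[1] & f[pk] < count_band[2])
}

#' Compute the five-index vector for one clip
#'
#' Applies the index recipes in their documented order: ACI and BI on the
#' spectrogram of the raw clip with explicit 3-10 kHz limits; ADI and H on the
#' clip after 3-10 kHz band-pass filtering; NP on the raw clip's mean spectrum
#' with the count restricted to 3-10 kHz.
#'
#' @param clip An `audio_clip`.
#' @param f_min,f_max Insect band limits in Hz.
#' @param window_length FFT window (default 512).
#' @param aci_chunk ACI chunk duration in seconds (default 5).
#' @param adi_threshold ADI occupancy threshold in dB (default -50).
#' @param np_threshold NP prominence threshold (default 0.01).
#' @return One-row `data.frame`: clip metadata, `aci`, `adi`, `bi`, `h`, `np`
#'   and a `silent` flag (silent clips carry NA indices).
#' @export
compute_indices <- function(clip, f_min = 3000, f_max = 10000,
                            window_length = 512, aci_chunk = 5,
                            adi_threshold = -50, np_threshold = 0.01) {
  stopifnot(inherits(clip, "audio_clip"))
  sp <- compute_spectrogram(clip, window_length = window_length)
  silent <- max(sp$amplitude) <= 0
  if (silent) {
    return(data.frame(clip_id = clip$clip_id, site = clip$site,
                      aci = NA_real_, adi = NA_real_, bi = NA_real_,
                      h = NA_real_, np = NA_real_, silent = TRUE,
                      stringsAsFactors = FALSE))
  }
  an <- band_analytic(clip, f_min, f_max)
  filtered <- clip
  filtered$samples <- pmax(pmin(an$filtered, 1), -1)
  sp_filt <- compute_spectrogram(filtered, window_length = window_length)
  adi <- compute_adi(filtered, max_freq = f_max,
                     db_threshold = adi_threshold,
                     window_length = window_length, spec = sp_filt)
  h <- compute_h(filtered, window_length = window_length, spec = sp_filt,
                 envelope = an$envelope)
  bi <- compute_bi(sp, f_min = f_min, f_max = f_max)
  data.frame(
    clip_id = clip$clip_id, site = clip$site,
    aci = compute_aci(sp, f_min = f_min, f_max = f_max,
                      chunk_duration = aci_chunk),
    adi = adi$adi,
    bi = bi$bi,
    h = h$h,
    np = as.numeric(compute_np(clip, count_band = c(f_min, f_max),
                               peak_threshold = np_threshold,
                               window_length = window_length, spec = sp)),
    silent = FALSE, stringsAsFactors = FALSE
  )
}

#' Min-max scale index columns to \[0.0001, 0.9999\]
#'
#' Affine rescaling per index over the whole table:
#' `x' = 0.0001 + (x - min) / (max - min) * (0.9999 - 0.0001)`. The (min, max)
#' pair per index is stored so the transform can be inverted or applied to new
#' data.
#'
#' @param df Data frame holding the raw index columns.
#' @param cols Index column names (default the five indices).
#' @param scaling Optional scaling table from a previous call (columns
#'   `index`, `min`, `max`); when supplied those bounds are reused and new
#'   values may fall outside \[0.0001, 0.9999\].
#' @return `df` with added `<col>_s` columns and attribute `"scaling"`.
#' @export
scale_indices <- function(df, cols = c("aci", "adi", "bi", "h", "np"),
                          scaling = NULL) {
  lo <- 0.0001; hi <- 0.9999
  if (is.null(scaling)) {
    scaling <- data.frame(index = cols,
                          min = vapply(cols, function(cl) min(df[[cl]]),
                                       numeric(1)),
                          max = vapply(cols, function(cl) max(df[[cl]]),
                                       numeric(1)),
                          stringsAsFactors = FALSE)
    bad <- scaling$max - scaling$min <= 0
    if (any(bad)) {
      stop("scale_indices: constant column(s): ",
           paste(cols[bad], collapse = ", "))
    }
  }
  for (cl in cols) {
    s <- scaling[scaling$index == cl, ]
    df[[paste0(cl, "_s")]] <- lo + (df[[cl]] - s$min) / (s$max - s$min) *
      (hi - lo)
  }
  attr(df, "scaling") <- scaling
  df
}

#' Invert the \[0.0001, 0.9999\] index scaling
#'
#' @param x Scaled values.
#' @param min,max The stored bounds for that index.
#' @return Raw-scale values.
#' @export
unscale_index <- function(x, min, max) {
  lo <- 0.0001; hi <- 0.9999
  min + (x - lo) / (hi - lo) * (max - min)
}
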