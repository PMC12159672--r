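# Quality-control screening: a two-band rain classifier (trained on known
# rain clips), then Mahalanobis-distance outlier removal on the five-index
# vector. Rain screening runs first, then the distance screen, matching the
# documented cleaning order.

#' Rain metrics for one clip
#'
#' Mean band power (PSD) and band signal-to-noise ratio (temporal mean /
#' temporal SD of the band amplitude) in two diagnostic bands: 0.6-1.2 kHz,
#' where rain adds strong low-frequency energy, and 4.4-5.6 kHz, where rain's
#' broadband hiss persists but insect tones fluctuate. Heavy rain yields high
#' power *and* high (steady) SNR in both bands simultaneously.
#'
#' @param clip An `audio_clip` with sample rate of at least 11.2 kHz.
#' @param window_length FFT window (default 512).
#' @param spec Optional precomputed `spectrogram` of `clip`.
#' @return One-row data frame: `psd_low`, `psd_mid`, `snr_low`, `snr_mid`.
#' @export
rain_metrics <- function(clip, window_length = 512, spec = NULL) {
  stopifnot(inherits(clip, "audio_clip"))
  if (clip$sample_rate < 11200) {
    stop("rain_metrics: sample rate must be at least 11.2 kHz")
  }
  sp <- if (is.null(spec)) {
    compute_spectrogram(clip, window_length = window_length)
  } else spec
  band_stats <- function(f_lo, f_hi) {
    rows <- sp$freq_axis >= f_lo & sp$freq_axis <= f_hi
    a <- colMeans(sp$amplitude[rows, , drop = FALSE])
    c(psd = mean(a^2),
      snr = if (stats::sd(a) > 0) mean(a) / stats::sd(a) else 0)
  }
  lo <- band_stats(600, 1200)
  mid <- band_stats(4400, 5600)
  data.frame(psd_low = lo[["psd"]], psd_mid = mid[["psd"]],
             snr_low = lo[["snr"]], snr_mid = mid[["snr"]])
}

#' Calibrate rain-detection thresholds from known rain clips
#'
#' Thresholds are the per-metric minima over the training rain clips, shrunk
#' by a safety factor; a clip is later flagged as rain only when all four
#' metrics exceed their thresholds.
#'
#' @param rain_clips List of `audio_clip` known to contain heavy rain, or a
#'   data frame of their [rain_metrics()].
#' @param safety Multiplicative shrink factor applied to the minima
#'   (default 0.9).
#' @param min_clips Minimum training set size (default 10).
#' @return A `rain_thresholds` object (named numeric vector).
#' @export
calibrate_rain_thresholds <- function(rain_clips, safety = 0.9,
                                      min_clips = 10L) {
  m <- if (is.data.frame(rain_clips)) rain_clips else {
    do.call(rbind, lapply(rain_clips, rain_metrics))
  }
  if (is.null(m) || nrow(m) < min_clips) {
    stop("calibrate_rain_thresholds: need at least ", min_clips,
         " training rain clips, got ", if (is.null(m)) 0L else nrow(m))
  }
  thr <- vapply(c("psd_low", "psd_mid", "snr_low", "snr_mid"),
                function(cl) min(m[[cl]]) * safety, numeric(1))
  structure(thr, class = "rain_thresholds")
}

#' Classify clips as rain-contaminated
#'
#' @param metrics Data frame of [rain_metrics()] rows.
#' @param thresholds A `rain_thresholds` object.
#' @return Logical vector: TRUE where all four metrics exceed thresholds.
#' @export
classify_rain <- function(metrics, thresholds) {
  stopifnot(inherits(thresholds, "rain_thresholds"))
  metrics$psd_low >= thresholds[["psd_low"]] &
    metrics$psd_mid >= thresholds[["psd_mid"]] &
    metrics$snr_low >= thresholds[["snr_low"]] &
    metrics$snr_mid >= thresholds[["snr_mid"]]
}

#' Mahalanobis-distance screening on the five-index vector
#'
#' Squared Mahalanobis distance of each clip's raw index vector from the
#' table mean under the sample covariance, computed over all clips (outliers
#' included, deliberately unrobust). Clips with squared distance above the
#' threshold are flagged for removal; the threshold of 12 captures the bulk
#' of malfunctioning recordings. The distance is invariant to any affine
#' rescaling of individual index columns, so it is identical on raw and
#' min-max scaled indices.
#'
#' @param df Data frame of index values.
#' @param cols Index columns (default the five indices).
#' @param threshold Squared-distance cut-off (default 12).
#' @return `df` with added `mahalanobis_sq` and `mahal_ok` columns.
#' @export
mahalanobis_screen <- function(df, cols = c("aci", "adi", "bi", "h", "np"),
                               threshold = 12) {
  x <- as.matrix(df[, cols])
  if (nrow(x) < length(cols) + 1L) {
    stop("mahalanobis_screen: need at least ", length(cols) + 1L, " clips")
  }
  S <- stats::cov(x)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < max(ev) * 1e-12) {
    sds <- apply(x, 2, stats::sd)
    cors <- stats::cor(x[, sds > 0, drop = FALSE])
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    stop("mahalanobis_screen: singular index covariance; near-collinear ",
         "columns include ", paste(colnames(cors)[worst], collapse = " ~ "),
         if (any(sds == 0)) paste0("; constant column(s): ",
                                   paste(cols[sds == 0], collapse = ", "))
         else "")
  }
  df$mahalanobis_sq <- stats::mahalanobis(x, colMeans(x), S)
  df$mahal_ok <- df$mahalanobis_sq <= threshold
  df
}

#' Full QC screen: rain classification then distance screening
#'
#' @param index_df Data frame with the five raw index columns and `clip_id`.
#' @param rain_metrics_df Data frame of [rain_metrics()] rows aligned with
#'   `index_df` (or NULL to skip rain screening).
#' @param thresholds `rain_thresholds` (required when `rain_metrics_df`
#'   given).
#' @param mahal_threshold Squared Mahalanobis cut-off (default 12).
#' @return A `qc_report`: `records` (per clip: rain metrics, `rain_flag`,
#'   `mahalanobis_sq`, `qc_label`, `retained`) and `summary` (counts and
#'   retention percentage).
#' @export
qc_screen <- function(index_df, rain_metrics_df = NULL, thresholds = NULL,
                      mahal_threshold = 12) {
  rain_flag <- if (!is.null(rain_metrics_df)) {
    if (is.null(thresholds)) stop("qc_screen: rain thresholds required")
    classify_rain(rain_metrics_df, thresholds)
  } else rep(FALSE, nrow(index_df))
  scr <- mahalanobis_screen(index_df, threshold = mahal_threshold)
  records <- data.frame(
    clip_id = index_df$clip_id,
    rain_flag = rain_flag,
    mahalanobis_sq = scr$mahalanobis_sq,
    qc_label = ifelse(!scr$mahal_ok, "problematic",
                      ifelse(rain_flag, "intermediate", "normal")),
    retained = !rain_flag & scr$mahal_ok,
    stringsAsFactors = FALSE
  )
  if (!is.null(rain_metrics_df)) records <- cbind(records, rain_metrics_df)
  n <- nrow(records)
  res <- list(records = records,
              summary = list(n_total = n,
                             n_rain = sum(records$rain_flag),
                             n_mahal = sum(!scr$mahal_ok),
                             n_retained = sum(records$retained),
                             retention = sum(records$retained) / n))
  class(res) <- "qc_report"
  res
}

#' @export
print.qc_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "QC screen: %d clips; %d rain-flagged, %d over distance threshold; %d (%.1f%%) retained\n",
    s$n_total, s$n_rain, s$n_mahal, s$n_retained, 100 * s$retention))
  invisible(x)
}
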