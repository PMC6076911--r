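#' Analysis frequency bands
#'
#' Ordered band table used for per-band decomposition.  Defaults are the
#' five classical resting-EEG bands: delta 0.5-3.5 Hz, theta 3.5-7.5 Hz,
#' alpha 7.5-12.5 Hz, beta 12.5-30 Hz, gamma 30-45 Hz.
#'
#' @param band character band names
#' @param low,high band edges (Hz), strictly increasing within each band
#' @return data.frame with columns `band`, `low`, `high`
#' @export
band_table <- function(band = c("delta", "theta", "alpha", "beta", "gamma"),
                       low = c(0.5, 3.5, 7.5, 12.5, 30),
                       high = c(3.5, 7.5, 12.5, 30, 45)) {
  stopifnot(length(band) == length(low), length(low) == length(high))
  if (any(high <= low))
    stop("band_table: band edges must be strictly increasing", call. = FALSE)
  if (is.unsorted(low))
    stop("band_table: bands must be ordered by low edge", call. = FALSE)
  data.frame(band = band, low = low, high = high, stringsAsFactors = FALSE)
}

apply_filtfilt <- function(rec, filt, stage) {
  out <- rec
  out$data <- t(apply(rec$data, 1, function(ch) signal::filtfilt(filt, ch)))
  rownames(out$data) <- rec$labels
  check_finite(out, stage)
}

#' Decimate a recording to a lower sampling rate
#'
#' Applies a zero-phase anti-alias low-pass (cutoff 80% of the new Nyquist)
#' and keeps every k-th sample, where k is the (integer) ratio of old to
#' new rate.
#'
#' @param rec an [eeg_recording()]
#' @param target_rate new sampling rate (Hz); must divide `rec$rate` evenly
#' @return the decimated [eeg_recording()]
#' @export
decimate <- function(rec, target_rate) {
  factor <- rec$rate / target_rate
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("decimate: unsupported rate ", target_rate,
         " (must divide ", rec$rate, " evenly)", call. = FALSE)
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  aa <- signal::butter(8, 0.8 / factor, type = "low")
  out <- apply_filtfilt(rec, aa, "decimate")
  out$data <- out$data[, seq(1L, n_samples(rec), by = factor), drop = FALSE]
  out$rate <- target_rate
  out
}

#' Notch-filter power-line interference
#'
#' Zero-phase band-stop filter centred on `freq` (default 50 Hz).
#'
#' @param rec an [eeg_recording()]
#' @param freq centre frequency (Hz), below Nyquist
#' @param bandwidth full stop-band width (Hz)
#' @return the filtered [eeg_recording()]
#' @export
notch <- function(rec, freq = 50, bandwidth = 4) {
  nyq <- rec$rate / 2
  if (freq <= 0 || freq >= nyq)
    stop("notch: invalid frequency ", freq, " Hz (Nyquist ", nyq, " Hz)",
         call. = FALSE)
  edges <- c(freq - bandwidth / 2, freq + bandwidth / 2) / nyq
  filt <- signal::butter(2, edges, type = "stop")
  apply_filtfilt(rec, filt, "notch")
}

#' Band-pass filter a recording
#'
#' Zero-phase band-pass implemented as a high-pass / low-pass cascade
#' (better conditioned near DC than a single band-pass design).  Elliptic
#' responses (0.2 dB ripple, 40 dB stop band), applied forward-backward,
#' give a near-flat pass band, sharp transitions (so adjacent analysis
#' bands tile the spectrum with little crossover loss) and far more than
#' 20 dB attenuation one octave outside the edges.
#'
#' @param rec an [eeg_recording()]
#' @param low,high band edges (Hz), `0 < low < high < ` Nyquist
#' @return the filtered [eeg_recording()]
#' @export
bandpass <- function(rec, low, high) {
  nyq <- rec$rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("bandpass: invalid frequencies [", low, ", ", high,
         "] Hz (Nyquist ", nyq, " Hz)", call. = FALSE)
  hp <- signal::ellip(5, 0.2, 40, low / nyq, type = "high")
  lp <- signal::ellip(5, 0.2, 40, high / nyq, type = "low")
  out <- apply_filtfilt(rec, hp, "bandpass")
  apply_filtfilt(out, lp, "bandpass")
}

#' Re-reference to the mean of two channels
#'
#' Subtracts the mean of the two named reference channels (typically the
#' bilateral mastoids) from every channel and records the new reference.
#'
#' @param rec an [eeg_recording()]
#' @param ref_labels two channel names
#' @return the re-referenced [eeg_recording()]
#' @export
rereference <- function(rec, ref_labels = c("56", "107")) {
  stopifnot(length(ref_labels) == 2)
  idx <- match(ref_labels, rec$labels)
  if (anyNA(idx))
    stop("rereference: unknown channel(s): ",
         paste(ref_labels[is.na(idx)], collapse = ", "), call. = FALSE)
  ref <- colMeans(rec$data[idx, , drop = FALSE])
  out <- rec
  out$data <- sweep(rec$data, 2, ref)
  out$reference <- paste0("mean(", paste(ref_labels, collapse = ","), ")")
  check_finite(out, "rereference")
}

#' Exclude channels by label
#'
#' Drops the named channels, preserving the order of the remaining ones.
#' The default list is the nine electrodes contaminated by eye movement or
#' noise in a 128-channel dense-array montage.
#'
#' @param rec an [eeg_recording()]
#' @param labels channel names to drop
#' @return the reduced [eeg_recording()]
#' @export
exclude_channels <- function(rec,
                             labels = c("8", "14", "17", "21", "25",
                                        "125", "126", "127", "128")) {
  if (length(labels) == 0) return(rec)
  idx <- match(labels, rec$labels)
  if (anyNA(idx))
    stop("exclude_channels: unknown channel(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  keep <- setdiff(seq_len(n_channels(rec)), idx)
  if (length(keep) == 0)
    stop("exclude_channels: excluding all channels leaves an empty recording",
         call. = FALSE)
  out <- rec
  out$data <- rec$data[keep, , drop = FALSE]
  out$labels <- rec$labels[keep]
  out
}

#' Decompose a recording into frequency bands
#'
#' Band-pass filters the recording once per row of the band table.
#'
#' @param rec an [eeg_recording()]
#' @param bands a [band_table()]
#' @return named list of [eeg_recording()] objects, one per band
#' @export
band_decompose <- function(rec, bands = band_table()) {
  out <- lapply(seq_len(nrow(bands)), function(i)
    bandpass(rec, bands$low[i], bands$high[i]))
  names(out) <- bands$band
  out
}

#' Preprocessing configuration
#'
#' Settings for [preprocess_recording()].  Defaults follow the standard
#' dense-array resting-EEG chain: decimate to 250 Hz, 50 Hz notch,
#' 0.5-80 Hz broadband filter, re-reference to the bilateral mastoid
#' electrodes 56/107 after dropping the online reference channel, exclude
#' nine noisy electrodes, then decompose into five bands.
#'
#' @param target_rate decimation target (Hz); `NULL` skips decimation
#' @param notch_freq,notch_bw notch centre / width (Hz); `NULL` freq skips
#' @param broadband length-2 band-pass edges (Hz); `NULL` skips
#' @param reference_pair two channel labels for re-referencing; `NULL` skips
#' @param drop_online_reference drop the online-reference channel (by
#'   `online_reference_label`) before re-referencing, if present
#' @param online_reference_label label of the online reference channel
#' @param exclusion channel labels to exclude; `NULL` skips
#' @param bands a [band_table()]; `NULL` skips band decomposition
#' @param artifact_hook optional function `eeg_recording -> eeg_recording`
#'   applied after channel exclusion (stand-in stage for artifact rejection
#'   / component denoising, which are interactive and out of scope)
#' @return config list
#' @export
preprocess_config <- function(target_rate = 250, notch_freq = 50,
                              notch_bw = 4, broadband = c(0.5, 80),
                              reference_pair = c("56", "107"),
                              drop_online_reference = TRUE,
                              online_reference_label = "CZ",
                              exclusion = c("8", "14", "17", "21", "25",
                                            "125", "126", "127", "128"),
                              bands = band_table(),
                              artifact_hook = NULL) {
  list(target_rate = target_rate, notch_freq = notch_freq,
       notch_bw = notch_bw, broadband = broadband,
       reference_pair = reference_pair,
       drop_online_reference = drop_online_reference,
       online_reference_label = online_reference_label,
       exclusion = exclusion, bands = bands, artifact_hook = artifact_hook)
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: decimate, notch, broadband band-pass, drop online
#' reference, re-reference, exclude channels, artifact hook, band
#' decomposition.  Any stage can be skipped via its config entry.
#'
#' @param rec an [eeg_recording()]
#' @param config a [preprocess_config()]
#' @return list with `broadband` (the preprocessed [eeg_recording()]) and
#'   `bands` (named list of band-filtered recordings, or `NULL`)
#' @export
preprocess_recording <- function(rec, config = preprocess_config()) {
  if (!is.null(config$target_rate))
    rec <- decimate(rec, config$target_rate)
  if (!is.null(config$notch_freq))
    rec <- notch(rec, config$notch_freq, config$notch_bw)
  if (!is.null(config$broadband))
    rec <- bandpass(rec, config$broadband[1], config$broadband[2])
  if (isTRUE(config$drop_online_reference) &&
      config$online_reference_label %in% rec$labels)
    rec <- exclude_channels(rec, config$online_reference_label)
  if (!is.null(config$reference_pair))
    rec <- rereference(rec, config$reference_pair)
  if (!is.null(config$exclusion) && length(config$exclusion))
    rec <- exclude_channels(rec, config$exclusion)
  if (!is.null(config$artifact_hook))
    rec <- config$artifact_hook(rec)
  bands <- if (!is.null(config$bands)) band_decompose(rec, config$bands)
  list(broadband = rec, bands = bands)
}
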