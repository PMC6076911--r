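# Shared fixture builders (all generated in code; no stored data).

# Pure tone recording: channels x samples, every channel the same sinusoid.
tone_recording <- function(freq, rate = 250, dur = 4, n_ch = 2, amp = 1) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  x <- amp * sin(2 * pi * freq * t)
  eeg_recording(matrix(rep(x, each = n_ch), n_ch), rate = rate)
}

white_recording <- function(rate = 250, dur = 8, n_ch = 1, seed = 1) {
  withr::with_seed(seed,
    eeg_recording(matrix(rnorm(n_ch * rate * dur), n_ch), rate = rate))
}

rms <- function(x) sqrt(mean(x^2))

# RMS of the central part of a channel (discards filter edge transients).
mid_rms <- function(rec, ch = 1, trim = 0.2) {
  n <- ncol(rec$data)
  i <- seq(floor(n * trim), ceiling(n * (1 - trim)))
  rms(rec$data[ch, i])
}

# Band power via periodogram, summed over [lo, hi) Hz.
band_power <- function(x, rate, lo, hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = rate), plot = FALSE,
                          taper = 0, detrend = FALSE)
  sum(sp$spec[sp$freq >= lo & sp$freq < hi])
}

# Small recovery-style DCM with separable per-source inputs.
recovery_model <- function(n_sources = 3, n_channels = 16, seed = 101,
                           response_time = 100, estimate = "lateral") {
  L <- make_lead_field(n_channels, n_sources, seed = seed)
  dcm_model(L, estimate = estimate, response_time = response_time,
            input_sources = seq_len(n_sources),
            input_spec = list(onset = 10 + 25 * (seq_len(n_sources) - 1),
                              sd = 6, amplitude = 100))
}

# 1-parameter linear-Gaussian observation model with conjugate closed form.
conjugate_fixture <- function(N = 40, s0 = 0.5, sig2 = 0.2, theta = 0.7,
                              seed = 1) {
  withr::with_seed(seed, {
    j <- rnorm(N)
    y <- j * theta + rnorm(N, sd = sqrt(sig2))
  })
  list(model = list(predict = function(th) j * th[1], n_params = 1L,
                    priors = list(mean = 0, variance = s0)),
       j = j, y = y, s0 = s0, sig2 = sig2,
       post_var = 1 / (sum(j^2) / sig2 + 1 / s0),
       post_mean = sum(j * y) / sig2 / (sum(j^2) / sig2 + 1 / s0))
}
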