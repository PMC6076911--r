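#' Synthetic cohort configuration
#'
#' Settings for [generate_cohort()].  Defaults emulate a dense-array
#' resting-EEG study: two groups of 14 subjects, 128 channels, 1000 Hz,
#' about 5 minutes per recording.
#'
#' @param n_per_group subjects per group (>= 1)
#' @param n_channels sensor count
#' @param acq_rate acquisition sampling rate (Hz)
#' @param duration recording length (s)
#' @param n_sources number of neural-mass sources
#' @param group_effect numeric vector, one entry per source: additive shift
#'   (log-gain units) applied to the lateral couplings *into* that source,
#'   patient group only.  Default all zero (null cohort).
#' @param noise_sd sensor white-noise standard deviation (same units as the
#'   projected source signal)
#' @param seed integer seed; the whole cohort is deterministic given it
#' @param deviation_sd spread of the shared ground-truth log-gain deviations
#' @param jitter_sd per-subject Gaussian jitter on the log-gain deviations
#' @param input_sources indices of the sources driven by the exogenous
#'   input (default the two auditory-cortex regions, rows 1-2 of the ROI
#'   table)
#' @param input_amplitude amplitude of the stochastic drive (a.u.)
#' @param input_cutoff low-pass cutoff (Hz) of the smooth stochastic drive
#' @param base_lateral total lateral coupling gain per source at the prior
#'   (split evenly over the `n_sources - 1` incoming edges)
#' @param lead_field optional channels-by-sources matrix; default a seeded
#'   random Gaussian matrix with unit-norm columns
#' @param params a [neural_mass_params()] object
#' @param dt integration step (ms)
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_per_group = 14, n_channels = 128,
                          acq_rate = 1000, duration = 300,
                          n_sources = 16, group_effect = NULL,
                          noise_sd = 0.01, seed = 1,
                          deviation_sd = 0.3, jitter_sd = 0.1,
                          input_sources = c(1, 2),
                          input_amplitude = 150, input_cutoff = 30,
                          base_lateral = 32, lead_field = NULL,
                          params = neural_mass_params(), dt = 1) {
  if (n_per_group < 1 || acq_rate <= 0 || duration <= 0 || noise_sd < 0)
    stop("cohort_config: need n_per_group >= 1, acq_rate > 0, duration > 0, ",
         "noise_sd >= 0", call. = FALSE)
  if (is.null(group_effect)) group_effect <- rep(0, n_sources)
  if (length(group_effect) != n_sources)
    stop("cohort_config: group_effect must have one entry per source",
         call. = FALSE)
  if (any(input_sources < 1 | input_sources > n_sources))
    stop("cohort_config: input_sources out of range", call. = FALSE)
  structure(list(n_per_group = n_per_group, n_channels = n_channels,
                 acq_rate = acq_rate, duration = duration,
                 n_sources = n_sources, group_effect = group_effect,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 deviation_sd = deviation_sd, jitter_sd = jitter_sd,
                 input_sources = input_sources,
                 input_amplitude = input_amplitude,
                 input_cutoff = input_cutoff,
                 base_lateral = base_lateral, lead_field = lead_field,
                 params = params, dt = dt),
            class = "cohort_config")
}

#' Random synthetic lead field
#'
#' Seeded Gaussian channels-by-sources mixing matrix with unit-norm
#' columns; full column rank with probability one (requires at least as
#' many channels as sources).
#'
#' @param n_channels,n_sources dimensions
#' @param seed integer seed
#' @return `n_channels x n_sources` matrix
#' @export
make_lead_field <- function(n_channels, n_sources, seed = 1) {
  stopifnot(n_channels >= n_sources)
  L <- withr::with_seed(seed,
    matrix(stats::rnorm(n_channels * n_sources), n_channels, n_sources))
  sweep(L, 2, sqrt(colSums(L^2)), "/")
}

# Lateral prior-gain matrix: total incoming gain split over the n-1 edges.
lateral_base_matrix <- function(n_sources, total_gain) {
  m <- matrix(total_gain / (n_sources - 1), n_sources, n_sources)
  diag(m) <- 0
  m
}

# Smooth stochastic drive: white Gaussian noise through a one-pole low-pass
# at `cutoff` Hz, rescaled to the requested RMS amplitude.
smooth_noise_input <- function(n_steps, dt, amplitude, cutoff) {
  w <- stats::rnorm(n_steps + 1)
  alpha <- exp(-2 * pi * cutoff * dt / 1000)
  x <- as.numeric(stats::filter(w, alpha, method = "recursive"))
  x <- x - mean(x)
  x * amplitude / stats::sd(x)
}

# Simulate one subject's sensor recording from its effective connectivity.
simulate_subject <- function(config, gt, deviations, sub_seed) {
  n <- config$n_sources
  dt <- config$dt
  sample_every <- round(1000 / (config$acq_rate * dt))
  if (abs(sample_every - 1000 / (config$acq_rate * dt)) > 1e-9)
    stop("cohort: acq_rate must be an integer division of the 1 kHz ",
         "integration grid", call. = FALSE)
  n_samp <- floor(config$duration * config$acq_rate)
  n_steps <- n_samp * sample_every
  AL <- gt$base_lateral_matrix * exp(deviations)
  diag(AL) <- 0
  n_u <- length(config$input_sources)
  Cmat <- matrix(0, n, n_u)
  Cmat[cbind(config$input_sources, seq_len(n_u))] <- 1
  conn <- extrinsic_connectivity(n, lateral = AL, input_gain = Cmat)
  withr::with_seed(sub_seed, {
    # independent smooth drive per input source
    u <- t(vapply(seq_len(n_u), function(j)
      smooth_noise_input(n_steps, dt, config$input_amplitude,
                         config$input_cutoff),
      numeric(n_steps + 1)))
    noise <- matrix(stats::rnorm(config$n_channels * n_samp,
                                 sd = config$noise_sd),
                    config$n_channels, n_samp)
  })
  u <- adapt_input(u, dt, config$params)
  x0 <- integrate_neural_mass(config$params, conn, u, dt = dt,
                              sample_every = sample_every)
  y <- gt$lead_field %*% x0 + noise
  eeg_recording(y, rate = config$acq_rate)
}

#' Generate a seeded synthetic two-group EEG cohort
#'
#' Builds a shared ground-truth signed connectivity (log-gain deviations on
#' all lateral couplings), then simulates every subject by integrating the
#' neural-mass network with per-subject jitter on the deviations, shifting
#' the couplings into the affected sources for the patient group, projecting
#' the pyramidal depolarizations through the lead field, and adding white
#' sensor noise.  Control and patient subject `j` share the same
#' subject-level random draws, so with zero noise and zero group effect the
#' paired recordings are identical.
#'
#' @param config a [cohort_config()]
#' @param out_dir if non-`NULL`, recordings are written as headered
#'   delimited text under this directory instead of being kept in memory
#'   (the returned `recording` entries then hold file paths)
#' @return list with `subjects` (list of `list(id, group, recording)`)
#'   and `ground_truth` (list: `true_gains` source-by-source signed
#'   deviations, zero diagonal; `input_sources`; `lead_field`;
#'   `base_lateral_matrix`; `group_effect`; `seed`)
#' @export
generate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_sources
  gt <- withr::with_seed(config$seed, {
    dev <- matrix(stats::rnorm(n * n, sd = config$deviation_sd), n, n)
    diag(dev) <- 0
    lf <- if (is.null(config$lead_field))
      make_lead_field(config$n_channels, n,
                      seed = stats::runif(1, 1, 2^30))
    else config$lead_field
    list(true_gains = dev, input_sources = config$input_sources,
         lead_field = lf,
         base_lateral_matrix = lateral_base_matrix(n, config$base_lateral),
         group_effect = config$group_effect, seed = config$seed)
  })
  if (qr(gt$lead_field)$rank < n)
    stop("generate_cohort: lead field must have full column rank",
         call. = FALSE)
  effect_shift <- matrix(rep(config$group_effect, each = n), n, n)
  effect_shift <- t(effect_shift)   # shift edges *into* affected sources
  diag(effect_shift) <- 0
  sub_seeds <- withr::with_seed(config$seed + 1L,
                                sample.int(2^30, config$n_per_group))
  jitters <- withr::with_seed(config$seed + 2L,
    lapply(seq_len(config$n_per_group), function(j) {
      m <- matrix(stats::rnorm(n * n, sd = config$jitter_sd), n, n)
      diag(m) <- 0
      m
    }))
  subjects <- list()
  for (j in seq_len(config$n_per_group)) {
    for (grp in c("control", "patient")) {
      devs <- gt$true_gains + jitters[[j]] +
        if (grp == "patient") effect_shift else 0
      rec <- simulate_subject(config, gt, devs, sub_seeds[j])
      id <- sprintf("%s_%02d", grp, j)
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, paste0(id, ".tsv"))
        write_recording_txt(rec, path)
        rec <- path
      }
      subjects[[id]] <- list(id = id, group = grp, recording = rec)
    }
  }
  res <- list(subjects = subjects, ground_truth = gt)
  if (!is.null(out_dir)) write_ground_truth(gt, out_dir)
  res
}

#' Write cohort ground truth to disk
#'
#' The signed deviation matrix as a labelled delimited matrix plus a JSON
#' sidecar with the input sources, seed and group effect.
#'
#' @param gt the `ground_truth` element of a [generate_cohort()] result
#' @param dir output directory
#' @export
write_ground_truth <- function(gt, dir) {
  write_signed_network(signed_network(gt$true_gains),
                       file.path(dir, "ground_truth_gains.tsv"))
  utils::write.table(gt$lead_field, file.path(dir, "lead_field.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(input_sources = gt$input_sources, seed = gt$seed,
         group_effect = gt$group_effect),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate noisy replicate data windows from a DCM
#'
#' Generates `n_windows` copies of the model's predicted sensor window at
#' the given true parameters, each with fresh white sensor noise at the
#' requested signal-to-noise ratio.  Used for parameter-recovery studies:
#' inverting the averaged windows should recover `theta_true`.
#'
#' @param model a [dcm_model()]
#' @param theta_true true parameter vector (log-gain deviations)
#' @param n_windows number of replicate windows
#' @param snr_db per-window sensor signal-to-noise ratio (dB)
#' @param seed integer seed
#' @return list of channels-by-samples window matrices; the noise-free
#'   prediction is attached as attribute `"clean"`
#' @export
simulate_recovery_windows <- function(model, theta_true, n_windows = 20,
                                      snr_db = 10, seed = 1) {
  clean <- predict_sensor(model, theta_true)
  noise_sd <- sqrt(mean(clean^2)) * 10^(-snr_db / 20)
  wins <- withr::with_seed(seed, lapply(seq_len(n_windows), function(i)
    clean + matrix(stats::rnorm(length(clean), sd = noise_sd),
                   nrow(clean), ncol(clean))))
  attr(wins, "clean") <- clean
  wins
}

#' Generate a random signed weighted network
#'
#' Off-diagonal entries are nonzero with probability `density`; nonzero
#' weights are drawn from a zero-mean Gaussian so both signs occur.
#'
#' @param n node count (>= 2)
#' @param density fraction of nonzero off-diagonal entries, in (0, 1]
#' @param weight_sd Gaussian weight scale
#' @param seed integer seed
#' @return a [signed_network()]
#' @export
generate_signed_network <- function(n, density = 1, weight_sd = 0.5,
                                    seed = 1) {
  if (n < 2) stop("generate_signed_network: need n >= 2", call. = FALSE)
  if (density <= 0 || density > 1)
    stop("generate_signed_network: density must be in (0, 1]", call. = FALSE)
  A <- withr::with_seed(seed, {
    mask <- matrix(stats::runif(n * n) < density, n, n)
    w <- matrix(stats::rnorm(n * n, sd = weight_sd), n, n)
    mask * w
  })
  diag(A) <- 0
  signed_network(A)
}
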