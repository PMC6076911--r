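#' Region-of-interest table
#'
#' Reads a tab-delimited ROI table (columns `name`, `x`, `y`, `z`).  The
#' bundled default is the 16-region auditory resting-state network set
#' (bilateral superior/transverse temporal gyri, bilateral
#' cuneus/precuneus, middle occipital, precentral, superior frontal,
#' prefrontal, superior parietal, basal ganglia/NAc, isthmus of cingulate,
#' bilateral thalamus, brainstem, bilateral parahippocampal gyri).
#'
#' @param path optional path to a custom table; default the bundled table
#' @return data.frame with columns `name`, `x`, `y`, `z`
#' @export
roi_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "roi_table.tsv", package = "dcmrank")
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           quote = "", comment.char = "")
  stopifnot(all(c("name", "x", "y", "z") %in% names(tab)))
  tab
}

#' Prior set for DCM parameters
#'
#' Estimated parameters are log-scale multipliers of their prior gains, so
#' the prior mean is 0 (multiplicative gain 1) everywhere.  A zero prior
#' variance freezes a parameter at its prior mean.
#'
#' @param n_params number of parameters
#' @param variance scalar or per-parameter prior variance on the log scale
#' @return list with `mean` and `variance` vectors
#' @export
prior_set <- function(n_params, variance = 1 / 16) {
  v <- rep_len(variance, n_params)
  if (any(v < 0)) stop("prior_set: negative prior variance", call. = FALSE)
  list(mean = rep(0, n_params), variance = v)
}

#' Specify a DCM for multichannel EEG windows
#'
#' A generative model: a network of neural-mass sources with (by default)
#' lateral extrinsic connections between all ROI pairs, driven by a
#' deterministic input bump, observed through a lead field.  Estimated
#' parameters are log-gain deviations from the prior on the lateral
#' couplings, the input gains and the per-source sensor contribution
#' gains K (selectable via `estimate`); intrinsic synaptic parameters stay
#' frozen at their priors.
#'
#' @param lead_field channels-by-sources matrix L
#' @param roi ROI table ([roi_table()] by default, truncated/checked
#'   against the lead-field column count)
#' @param response_time modeled window length (ms); typical settings are
#'   60, 100 or 2000
#' @param fs working sampling rate (Hz) of the data windows
#' @param input_sources source indices receiving the exogenous input
#' @param input_spec list with `onset`, `sd`, `amplitude`: a Gaussian input
#'   bump u(t) = amplitude * exp(-(t-onset)^2 / (2 sd^2)), t in ms
#' @param estimate character subset of `c("lateral", "input", "K")`
#' @param prior_variance prior variance of the log-gain deviations
#' @param base_lateral total lateral prior gain per source (split over
#'   incoming edges)
#' @param params a [neural_mass_params()] object
#' @param K0 prior sensor contribution gain per source
#' @param dt integration step (ms); `1000 / (fs * dt)` must be integer
#' @return object of class `dcm_model`
#' @export
dcm_model <- function(lead_field, roi = NULL, response_time = 60, fs = 250,
                      input_sources = c(1, 2),
                      input_spec = list(onset = 16, sd = 6, amplitude = 1),
                      estimate = c("lateral", "input", "K"),
                      prior_variance = 1 / 16, base_lateral = 32,
                      params = neural_mass_params(), K0 = 1, dt = 1) {
  lead_field <- as.matrix(lead_field)
  n <- ncol(lead_field)
  if (is.null(roi)) {
    roi <- roi_table()
    roi <- roi[seq_len(min(n, nrow(roi))), , drop = FALSE]
    if (nrow(roi) < n)
      roi <- data.frame(name = paste0("source", seq_len(n)),
                        x = 0, y = 0, z = 0)
  }
  if (nrow(roi) != n)
    stop("dcm_model: ROI table must have one row per lead-field column",
         call. = FALSE)
  if (response_time <= 0) stop("dcm_model: response_time must be positive",
                               call. = FALSE)
  sample_every <- 1000 / (fs * dt)
  if (abs(sample_every - round(sample_every)) > 1e-9)
    stop("dcm_model: 1000/(fs*dt) must be an integer", call. = FALSE)
  estimate <- match.arg(estimate, c("lateral", "input", "K"), several.ok = TRUE)
  edges <- expand.grid(from = seq_len(n), to = seq_len(n))
  edges <- edges[edges$from != edges$to, c("from", "to")]
  rownames(edges) <- NULL
  idx <- list()
  off <- 0L
  if ("lateral" %in% estimate) {
    idx$lateral <- off + seq_len(nrow(edges)); off <- off + nrow(edges)
  }
  if ("input" %in% estimate) {
    idx$input <- off + seq_along(input_sources)
    off <- off + length(input_sources)
  }
  if ("K" %in% estimate) {
    idx$K <- off + seq_len(n); off <- off + n
  }
  model <- list(lead_field = lead_field, roi = roi, n_sources = n,
                response_time = response_time, fs = fs,
                input_sources = input_sources, input_spec = input_spec,
                estimate = estimate, edges = edges, theta_index = idx,
                n_params = off, priors = prior_set(off, prior_variance),
                base_lateral = base_lateral,
                base_lateral_matrix = lateral_base_matrix(n, base_lateral),
                params = params, K0 = rep_len(K0, n), dt = dt,
                sample_every = as.integer(round(sample_every)))
  class(model) <- "dcm_model"
  model
}

# Expand a theta vector into effective lateral matrix, input gains and K.
theta_expand <- function(model, theta) {
  n <- model$n_sources
  AL <- model$base_lateral_matrix
  if (!is.null(model$theta_index$lateral)) {
    dev <- theta[model$theta_index$lateral]
    # receiver-row convention: AL[to, from]
    AL[cbind(model$edges$to, model$edges$from)] <-
      AL[cbind(model$edges$to, model$edges$from)] * exp(dev)
  }
  # one input channel per driven source
  n_u <- length(model$input_sources)
  Cmat <- matrix(0, n, n_u)
  gains <- if (!is.null(model$theta_index$input))
    exp(theta[model$theta_index$input]) else rep(1, n_u)
  Cmat[cbind(model$input_sources, seq_len(n_u))] <- gains
  K <- model$K0
  if (!is.null(model$theta_index$K))
    K <- model$K0 * exp(theta[model$theta_index$K])
  list(lateral = AL, input_gain = Cmat, K = K)
}

# Deterministic input bumps sampled on the integration grid: one row per
# driven source; onsets may differ per source (staggered activation makes
# incoming connections separable).
input_trajectory <- function(model, n_steps) {
  t_ms <- (0:n_steps) * model$dt
  s <- model$input_spec
  n_u <- length(model$input_sources)
  onset <- rep_len(s$onset, n_u)
  sd_ <- rep_len(s$sd, n_u)
  amp <- rep_len(s$amplitude, n_u)
  t(vapply(seq_len(n_u), function(j)
    amp[j] * exp(-(t_ms - onset[j])^2 / (2 * sd_[j]^2)),
    numeric(length(t_ms))))
}

#' Predict a sensor window from a DCM
#'
#' Integrates the neural-mass network with the coupling gains implied by
#' `theta` (log-scale deviations from the priors), extracts the pyramidal
#' depolarization x0 of every source and projects it through the
#' observation model `y = L diag(K) x0`.
#'
#' @param model a [dcm_model()]
#' @param theta parameter vector (length `model$n_params`); default the
#'   prior mean (all zeros, i.e. all multiplicative gains 1)
#' @return channels-by-samples predicted window (`response_time` ms at
#'   rate `fs`)
#' @export
predict_sensor <- function(model, theta = rep(0, model$n_params)) {
  if (length(theta) != model$n_params)
    stop("predict_sensor: theta must have length ", model$n_params,
         call. = FALSE)
  ops <- theta_expand(model, theta)
  n_samp <- round(model$response_time / 1000 * model$fs)
  n_steps <- n_samp * model$sample_every
  conn <- extrinsic_connectivity(model$n_sources, lateral = ops$lateral,
                                 input_gain = ops$input_gain)
  u <- input_trajectory(model, n_steps)
  x0 <- integrate_neural_mass(model$params, conn, u, dt = model$dt,
                              sample_every = model$sample_every)
  model$lead_field %*% (ops$K * x0)
}

#' Bilinear approximation of a state equation
#'
#' Central finite-difference linearization of `f(x, u)` around an
#' expansion point: `A = df/dx`, `C = df/du`, and one bilinear matrix
#' `B[[j]] = d^2 f / dx du_j` per input.  Exact (to rounding) for
#' functions linear in `x` and bilinear in `(x, u)`.
#'
#' @param f function of `(x, u)` returning the state derivative
#' @param x_ref,u_ref expansion point
#' @param step finite-difference step
#' @return list with matrices `A`, `C` and list `B`
#' @export
bilinear_approximation <- function(f, x_ref, u_ref, step = 1e-4) {
  nx <- length(x_ref)
  nu <- length(u_ref)
  jac_x <- function(u) {
    J <- matrix(0, nx, nx)
    for (i in seq_len(nx)) {
      e <- rep(0, nx); e[i] <- step
      J[, i] <- (f(x_ref + e, u) - f(x_ref - e, u)) / (2 * step)
    }
    J
  }
  A <- jac_x(u_ref)
  C <- matrix(0, nx, nu)
  for (j in seq_len(nu)) {
    e <- rep(0, nu); e[j] <- step
    C[, j] <- (f(x_ref, u_ref + e) - f(x_ref, u_ref - e)) / (2 * step)
  }
  B <- lapply(seq_len(nu), function(j) {
    e <- rep(0, nu); e[j] <- step
    (jac_x(u_ref + e) - jac_x(u_ref - e)) / (2 * step)
  })
  if (!all(is.finite(A)) || !all(is.finite(C)) ||
      !all(vapply(B, function(m) all(is.finite(m)), logical(1))))
    stop("bilinear_approximation: non-finite differences", call. = FALSE)
  list(A = A, B = B, C = C)
}

#' Derivative function of a neural-mass model
#'
#' Convenience closure `f(x, u)` over [network_derivative()], suitable for
#' [bilinear_approximation()].
#'
#' @param params a [neural_mass_params()]
#' @param conn an [extrinsic_connectivity()]
#' @param linear_gain identity-gain test hook
#' @return function of `(x, u)`
#' @export
nm_derivative_fn <- function(params, conn, linear_gain = FALSE) {
  function(x, u) network_derivative(x, u, params, conn,
                                    linear_gain = linear_gain)
}

#' Segment a recording into consecutive windows
#'
#' Non-overlapping windows of `response_time` ms; a trailing partial
#' window is dropped.
#'
#' @param rec an [eeg_recording()]
#' @param response_time window length (ms)
#' @return list of channels-by-samples matrices
#' @export
segment_windows <- function(rec, response_time) {
  w <- round(response_time / 1000 * rec$rate)
  n_win <- floor(n_samples(rec) / w)
  if (n_win < 1)
    stop("segment_windows: recording shorter than one window", call. = FALSE)
  lapply(seq_len(n_win), function(i)
    rec$data[, ((i - 1) * w + 1):(i * w), drop = FALSE])
}

#' Average a list of data windows
#'
#' @param windows list of equal-size matrices
#' @return their element-wise mean
#' @export
average_windows <- function(windows) {
  Reduce(`+`, windows) / length(windows)
}
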