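#' Neural-mass synaptic and gain parameters
#'
#' Container for the per-source constants of the neural-mass model: maximum
#' excitatory/inhibitory postsynaptic potentials, synaptic rate constants
#' (as time constants, ms), intrinsic coupling strengths (average synaptic
#' contact counts) and the sigmoid gain-function parameters.  Defaults are
#' the standard prior means used throughout the ERP neural-mass literature.
#'
#' @param H_e,H_i maximum excitatory / inhibitory postsynaptic potential (mV)
#' @param tau_e,tau_i excitatory / inhibitory lumped membrane time constants
#'   (ms); the rate constants are their reciprocals
#' @param tau_a adaptation time constant (ms) of the slow input pathway
#' @param gamma1,gamma2,gamma3,gamma4 intrinsic coupling strengths
#'   (dimensionless synaptic-contact counts)
#' @param gamma5 gain of the adaptation/input pathway (the fifth printed
#'   contact count); scales exogenous input after adaptation filtering
#' @param rho1,rho2 slope and offset of the population gain function
#' @return an object of class `neural_mass_params`
#' @export
neural_mass_params <- function(H_e = 4, H_i = 32, tau_e = 4, tau_i = 16,
                               tau_a = 512, gamma1 = 128, gamma2 = 128,
                               gamma3 = 64, gamma4 = 64, gamma5 = 16,
                               rho1 = 2, rho2 = 1) {
  p <- list(H_e = H_e, H_i = H_i, tau_e = tau_e, tau_i = tau_i, tau_a = tau_a,
            gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3, gamma4 = gamma4,
            gamma5 = gamma5, rho1 = rho1, rho2 = rho2)
  pos <- c("H_e", "H_i", "tau_e", "tau_i", "tau_a",
           "gamma1", "gamma2", "gamma3", "gamma4")
  bad <- pos[vapply(p[pos], function(v) !is.finite(v) || v <= 0, logical(1))]
  if (length(bad))
    stop("neural_mass_params: non-positive value for ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(p, class = "neural_mass_params")
}

#' Population firing-rate gain function
#'
#' Baseline-centred sigmoid mapping membrane potential to normalized mean
#' firing rate: `S(v) = 1/(1+exp(-rho1*(v-rho2))) - 1/(1+exp(rho1*rho2))`.
#' Centring makes `S(0) = 0`, so the all-zero state is an equilibrium of the
#' unforced network.
#'
#' @param v membrane potential (mV); vectorized
#' @param rho1 slope parameter
#' @param rho2 offset (position) parameter
#' @return firing rate(s), dimensionless, bounded
#' @export
firing_rate <- function(v, rho1 = 2, rho2 = 1) {
  stopifnot(is.numeric(v), all(is.finite(v)))
  1 / (1 + exp(-rho1 * (v - rho2))) - 1 / (1 + exp(rho1 * rho2))
}

#' Extrinsic connectivity of a neural-mass network
#'
#' The three source-by-source non-negative extrinsic gain matrices and the
#' input gain matrix.  Matrices use the receiver-row convention:
#' `forward[i, j]` is the gain of the forward connection from source `j`
#' onto source `i`.  Forward connections target the spiny stellate
#' subpopulation only, backward connections target the pyramidal and
#' inhibitory subpopulations, lateral connections target all three.
#'
#' @param n_sources number of sources
#' @param forward,backward,lateral `n x n` gain matrices (zero diagonal);
#'   defaults are all-zero
#' @param input_gain `n x n_inputs` matrix mapping exogenous inputs to
#'   sources (matrix C); default a single input driving no source
#' @return object of class `extrinsic_connectivity`
#' @export
extrinsic_connectivity <- function(n_sources,
                                   forward = NULL, backward = NULL,
                                   lateral = NULL, input_gain = NULL) {
  zero <- matrix(0, n_sources, n_sources)
  conn <- list(
    forward  = if (is.null(forward)) zero else as.matrix(forward),
    backward = if (is.null(backward)) zero else as.matrix(backward),
    lateral  = if (is.null(lateral)) zero else as.matrix(lateral),
    input_gain = if (is.null(input_gain)) matrix(0, n_sources, 1)
                 else as.matrix(input_gain)
  )
  for (nm in c("forward", "backward", "lateral")) {
    m <- conn[[nm]]
    if (!all(dim(m) == c(n_sources, n_sources)))
      stop("extrinsic_connectivity: ", nm, " must be ", n_sources, " x ",
           n_sources, call. = FALSE)
    if (any(diag(m) != 0))
      stop("extrinsic_connectivity: ", nm, " must have a zero diagonal",
           call. = FALSE)
  }
  if (nrow(conn$input_gain) != n_sources)
    stop("extrinsic_connectivity: input_gain must have ", n_sources, " rows",
         call. = FALSE)
  conn$n_sources <- n_sources
  structure(conn, class = "extrinsic_connectivity")
}

#' Time derivative of the neural-mass network state
#'
#' Assembles the state derivative of the coupled neural-mass network:
#' second-order synaptic kernel dynamics per subpopulation, intrinsic
#' couplings gamma1..gamma4, and extrinsic input arriving as mean firing
#' rates of the remote pyramidal populations through the forward, backward
#' and lateral gain matrices.
#'
#' @param state numeric vector of length `9 * n_sources` (source-major; the
#'   first state of each source block is the pyramidal depolarization x0)
#' @param u exogenous input values at this instant (length = number of input
#'   columns of `conn$input_gain`)
#' @param params a [neural_mass_params()] object
#' @param conn an [extrinsic_connectivity()] object
#' @param linear_gain replace the sigmoid by the identity (test hook that
#'   makes the network an exactly linear system)
#' @return the state derivative, same length as `state`
#' @export
network_derivative <- function(state, u, params, conn, linear_gain = FALSE) {
  n <- conn$n_sources
  if (length(state) != 9L * n)
    stop("network_derivative: state must have length ", 9L * n, call. = FALSE)
  if (length(u) != ncol(conn$input_gain))
    stop("network_derivative: u must have length ", ncol(conn$input_gain),
         call. = FALSE)
  drive <- as.numeric(conn$input_gain %*% u)
  # derivative is per second (tau in ms => rate constants 1000/tau 1/s)
  drop(.nm_deriv_cpp(state, drive, unclass(params), conn$forward,
                     conn$backward, conn$lateral, linear_gain))
}

#' Adaptation filtering of an exogenous input trajectory
#'
#' Passes the input through a first-order low-pass kernel with rate
#' `1/tau_a` and steady-state gain `gamma5`, modelling slow adaptation of
#' the subcortical drive before it reaches the spiny stellate population.
#'
#' @param u input trajectory: matrix `n_inputs x n_time` (or a vector for a
#'   single input) sampled every `dt` ms
#' @param dt sample interval (ms)
#' @param params a [neural_mass_params()] object supplying `tau_a`, `gamma5`
#' @return filtered trajectory, same shape as `u`
#' @export
adapt_input <- function(u, dt, params) {
  vec <- is.null(dim(u))
  um <- if (vec) matrix(u, nrow = 1) else u
  a <- matrix(0, nrow(um), ncol(um))
  decay <- exp(-dt / params$tau_a)
  g <- params$gamma5
  state <- rep(0, nrow(um))
  for (k in seq_len(ncol(um))) {
    state <- decay * state + (1 - decay) * g * um[, k]
    a[, k] <- state
  }
  if (vec) drop(a) else a
}

#' Integrate a neural-mass network
#'
#' Fixed-step 4th-order Runge-Kutta integration of [network_derivative()].
#' The input trajectory is given on the integration grid; midpoint values
#' are linearly interpolated.
#'
#' @param params a [neural_mass_params()] object
#' @param conn an [extrinsic_connectivity()] object
#' @param u input trajectory: `n_inputs x (n_steps + 1)` matrix (or vector
#'   for one input) sampled every `dt` ms; its length fixes the duration
#' @param dt integration step (ms), default 1
#' @param sample_every keep every k-th step in the output (1 = every step)
#' @param init initial state (default all zero, the unforced equilibrium)
#' @param linear_gain identity gain-function test hook (see
#'   [network_derivative()])
#' @param full_state return all `9 n` states (`TRUE`) or only the pyramidal
#'   depolarization x0 per source (`FALSE`, default)
#' @return matrix of trajectories, one row per source (or per state), one
#'   column per retained sample (the initial state is not included)
#' @export
integrate_neural_mass <- function(params, conn, u, dt = 1, sample_every = 1L,
                                  init = NULL, linear_gain = FALSE,
                                  full_state = FALSE) {
  stopifnot(dt > 0, sample_every >= 1)
  n <- conn$n_sources
  um <- if (is.null(dim(u))) matrix(u, nrow = 1) else u
  if (ncol(um) < 2)
    stop("integrate_neural_mass: u must cover at least one step",
         call. = FALSE)
  drive <- conn$input_gain %*% um
  if (is.null(init)) init <- rep(0, 9L * n)
  # dynamics run in seconds; dt is user-facing ms
  .nm_integrate_cpp(init, drive, unclass(params), conn$forward,
                    conn$backward, conn$lateral, dt / 1000,
                    as.integer(sample_every), linear_gain, full_state)
}

# Row indices of the x0 (pyramidal depolarization) states in a full-state
# trajectory with 9 states per source.
x0_indices <- function(n_sources) 9L * (seq_len(n_sources) - 1L) + 1L
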