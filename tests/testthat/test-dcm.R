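test_that("bilinear approximation is exact for linear and bilinear maps", {
  M <- matrix(c(-1, 0.5, 0, -2), 2, 2)
  N <- matrix(c(1, 3), 2, 1)
  f_lin <- function(x, u) M %*% x + N %*% u
  ops <- bilinear_approximation(f_lin, c(0.3, -0.2), 0.1)
  expect_equal(ops$A, M, tolerance = 1e-8)
  expect_equal(ops$C, N, tolerance = 1e-8)
  expect_equal(ops$B[[1]], matrix(0, 2, 2), tolerance = 1e-8)

  M1 <- matrix(c(0, 1, -1, 0), 2, 2)
  f_bil <- function(x, u) (M + u[1] * M1) %*% x
  ops2 <- bilinear_approximation(f_bil, c(0.2, 0.4), 0)
  expect_equal(ops2$B[[1]], M1, tolerance = 1e-6)
})

test_that("the numerical Jacobian matches the analytic one at baseline", {
  p <- neural_mass_params()
  conn <- extrinsic_connectivity(1, input_gain = matrix(1, 1, 1))
  f <- nm_derivative_fn(p, conn)
  A <- bilinear_approximation(f, rep(0, 9), 0)$A

  # hand-assembled Jacobian: second-order kernels plus sigmoid slope at 0
  ke <- 1000 / p$tau_e; ki <- 1000 / p$tau_i
  s1 <- p$rho1 * exp(-p$rho1 * (0 - p$rho2)) /
    (1 + exp(-p$rho1 * (0 - p$rho2)))^2
  Aref <- matrix(0, 9, 9)
  Aref[1, 6] <- 1; Aref[1, 7] <- -1                  # x0' = x5 - x6
  Aref[2, 5] <- 1                                     # x1' = x4
  Aref[5, 1] <- ke * p$H_e * p$gamma1 * s1            # gamma1 S(x0)
  Aref[5, 2] <- -ke^2; Aref[5, 5] <- -2 * ke
  Aref[3, 6] <- 1                                     # x2' = x5
  Aref[6, 2] <- ke * p$H_e * p$gamma2 * s1            # gamma2 S(x1)
  Aref[6, 3] <- -ke^2; Aref[6, 6] <- -2 * ke
  Aref[4, 7] <- 1                                     # x3' = x6
  Aref[7, 8] <- ki * p$H_i * p$gamma4 * s1            # gamma4 S(x7)
  Aref[7, 4] <- -ki^2; Aref[7, 7] <- -2 * ki
  Aref[8, 9] <- 1                                     # x7' = x8
  Aref[9, 1] <- ke * p$H_e * p$gamma3 * s1            # gamma3 S(x0)
  Aref[9, 8] <- -ke^2; Aref[9, 9] <- -2 * ke
  expect_equal(A, Aref, tolerance = 1e-4 * max(abs(Aref)))
})

test_that("the bilinear reduction reproduces small-signal dynamics", {
  p <- neural_mass_params()
  lat <- matrix(c(0, 4, 4, 0), 2, 2)
  conn <- extrinsic_connectivity(2, lateral = lat,
                                 input_gain = matrix(c(1, 0), 2, 1))
  f <- nm_derivative_fn(p, conn)
  ops <- bilinear_approximation(f, rep(0, 18), 0)
  u <- 0.5 * sin(2 * pi * 10 * (0:300) / 1000)   # small 10 Hz drive
  # reference: full nonlinear integration
  x_nl <- integrate_neural_mass(p, conn, u, full_state = TRUE)
  # bilinear system integrated with the same fixed-step RK4 (in seconds)
  h <- 1e-3
  fb <- function(x, uu) ops$A %*% x + uu * (ops$B[[1]] %*% x) + ops$C * uu
  x <- rep(0, 18)
  x_bl <- matrix(0, 18, 300)
  for (s in 1:300) {
    um <- (u[s] + u[s + 1]) / 2
    k1 <- fb(x, u[s]); k2 <- fb(x + h / 2 * k1, um)
    k3 <- fb(x + h / 2 * k2, um); k4 <- fb(x + h * k3, u[s + 1])
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    x_bl[, s] <- x
  }
  rel <- sqrt(sum((x_nl - x_bl)^2)) / sqrt(sum(x_nl^2))
  expect_lt(rel, 0.05)
})

test_that("sensor prediction is the lead-field mixture of x0", {
  # identity lead field, K = 1, one source: prediction equals x0
  m1 <- dcm_model(matrix(1, 1, 1), response_time = 100, input_sources = 1,
                  estimate = "lateral",
                  input_spec = list(onset = 20, sd = 6, amplitude = 50))
  h <- predict_sensor(m1)
  conn <- extrinsic_connectivity(1, input_gain = matrix(1, 1, 1))
  u <- dcmrank:::input_trajectory(m1, 100)
  x0 <- integrate_neural_mass(m1$params, conn, u, sample_every = 4)
  expect_equal(as.numeric(h), as.numeric(x0), tolerance = 1e-12)

  # theta at the prior mean reproduces the prior-model simulation
  m3 <- recovery_model()
  expect_equal(predict_sensor(m3), predict_sensor(m3, rep(0, m3$n_params)))

  # doubling K doubles a single source's additive contribution
  mk <- dcm_model(make_lead_field(5, 1, seed = 2), response_time = 60,
                  input_sources = 1, estimate = "K",
                  input_spec = list(onset = 10, sd = 5, amplitude = 50))
  h1 <- predict_sensor(mk, 0)
  h2 <- predict_sensor(mk, log(2))
  expect_equal(h2, 2 * h1, tolerance = 1e-10)
})

test_that("free energy behaves like an evidence bound", {
  fix <- conjugate_fixture()
  m <- fix$model
  # q = prior: KL term is zero, F equals the expected log-likelihood
  Sig <- matrix(fix$s0, 1, 1)
  J <- matrix(fix$j, ncol = 1)
  F0 <- free_energy(m, matrix(fix$y, 1), 0, Sig, fix$sig2, J)
  r <- fix$y
  elik <- -length(r) / 2 * log(2 * pi * fix$sig2) -
    (sum(r^2) + sum((J %*% Sig) * J)) / (2 * fix$sig2)
  expect_equal(F0, elik, tolerance = 1e-10)

  # corrupting the data lowers F, all else equal
  F_bad <- free_energy(m, matrix(fix$y + 3, 1), 0, Sig, fix$sig2, J)
  expect_lt(F_bad, F0)
})

test_that("inversion reproduces the conjugate-Gaussian posterior", {
  fix <- conjugate_fixture()
  post <- invert_dcm(fix$model, matrix(fix$y, 1), update_noise = FALSE,
                     sigma2_init = fix$sig2)
  expect_equal(post$mu_theta[1], fix$post_mean, tolerance = 1e-6)
  expect_equal(post$Sigma_theta[1, 1], fix$post_var, tolerance = 1e-6)
  expect_true(all(diff(post$trace) > -1e-3))
  # information gain: posterior variance below the prior variance
  expect_lt(post$Sigma_theta[1, 1], fix$s0)
  # at the optimum F equals the closed-form log evidence
  N <- length(fix$y)
  Cov <- fix$sig2 * diag(N) + fix$s0 * tcrossprod(fix$j)
  logev <- -0.5 * (N * log(2 * pi) +
                   as.numeric(determinant(Cov)$modulus) +
                   drop(t(fix$y) %*% solve(Cov, fix$y)))
  expect_equal(post$F, logev, tolerance = 1e-6)
})

test_that("self-consistent data keeps the posterior near the prior", {
  m <- recovery_model(n_sources = 2, n_channels = 6, seed = 31)
  clean <- predict_sensor(m, rep(0, m$n_params))
  noisy <- clean + withr::with_seed(4,
    matrix(rnorm(length(clean), sd = 1e-6 * rms(clean)),
           nrow(clean), ncol(clean)))
  post <- invert_dcm(m, noisy, max_iter = 20)
  expect_lt(max(abs(post$mu_theta)), 0.05)
  expect_true(all(diff(post$trace) > -1e-3))
  # posterior covariance is symmetric PSD
  expect_equal(post$Sigma_theta, t(post$Sigma_theta))
  expect_true(all(eigen(post$Sigma_theta, only.values = TRUE)$values > -1e-10))
})

test_that("zero prior variance freezes the posterior at the prior", {
  m <- recovery_model(n_sources = 2, n_channels = 4, seed = 32)
  m$priors$variance[] <- 0
  dat <- withr::with_seed(5,
    matrix(rnorm(4 * 25), 4, 25))
  post <- invert_dcm(m, dat)
  expect_equal(post$mu_theta, m$priors$mean)
  expect_equal(post$Sigma_theta, matrix(0, m$n_params, m$n_params))
  expect_true(post$converged)
})

test_that("connectivity deviations map posterior gains to signed edges", {
  m <- recovery_model(n_sources = 3, n_channels = 4, seed = 33)
  # posterior at the prior: all-zero network
  post0 <- list(mu_theta = rep(0, m$n_params), model = m)
  net0 <- connectivity_deviation(post0, m)
  expect_equal(max(abs(net0$A)), 0)
  expect_equal(rownames(net0$A), m$roi$name)

  # multiplicative gains 0.5 / 2.0 become -+ log 2 edge weights
  th <- rep(0, m$n_params)
  e1 <- which(m$edges$from == 1 & m$edges$to == 2)
  e2 <- which(m$edges$from == 3 & m$edges$to == 1)
  th[m$theta_index$lateral[e1]] <- log(0.5)
  th[m$theta_index$lateral[e2]] <- log(2)
  net <- connectivity_deviation(list(mu_theta = th, model = m), m)
  expect_equal(net$A[1, 2], log(0.5))
  expect_equal(net$A[3, 1], log(2))
  expect_equal(sum(net$A != 0), 2)
})

test_that("window segmentation and averaging are exact", {
  rec <- eeg_recording(matrix(1:40, 2, 20, byrow = TRUE), rate = 100)
  w <- segment_windows(rec, 50)      # 5 samples per window at 100 Hz
  expect_length(w, 4)
  expect_equal(w[[2]], rec$data[, 6:10])
  expect_equal(average_windows(w), (w[[1]] + w[[2]] + w[[3]] + w[[4]]) / 4)
  expect_error(segment_windows(rec, 10000), "shorter than one window")
})
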