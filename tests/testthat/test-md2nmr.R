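# trajectory-side relaxation prediction: autocorrelation, chunking, tumbling,
# spectral-density fits, relaxation observables

test_that("P2 autocorrelation is 1 for static vectors and ~0 for i.i.d. orientations", {
  U <- array(0, c(100, 1, 3)); U[, , 3] <- 1
  v <- vector_trajectory(U, 0.1)
  cf <- nh_autocorrelation(v, 1, max_lag_ns = 4)
  expect_true(all(abs(cf$value - 1) < 1e-9))
  set.seed(2)
  n <- 4000
  R <- matrix(rnorm(n * 3), n); R <- R / sqrt(rowSums(R^2))
  U2 <- array(R, c(n, 1, 3))
  cf2 <- nh_autocorrelation(vector_trajectory(U2, 1), 1, max_lag_ns = 50)
  expect_equal(cf2$value[1], 1, tolerance = 1e-9)
  # sphere average of P2 is 0; allow a 3-sigma sampling band
  expect_true(all(abs(cf2$value[-1]) < 3 * sqrt(0.2 / (n - 50))))
})

test_that("FFT and direct autocorrelation routes agree to rounding", {
  set.seed(3)
  n <- 300
  U <- matrix(rnorm(n * 3), n); U <- U / sqrt(rowSums(U^2))
  expect_equal(taildyn:::p2_acf(U, 100, "fft"),
               taildyn:::p2_acf(U, 100, "direct"), tolerance = 1e-10)
})

test_that("chunk averaging reduces to the plain estimate for one chunk and respects windows", {
  v <- gen_internal_motion(0.5, 0.5, 0.05, 2000, 1, seed = 4)
  a <- chunk_average(v, 1, n_chunks = 1, max_lag_ns = 20)
  b <- nh_autocorrelation(v, 1, max_lag_ns = 20)
  expect_equal(a$value, b$value, tolerance = 1e-12)
  # 2000 frames in 20 chunks -> 100-frame chunks; longer lags must error
  expect_error(chunk_average(v, 1, n_chunks = 20, max_lag_ns = 6),
               class = "window_error")
  cc <- chunk_average(v, 1, n_chunks = 20, max_lag_ns = 4)
  expect_equal(cc$n_chunks, 20L)
  expect_equal(length(cc$se), length(cc$value))
  # stationary signal: chunked and whole-trajectory estimates agree within
  # the chunk-scatter error
  full <- nh_autocorrelation(v, 1, max_lag_ns = 4)
  expect_true(mean(abs(cc$value - full$value) <
                     4 * pmax(cc$se, 1e-3)) > 0.95)
})

test_that("tumbling reintroduction multiplies by exp(-t/tau_rot) exactly once", {
  lag <- seq(0, 100, by = 1)
  co <- make_corr(lag, rep(1, length(lag)))
  tb <- apply_tumbling(co, 163.4)
  expect_equal(tb$value, exp(-lag / 163.4), tolerance = 1e-12)
  expect_true(tb$tumbling_applied)
  expect_error(apply_tumbling(tb, 163.4), class = "state_error")
  # infinite tumbling time leaves the function unchanged
  slow <- apply_tumbling(make_corr(lag, rep(1, length(lag))), 1e12)
  expect_equal(slow$value, rep(1, length(lag)), tolerance = 1e-9)
  # plateau input gives the model-free product form
  pl <- apply_tumbling(make_corr(lag, 0.8 + 0.2 * exp(-lag / 0.5)), 20)
  expect_equal(pl$value, (0.8 + 0.2 * exp(-lag / 0.5)) * exp(-lag / 20),
               tolerance = 1e-12)
})

test_that("multi-exponential fits recover models inside the model class", {
  lag <- seq(0, 50, by = 0.1)
  f1 <- fit_exponentials(make_corr(lag, exp(-lag / 10)))
  expect_equal(sum(f1$amplitudes), 1, tolerance = 1e-3)
  i <- which.max(f1$amplitudes)
  expect_equal(f1$tau_ns[i], 10, tolerance = 0.02)
  expect_lt(sum(f1$amplitudes[-i]), 1e-3)

  lag2 <- seq(0, 400, by = 0.1)
  y2 <- 0.3 * exp(-lag2 / 0.5) + 0.7 * exp(-lag2 / 163.4)
  f2 <- fit_exponentials(make_corr(lag2, y2, tumbling_applied = TRUE,
                                   tau_rot_ns = 163.4))
  expect_equal(length(f2$amplitudes), 2)
  expect_equal(f2$amplitudes, c(0.3, 0.7), tolerance = 0.02)
  expect_equal(f2$tau_ns, c(0.5, 163.4), tolerance = 0.02)
})

test_that("additive noise moves J(0) of the fit by under 5%", {
  lag <- seq(0, 400, by = 0.1)
  y <- 0.3 * exp(-lag / 0.5) + 0.7 * exp(-lag / 163.4)
  clean <- fit_exponentials(make_corr(lag, y, tumbling_applied = TRUE,
                                      tau_rot_ns = 163.4))
  set.seed(5)
  noisy <- fit_exponentials(make_corr(lag, pmin(1, y + rnorm(length(lag), 0, 0.01)),
                                      tumbling_applied = TRUE,
                                      tau_rot_ns = 163.4))
  expect_lt(abs(spectral_density(noisy, 0) / spectral_density(clean, 0) - 1),
            0.05)
})

test_that("spectral density follows the 2/5 Lorentzian convention", {
  m <- spectral_density_model(1, 10)
  expect_equal(spectral_density(m, 0), 0.4 * 10e-9, tolerance = 1e-15)
  w <- 1 / 10e-9
  expect_equal(spectral_density(m, w), spectral_density(m, 0) / 2,
               tolerance = 1e-12)
  expect_true(all(spectral_density(m, 10^seq(6, 10, by = 0.5)) >= 0))
})

test_that("analytic spectral density agrees with the FFT cosine-transform oracle", {
  m <- spectral_density_model(c(0.2, 0.3, 0.5), c(0.5, 8, 163.4))
  fp <- field_parameters(600)
  om <- c(0, fp$omega_N, fp$omega_H - fp$omega_N, fp$omega_H,
          fp$omega_H + fp$omega_N, 2 * fp$omega_H)
  num <- spectral_density_fft(m, om)
  ana <- spectral_density(m, num$omega)
  expect_true(all(abs(num$J / ana - 1) < 0.01))
})

test_that("relaxation observables behave physically", {
  fp <- field_parameters(600)
  # zero spectral density gives zero rates
  z <- relaxation_from_J(spectral_density_model(0, 1), fp)
  expect_equal(z$R1, 0); expect_equal(z$R2, 0)
  # R2 >= R1 whenever the slowest timescale exceeds 1/omega_N
  set.seed(6)
  for (i in 1:10) {
    a <- runif(3); a <- a / sum(a)
    tau <- sort(exp(runif(3, log(0.05), log(300))))
    if (tau[3] < 1e9 / fp$omega_N) next
    p <- relaxation_from_J(spectral_density_model(a, tau), fp)
    expect_gte(p$R2, p$R1)
  }
  # R2 grows monotonically with the tumbling time at fixed internal motion
  r2 <- vapply(c(50, 100, 163.4, 300), function(tr) {
    co <- apply_tumbling(make_corr(seq(0, 400, 0.2),
                                   0.85 + 0.15 * exp(-seq(0, 400, 0.2) / 0.5)),
                         tr)
    relaxation_from_J(fit_exponentials(co), fp)$R2
  }, 0)
  expect_true(all(diff(r2) > 0))
})

test_that("fit and evaluate round-trip preserves J at the five canonical frequencies", {
  fp <- field_parameters(600)
  m <- spectral_density_model(c(0.25, 0.35, 0.4), c(0.3, 5, 163.4))
  lag <- c(seq(0, 2, by = 0.01), seq(2.1, 700, by = 0.5))
  y <- vapply(lag, function(t) sum(m$amplitudes * exp(-t / m$tau_ns)), 0)
  f <- fit_exponentials(make_corr(lag, y, tumbling_applied = TRUE,
                                  tau_rot_ns = 163.4))
  om <- c(0, fp$omega_N, fp$omega_H - fp$omega_N, fp$omega_H,
          fp$omega_H + fp$omega_N)
  expect_true(all(abs(spectral_density(f, om) / spectral_density(m, om) - 1)
                  < 0.01))
})

test_that("internal motion times overall tumbling factorizes like a co-simulated process", {
  # co-simulate: apply a global rotational-diffusion rotation R(t) to
  # cone-model internal vectors, then compare the resulting ACF with the
  # product C_internal(t) * exp(-t/tau_rot)
  S2 <- 0.8; tau_e <- 0.5; tau_rot <- 20; dt <- 0.05; n <- 4e4
  vi <- gen_internal_motion(S2, tau_e, dt, n, 2, seed = 7)
  set.seed(8)
  sig <- sqrt(dt / tau_rot)
  Rm <- diag(3)
  U <- vi$vectors
  tot <- array(NA_real_, dim(U))
  for (f in seq_len(n)) {
    if (f > 1) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      th <- rnorm(1) * sig
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3,
                  byrow = TRUE)
      Rm <- (diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K) %*% Rm
    }
    tot[f, , ] <- U[f, , ] %*% t(Rm)
  }
  nrm <- sqrt(tot[, , 1]^2 + tot[, , 2]^2 + tot[, , 3]^2)
  for (k in 1:3) tot[, , k] <- tot[, , k] / nrm
  vt <- vector_trajectory(tot, dt)
  ci <- nh_autocorrelation(vi, 1, max_lag_ns = 10)
  ct <- nh_autocorrelation(vt, 1, max_lag_ns = 10)
  prod <- ci$value * exp(-ci$lag_ns / tau_rot)
  expect_lt(max(abs(ct$value - prod)), 0.06)
})

test_that("full prediction chain recovers the generating tumbling time from raw vectors", {
  v <- gen_rotational_diffusion(5, 0.02, 2e4, 1, seed = 9)
  prof <- md_relaxation_profile(v, tau_rot_ns = NULL, n_chunks = 10)
  expect_equal(prof$tau_c_ns, 5, tolerance = 0.1)
})

test_that("predicted and observed tau_c profiles are compared by Pearson correlation", {
  a <- data.frame(residue = 1:10, tau_c_ns = 1:10)
  b <- data.frame(residue = 1:10, tau_c_ns = 2 * (1:10) + 3)
  expect_equal(compare_to_experiment(a, b)$pearson_r, 1)
  b$tau_c_ns <- rev(b$tau_c_ns)
  expect_equal(compare_to_experiment(a, b)$pearson_r, -1)
  expect_error(compare_to_experiment(a[1:2, ], b[1:2, ]),
               class = "insufficient_data_error")
  # sampling distribution check: known rho = 0.8, n = 30, Fisher-z interval
  set.seed(10)
  x <- rnorm(30); y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(30)
  r <- compare_to_experiment(data.frame(residue = 1:30, tau_c_ns = x),
                             data.frame(residue = 1:30, tau_c_ns = y))$pearson_r
  z <- atanh(r); z0 <- atanh(0.8); sez <- 1 / sqrt(30 - 3)
  expect_lt(abs(z - z0), 1.96 * sez)
})
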