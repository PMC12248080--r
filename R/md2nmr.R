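# Trajectory-side prediction of NMR relaxation observables.
#
# The chain is: NH bond vectors from a core-aligned trajectory -> rank-2
# (second Legendre) orientational autocorrelation C(t), averaged over equal
# chunks for convergence -> multiplicative reintroduction of the overall
# nucleosome tumbling exp(-t/tau_rot) -> constrained tri-exponential fit ->
# analytic spectral density J(w) -> dipolar + CSA expressions for R1, R2 and
# NOE -> effective correlation time via the R2/R1 estimator. The rank-2
# correlation is dictated by the relaxation mechanism (15N-1H dipole-dipole
# plus 15N CSA); the 2/5 normalization lives in J(w), one self-consistent
# convention validated by the rigid-rotor inversion test.

# ---- correlation functions --------------------------------------------------

# P2 autocorrelation of a frames x 3 matrix of unit vectors, all time origins.
# "fft" computes the 6 unique component-product autocorrelations by FFT
# (identical to "direct" up to rounding); "direct" is the brute-force oracle.
p2_acf <- function(U, max_lag, method = c("fft", "direct")) {
  method <- match.arg(method)
  n <- nrow(U)
  if (max_lag >= n)
    stop_taildyn("max_lag exceeds available frames", "window_error")
  if (method == "direct") {
    vapply(0:max_lag, function(l) {
      d <- rowSums(U[1:(n - l), , drop = FALSE] * U[(1 + l):n, , drop = FALSE])
      mean((3 * d^2 - 1) / 2)
    }, 0)
  } else {
    m <- stats::nextn(2L * n)
    S <- numeric(max_lag + 1)
    for (a in 1:3) for (b in a:3) {
      q <- U[, a] * U[, b]
      fq <- stats::fft(c(q, rep(0, m - n)))
      ac <- Re(stats::fft(fq * Conj(fq), inverse = TRUE)) / m
      S <- S + (if (a == b) 1 else 2) * ac[1:(max_lag + 1)]
    }
    msq <- S / (n - 0:max_lag)        # <(u(s).u(s+t))^2>
    (3 * msq - 1) / 2
  }
}

new_corr_fn <- function(lag_ns, value, n_chunks, residue,
                        tumbling_applied = FALSE, tau_rot_ns = NA_real_,
                        se = NULL) {
  if (any(diff(lag_ns) <= 0))
    stop_taildyn("lags must be strictly increasing", "domain_error")
  if (!tumbling_applied && abs(value[1] - 1) > 1e-6)
    stop_taildyn("C(0) must equal 1 before tumbling multiplication",
                 "domain_error")
  structure(list(lag_ns = lag_ns, value = value, n_chunks = n_chunks,
                 residue = residue, tumbling_applied = tumbling_applied,
                 tau_rot_ns = tau_rot_ns, se = se),
            class = "corr_fn")
}

#' @export
print.corr_fn <- function(x, ...) {
  cat(sprintf(
    "<corr_fn> residue %s: %d lags to %g ns, %d chunk(s), tumbling %s\n",
    as.character(x$residue), length(x$lag_ns), max(x$lag_ns), x$n_chunks,
    if (x$tumbling_applied) sprintf("applied (tau_rot = %g ns)", x$tau_rot_ns)
    else "not applied"))
  invisible(x)
}

#' Orientational autocorrelation of an NH bond vector
#'
#' `C(t) = <P2(u(s) . u(s+t))>` averaged over all time origins `s`, with
#' `P2(x) = (3x^2 - 1)/2`. For core-aligned trajectories this is the internal
#' correlation function; overall tumbling is reintroduced afterwards with
#' [apply_tumbling()].
#'
#' @param vectors a [vector_trajectory()].
#' @param residue vector (residue) index.
#' @param max_lag_ns longest lag, ns; defaults to half the trajectory.
#' @param method `"fft"` (default) or the brute-force `"direct"` oracle.
#' @return a `corr_fn` object (lags in ns, values, chunk metadata).
#' @export
nh_autocorrelation <- function(vectors, residue = 1, max_lag_ns = NULL,
                               method = "fft") {
  U <- vectors$vectors[, residue, , drop = TRUE]
  dt <- vectors$frame_interval_ns
  n <- nrow(U)
  max_lag <- if (is.null(max_lag_ns)) floor((n - 1) / 2)
             else round(max_lag_ns / dt)
  if (max_lag >= n)
    stop_taildyn("max_lag exceeds available frames", "window_error")
  new_corr_fn((0:max_lag) * dt, p2_acf(U, max_lag, method), 1L, residue)
}

#' Chunk-averaged autocorrelation function
#'
#' Splits the trajectory into `n_chunks` equal chunks, computes the P2
#' autocorrelation independently in each, and averages pointwise — the
#' convergence device used for long trajectories (20 chunks of 100 ns for a
#' 2000 ns run). Lags are truncated at half the chunk length by default to
#' control the variance of the long-lag estimates.
#'
#' @param vectors a [vector_trajectory()].
#' @param residue vector (residue) index.
#' @param n_chunks number of equal chunks (default 20).
#' @param max_lag_ns longest lag, ns; must not exceed the chunk length.
#' @param method passed to [p2_acf()].
#' @return a `corr_fn` with `n_chunks` recorded.
#' @export
chunk_average <- function(vectors, residue = 1, n_chunks = 20,
                          max_lag_ns = NULL, method = "fft") {
  U <- vectors$vectors[, residue, , drop = TRUE]
  dt <- vectors$frame_interval_ns
  n <- nrow(U)
  len <- n %/% n_chunks
  if (abs(n - len * n_chunks) > 1)
    stop_taildyn("frame count not divisible into n_chunks within one frame",
                 "window_error")
  max_lag <- if (is.null(max_lag_ns)) floor((len - 1) / 2)
             else round(max_lag_ns / dt)
  if (max_lag >= len)
    stop_taildyn("chunk shorter than max_lag", "window_error")
  per <- vapply(seq_len(n_chunks), function(k) {
    rows <- ((k - 1) * len + 1):(k * len)
    p2_acf(U[rows, , drop = FALSE], max_lag, method)
  }, numeric(max_lag + 1))
  per <- matrix(per, nrow = max_lag + 1)
  se <- if (n_chunks >= 2) apply(per, 1, stats::sd) / sqrt(n_chunks) else NULL
  out <- new_corr_fn((0:max_lag) * dt, rowMeans(per), as.integer(n_chunks),
                     residue, se = se)
  out$chunk_values <- if (n_chunks >= 2) per else NULL
  out
}

#' Reintroduce overall tumbling into a correlation function
#'
#' Multiplies an internal (core-aligned) correlation function pointwise by
#' `exp(-t / tau_rot)`, the isotropic overall tumbling of the intact
#' particle; the default 163.4 ns is the nucleosome core particle tumbling
#' time used throughout. Applying tumbling twice is a state error.
#'
#' @param corr a `corr_fn`.
#' @param tau_rot_ns overall rotational correlation time, ns (> 0).
#' @return the modified `corr_fn` with its tumbling flag set.
#' @export
apply_tumbling <- function(corr, tau_rot_ns = 163.4) {
  if (corr$tumbling_applied)
    stop_taildyn("tumbling already applied to this correlation function",
                 "state_error")
  if (!is.numeric(tau_rot_ns) || tau_rot_ns <= 0)
    stop_taildyn("tau_rot_ns must be > 0", "domain_error")
  damp <- exp(-corr$lag_ns / tau_rot_ns)
  corr$value <- corr$value * damp
  if (!is.null(corr$se)) corr$se <- corr$se * damp
  if (!is.null(corr$chunk_values))
    corr$chunk_values <- corr$chunk_values * damp
  corr$tumbling_applied <- TRUE
  corr$tau_rot_ns <- tau_rot_ns
  corr
}

# ---- spectral density model -------------------------------------------------

#' Construct a multi-exponential spectral density model
#'
#' `C(t) = sum_i a_i exp(-t / tau_i)` with `a_i >= 0`, `tau_i > 0` and
#' `sum a_i <= 1`; evaluates `J(w) = (2/5) sum_i a_i tau_i / (1 + (w tau_i)^2)`.
#'
#' @param amplitudes non-negative amplitudes.
#' @param tau_ns timescales in ns (> 0); stored sorted ascending.
#' @param residual RMS fit residual (optional).
#' @param poor_fit logical warning flag carried from the fit.
#' @return object of class `sdens_model` (normalization tag `"P2-2/5"`).
#' @export
spectral_density_model <- function(amplitudes, tau_ns, residual = NA_real_,
                                   poor_fit = FALSE) {
  if (any(amplitudes < 0) || any(tau_ns <= 0))
    stop_taildyn("need amplitudes >= 0 and tau > 0", "domain_error")
  if (sum(amplitudes) > 1 + 1e-3)
    stop_taildyn("sum of amplitudes exceeds 1", "domain_error")
  o <- order(tau_ns)
  structure(list(amplitudes = amplitudes[o], tau_ns = tau_ns[o],
                 normalization = "P2-2/5", residual = residual,
                 poor_fit = poor_fit),
            class = "sdens_model")
}

#' @export
print.sdens_model <- function(x, ...) {
  cat("<sdens_model> C(t) = sum a_i exp(-t/tau_i):\n")
  for (i in seq_along(x$amplitudes))
    cat(sprintf("  a = %.4f  tau = %.4g ns\n", x$amplitudes[i], x$tau_ns[i]))
  if (!is.na(x$residual)) cat(sprintf("  rms residual %.2e%s\n", x$residual,
                                      if (x$poor_fit) " (poor fit)" else ""))
  invisible(x)
}

# reconstruct C(t) from a model, t in ns
reconstruct_corr <- function(model, t_ns) {
  as.numeric(exp(-outer(t_ns, model$tau_ns, "/")) %*% model$amplitudes)
}

# non-negative LS amplitudes on a (possibly whitened) design; cap sum(a) at 1
nnls_capped <- function(A, y, n_tau) {
  a <- pracma::lsqnonneg(A, y)$x
  if (sum(a) > 1 + 1e-3) {            # refit on the boundary sum(a) = 1
    w <- 1e4 * max(abs(A))
    a <- pracma::lsqnonneg(rbind(A, rep(w, n_tau)), c(y, w))$x
  }
  a
}

#' Fit a correlation function with a sum of exponentials
#'
#' Constrained least squares (`a_i >= 0`, `tau_i > 0`, `sum a_i <= 1`) with
#' multistart initialization over logarithmically spaced timescale tuples
#' spanning the lag window; the best restart (lowest residual) wins for each
#' model size. Timescales closer than 5% are collapsed. A poor-fit flag (RMS
#' residual above three times the data's chunk-scatter noise level, or above
#' 0.02 when no noise estimate exists) is carried on the result rather than
#' raised as an error.
#'
#' Several safeguards keep the non-negative fit from absorbing estimator
#' noise into spurious components that would inflate J(0):
#' \itemize{
#'   \item when the correlation comes from [chunk_average()], the noise
#'     covariance of the chunk-mean C(t) — including the strong lag-to-lag
#'     correlation of finite-trajectory noise — is estimated from the
#'     independent chunks (with diagonal shrinkage) and the fit is performed
#'     by whitened generalized least squares, so a coherent excursion of the
#'     realized C(t) counts as the single fluctuation it is rather than as
#'     hundreds of independent observations of a slow component;
#'   \item the lag grid is subsampled logarithmically (~12 points per
#'     decade), matching the fitted point count to the information content
#'     and keeping the covariance estimable from the available chunks;
#'   \item the number of exponential terms (1 to `n_terms`) is selected by
#'     BIC, so a component supported only by a ~1-sigma excursion is
#'     rejected while well-separated genuine components are kept;
#'   \item lags after the (lightly smoothed) correlation first drops below
#'     `noise_floor` are discarded, and timescales are capped at the fitted
#'     lag window (slower components are unidentifiable from the window;
#'     with tumbling applied the cap extends to twice the tumbling time).
#' }
#'
#' @param corr a `corr_fn` (typically chunk-averaged, tumbling applied).
#' @param n_terms maximum number of exponentials (default 3).
#' @param n_starts number of multistart initializations per model size.
#' @param noise_floor truncation level for the decayed tail (correlation
#'   units); `NULL` or 0 disables truncation.
#' @return a [spectral_density_model()].
#' @export
fit_exponentials <- function(corr, n_terms = 3, n_starts = 8,
                             noise_floor = 0.02) {
  t <- corr$lag_ns; y <- corr$value
  if (length(t) < 3 * n_terms)
    stop_taildyn("need at least 3 x n_terms lag points", "domain_error")
  if (any(y < -0.5 - 1e-6) || any(y > 1 + 1e-6))
    stop_taildyn("correlation values outside [-0.5, 1]", "domain_error")
  se <- corr$se
  X <- corr$chunk_values
  if (!is.null(noise_floor) && noise_floor > 0) {
    ys <- boxcar(y, max(3, length(y) %/% 50))
    below <- which(ys < noise_floor)
    min_pts <- min(length(y), max(9 * n_terms, 30))
    if (length(below)) {
      keep <- seq_len(max(below[1], min_pts))
      t <- t[keep]; y <- y[keep]
      if (!is.null(se)) se <- se[keep]
      if (!is.null(X)) X <- X[keep, , drop = FALSE]
    }
  }
  # log-spaced lag subsample (~12 points per decade): matches the fitted
  # point count to the information content of the correlated estimator and
  # keeps the noise covariance estimable from the available chunks, while
  # leaving noiseless fits exact
  if (length(t) > 60) {
    idx <- sort(unique(c(1L, pmin(length(t), round(
      10^(seq(0, log10(length(t)), by = 1 / 12)))))))
    t <- t[idx]; y <- y[idx]
    if (!is.null(se)) se <- se[idx]
    if (!is.null(X)) X <- X[idx, , drop = FALSE]
  }
  # whitening transform: full noise covariance of the chunk-mean C(t) from
  # the independent chunks (diagonal shrinkage + ridge keeps it positive
  # definite with n_lags > n_chunks); fall back to inverse-variance weights
  # when chunk values are unavailable
  W <- NULL
  if (!is.null(X) && ncol(X) >= 8) {
    S <- stats::cov(t(X)) / ncol(X)
    lam <- 0.3
    Sh <- (1 - lam) * S + lam * diag(diag(S), nrow(S))
    diag(Sh) <- diag(Sh) + 1e-10
    R <- tryCatch(chol(Sh), error = function(e) NULL)
    if (!is.null(R)) W <- forwardsolve(t(R), diag(nrow(Sh)))
  }
  if (is.null(W) && !is.null(se) && any(se > 0))
    W <- diag(1 / sqrt(se^2 + 1e-10))
  chisq_scale <- !is.null(W)         # objective in chi-square units?
  lo <- max(t[2] / 2, 1e-3)
  hi <- max(t)
  if (corr$tumbling_applied && is.finite(corr$tau_rot_ns))
    hi <- max(2 * hi, 2 * corr$tau_rot_ns)
  grid <- logspace(lo, hi, max(3 * n_starts %/% 2, n_terms + 2))
  solve_amp <- function(tau) {
    A <- exp(-outer(t, tau, "/"))
    if (!is.null(W)) { Aw <- W %*% A; yw <- drop(W %*% y) }
    else { Aw <- A; yw <- y }
    a <- nnls_capped(Aw, yw, length(tau))
    list(a = a, rss = sum((yw - Aw %*% a)^2))
  }
  obj <- function(ltau) solve_amp(exp(ltau))$rss
  fit_size <- function(k) {
    starts <- lapply(seq_len(n_starts), function(s) {
      idx <- round(seq(1 + (s - 1) %% 3, length(grid) - (s %% 3),
                       length.out = k))
      log(grid[pmax(1, pmin(length(grid), idx))] * (1 + 0.13 * s))
    })
    best <- NULL
    for (s in starts) {
      s <- pmin(pmax(s, log(lo / 10)), log(hi))
      op <- tryCatch(stats::nlminb(s, obj, lower = log(lo / 10),
                                   upper = log(hi)),
                     error = function(e) NULL)
      if (is.null(op)) next
      if (is.null(best) || op$objective < best$objective) best <- op
    }
    best
  }
  n_pts <- length(t)
  fits <- lapply(seq_len(n_terms), fit_size)
  bic <- vapply(seq_len(n_terms), function(k) {
    if (is.null(fits[[k]])) return(Inf)
    pen <- 2 * k * log(n_pts)
    if (chisq_scale) fits[[k]]$objective + pen
    else n_pts * log(fits[[k]]$objective / n_pts + 1e-30) + pen
  }, 0)
  if (all(!is.finite(bic)))
    stop_taildyn("multi-exponential fit failed from every start", "fit_error")
  best <- fits[[which.min(bic)]]
  tau <- exp(best$par)
  a <- solve_amp(tau)$a
  # collapse (near-)duplicate timescales and drop inactive terms
  o <- order(tau); tau <- tau[o]; a <- a[o]
  keep_tau <- c(); keep_a <- c()
  for (i in seq_along(tau)) {
    if (length(keep_tau) && tau[i] / keep_tau[length(keep_tau)] < 1.05) {
      keep_a[length(keep_a)] <- keep_a[length(keep_a)] + a[i]
    } else {
      keep_tau <- c(keep_tau, tau[i]); keep_a <- c(keep_a, a[i])
    }
  }
  act <- keep_a > 1e-8
  if (!any(act)) act <- which.max(keep_a)
  resid <- y - as.numeric(exp(-outer(t, keep_tau, "/")) %*% keep_a)
  rms <- sqrt(mean(resid^2))
  # flag a fit as poor only if its residual exceeds the data's own noise
  # level (when known from chunk scatter) or an absolute floor
  noise_ref <- if (!is.null(se)) sqrt(mean(se^2)) else 0
  spectral_density_model(keep_a[act], keep_tau[act], residual = rms,
                         poor_fit = rms > max(0.02, 3 * noise_ref))
}

#' Evaluate the spectral density of a fitted model
#'
#' `J(w) = (2/5) sum_i a_i tau_i / (1 + (w tau_i)^2)` with timescales
#' converted to seconds; units s/rad.
#'
#' @param model a `sdens_model`.
#' @param omega_rad_per_s angular frequency (vectorized), rad/s.
#' @return J(omega), s/rad.
#' @export
spectral_density <- function(model, omega_rad_per_s) {
  tau_s <- model$tau_ns * 1e-9
  vapply(omega_rad_per_s,
         function(w) 0.4 * sum(model$amplitudes * tau_s / (1 + (w * tau_s)^2)),
         0)
}

#' Numeric cosine-transform spectral density (FFT oracle)
#'
#' Independent route to `J(w)`: the model's correlation function is
#' reconstructed on a fine time grid and cosine-transformed numerically via
#' FFT (trapezoid endpoint correction, truncation at many multiples of the
#' slowest timescale). Used to cross-check the analytic transform; the
#' analytic route is primary.
#'
#' @param model a `sdens_model`.
#' @param omega_rad_per_s requested angular frequencies, rad/s.
#' @param dt_ns grid spacing; default resolves both the fastest timescale and
#'   the highest requested frequency.
#' @return list with `omega` (FFT grid frequencies nearest each request) and
#'   `J` (s/rad).
#' @export
spectral_density_fft <- function(model, omega_rad_per_s, dt_ns = NULL) {
  wmax <- max(omega_rad_per_s, 1)
  if (is.null(dt_ns))
    dt_ns <- min(min(model$tau_ns) / 10, 0.25 / (wmax * 1e-9), 0.02)
  t_max <- 12 * max(model$tau_ns)
  n <- stats::nextn(ceiling(t_max / dt_ns))
  tg <- (0:(n - 1)) * dt_ns
  C <- reconstruct_corr(model, tg)
  F <- Re(stats::fft(C))                       # sum C_j cos(2 pi j k / n)
  Jgrid <- 0.4 * (F - C[1] / 2) * dt_ns * 1e-9 # trapezoid, s/rad
  wgrid <- 2 * pi * (0:(n - 1)) / (n * dt_ns * 1e-9)
  idx <- vapply(omega_rad_per_s, function(w) which.min(abs(wgrid - w)), 0L)
  list(omega = wgrid[idx], J = Jgrid[idx])
}

# ---- relaxation observables -------------------------------------------------

#' Spectrometer and spin-pair parameters
#'
#' Field-standard constants for the backbone amide 15N-1H pair: NH bond
#' length 1.02 A, 15N CSA -170 ppm, gyromagnetic ratios of 1H and 15N. The
#' 15N frequency is derived from the 1H frequency through the ratio of
#' gyromagnetic ratios (60.8 MHz at 600 MHz).
#'
#' @param h_freq_mhz 1H spectrometer frequency, MHz.
#' @param nh_bond_A NH bond length, Angstrom.
#' @param csa_ppm 15N chemical shift anisotropy, ppm.
#' @return object of class `field_params` with frequencies (Hz and rad/s)
#'   and the dipolar (`d`) and CSA (`c`) interaction constants in rad/s.
#' @export
field_parameters <- function(h_freq_mhz = 600, nh_bond_A = 1.02,
                             csa_ppm = -170) {
  stopifnot(h_freq_mhz > 0, nh_bond_A > 0)
  gH <- 2.6752218744e8                # rad s^-1 T^-1
  gN <- -2.71261804e7
  hbar <- 1.054571817e-34
  nu_H <- h_freq_mhz * 1e6
  nu_N <- nu_H * abs(gN) / gH
  wH <- 2 * pi * nu_H
  wN <- 2 * pi * nu_N
  d <- 1e-7 * hbar * gH * abs(gN) / (nh_bond_A * 1e-10)^3
  cc <- wN * abs(csa_ppm) * 1e-6 / sqrt(3)
  structure(list(nu_H_Hz = nu_H, nu_N_Hz = nu_N, omega_H = wH, omega_N = wN,
                 gamma_H = gH, gamma_N = gN, nh_bond_A = nh_bond_A,
                 csa_ppm = csa_ppm, d = d, c = cc),
            class = "field_params")
}

#' Relaxation observables from a spectral density model
#'
#' Standard dipolar + CSA expressions evaluated at the five canonical
#' frequencies:
#' `R1 = (d^2/4)[J(wH-wN) + 3 J(wN) + 6 J(wH+wN)] + c^2 J(wN)`,
#' `R2 = (d^2/8)[4 J(0) + J(wH-wN) + 3 J(wN) + 6 J(wH) + 6 J(wH+wN)]
#'       + (c^2/6)[4 J(0) + 3 J(wN)]`,
#' `NOE = 1 + (d^2/(4 R1)) (gH/gN) [6 J(wH+wN) - J(wH-wN)]`,
#' followed by the R2/R1 estimator of the effective correlation time.
#'
#' @param model a `sdens_model`.
#' @param field a [field_parameters()] object.
#' @return list of class `relax_pred` with `R1`, `R2` (1/s), `NOE`,
#'   `tau_c_ns` (NA if the R2/R1 discriminant is negative), `nu_N_Hz`.
#' @export
relaxation_from_J <- function(model, field = field_parameters()) {
  wH <- field$omega_H; wN <- field$omega_N
  J <- function(w) spectral_density(model, w)
  d2 <- field$d^2; c2 <- field$c^2
  R1 <- (d2 / 4) * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  R2 <- (d2 / 8) * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                      6 * J(wH + wN)) +
        (c2 / 6) * (4 * J(0) + 3 * J(wN))
  NOE <- if (R1 > 0)
    1 + (d2 / (4 * R1)) * (field$gamma_H / field$gamma_N) *
      (6 * J(wH + wN) - J(wH - wN))
  else NA_real_
  tc <- if (R1 > 0 && 6 * R2 / R1 - 7 >= 0)
    tau_c_from_rates(R1, R2, 0, 0, field$nu_N_Hz)$tau_c_ns
  else NA_real_
  structure(list(R1 = R1, R2 = R2, NOE = NOE, tau_c_ns = tc,
                 nu_N_Hz = field$nu_N_Hz, model = model),
            class = "relax_pred")
}

#' @export
print.relax_pred <- function(x, ...) {
  cat(sprintf("<relax_pred> R1 = %.4g /s, R2 = %.4g /s, NOE = %.3f, tau_c = %.4g ns\n",
              x$R1, x$R2, x$NOE, x$tau_c_ns))
  invisible(x)
}

#' Predict per-residue relaxation observables from NH vectors
#'
#' Convenience wrapper running the full trajectory-side chain for every
#' residue in a vector trajectory: chunk-averaged P2 autocorrelation,
#' optional tumbling reintroduction, tri-exponential fit, and relaxation
#' observables.
#'
#' @param vectors a [vector_trajectory()] (core-aligned NH vectors, or
#'   synthetic full-motion vectors with `tau_rot_ns = NULL`).
#' @param tau_rot_ns overall tumbling time to reintroduce (ns), or `NULL` to
#'   skip (when the vectors already contain the overall motion).
#' @param n_chunks,max_lag_ns passed to [chunk_average()].
#' @param field a [field_parameters()] object.
#' @return data.frame with one row per residue: `residue`, `R1`, `R2`,
#'   `NOE`, `tau_c_ns`; fitted models in `attr(, "models")`.
#' @export
md_relaxation_profile <- function(vectors, tau_rot_ns = 163.4, n_chunks = 20,
                                  max_lag_ns = NULL,
                                  field = field_parameters()) {
  nres <- dim(vectors$vectors)[2]
  models <- vector("list", nres)
  rows <- lapply(seq_len(nres), function(r) {
    co <- chunk_average(vectors, r, n_chunks = n_chunks,
                        max_lag_ns = max_lag_ns)
    if (!is.null(tau_rot_ns)) co <- apply_tumbling(co, tau_rot_ns)
    m <- fit_exponentials(co)
    models[[r]] <<- m
    p <- relaxation_from_J(m, field)
    data.frame(residue = r, R1 = p$R1, R2 = p$R2, NOE = p$NOE,
               tau_c_ns = p$tau_c_ns)
  })
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  out
}

#' Compare predicted and observed per-residue correlation times
#'
#' Pearson correlation over residues present in both profiles (missing data
#' excluded pairwise) plus per-residue differences — the headline agreement
#' statistic between trajectory-derived and measured tau_c profiles.
#'
#' @param predicted,observed data.frames with columns `residue` and a value
#'   column (default `tau_c_ns`).
#' @param value name of the value column.
#' @return list with `pearson_r`, `n`, and a merged data.frame of
#'   per-residue `delta` (predicted - observed).
#' @export
compare_to_experiment <- function(predicted, observed, value = "tau_c_ns") {
  m <- merge(predicted[, c("residue", value)], observed[, c("residue", value)],
             by = "residue", suffixes = c("_pred", "_obs"))
  vp <- m[[paste0(value, "_pred")]]; vo <- m[[paste0(value, "_obs")]]
  ok <- is.finite(vp) & is.finite(vo)
  if (sum(ok) < 3)
    stop_taildyn("need >= 3 shared residues with finite values",
                 "insufficient_data_error")
  m$delta <- vp - vo
  list(pearson_r = stats::cor(vp[ok], vo[ok]), n = sum(ok), table = m)
}
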