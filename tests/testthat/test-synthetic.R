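# ground-truth generators: determinism, invariants, analytic laws

test_that("generators are deterministic under a fixed seed", {
  a <- gen_rotational_diffusion(5, 0.1, 200, 2, seed = 9)
  b <- gen_rotational_diffusion(5, 0.1, 200, 2, seed = 9)
  expect_identical(a$vectors, b$vectors)
  expect_false(identical(
    a$vectors, gen_rotational_diffusion(5, 0.1, 200, 2, seed = 10)$vectors))
  t1 <- gen_two_state_timeline(0.02, 0.01, 6, n_frames = 500, seed = 4)
  t2 <- gen_two_state_timeline(0.02, 0.01, 6, n_frames = 500, seed = 4)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$truth$hidden_bound, t2$truth$hidden_bound)
  d1 <- gen_intensity_decays(c(A = 2), noise_sd = 1, seed = 5)
  d2 <- gen_intensity_decays(c(A = 2), noise_sd = 1, seed = 5)
  expect_identical(d1$intensity, d2$intensity)
  m1 <- gen_melt_curve(noise_sd = 0.02, seed = 6)
  m2 <- gen_melt_curve(noise_sd = 0.02, seed = 6)
  expect_identical(m1$raw, m2$raw)
  y1 <- gen_toy_nucleosome(n_frames = 10, seed = 7)
  y2 <- gen_toy_nucleosome(n_frames = 10, seed = 7)
  expect_identical(y1$coords, y2$coords)
})

test_that("rotational diffusion vectors stay unit norm and freeze in the tau -> Inf limit", {
  v <- gen_rotational_diffusion(2, 0.05, 500, 3, seed = 11)
  nrm <- sqrt(v$vectors[, , 1]^2 + v$vectors[, , 2]^2 + v$vectors[, , 3]^2)
  expect_lt(max(abs(nrm - 1)), 1e-9)
  frozen <- gen_rotational_diffusion(Inf, 0.05, 50, 2, seed = 11)
  expect_true(all(apply(frozen$vectors, 2, function(m)
    max(abs(sweep(m, 2, m[1, ]))) < 1e-12)))
  expect_error(gen_rotational_diffusion(5, 1, 100, 1, seed = 1),
               class = "resolution_error")
})

test_that("rotational diffusion follows the rigid-rotor P2 law exp(-t/tau)", {
  tau <- 2
  v <- gen_rotational_diffusion(tau, 0.02, 4e4, 4, seed = 12)
  cf <- vapply(1:4, function(r)
    nh_autocorrelation(v, r, max_lag_ns = 6)$value, numeric(301))
  cm <- rowMeans(cf)
  lags <- (0:300) * 0.02
  for (tl in c(1, 2, 4)) {
    i <- which.min(abs(lags - tl))
    expect_lt(abs(cm[i] - exp(-tl / tau)), 0.04)  # sampling band, 4 x 800 ns
  }
})

test_that("cone-model internal motion has plateau S2 with the right limits", {
  static <- gen_internal_motion(1, 1, 0.01, 50, 2, seed = 13)
  expect_true(all(abs(nh_autocorrelation(static, 1, max_lag_ns = 0.2)$value - 1) < 1e-9))
  v <- gen_internal_motion(0.5, 1, 0.01, 1e5, 3, seed = 14)
  pl <- vapply(1:3, function(r) {
    cf <- nh_autocorrelation(v, r, max_lag_ns = 40)
    mean(cf$value[cf$lag_ns >= 8])
  }, 0)
  expect_true(all(abs(pl - 0.5) < 0.05))
  # free diffusion limit: plateau indistinguishable from 0
  v0 <- gen_internal_motion(0, 1, 0.01, 1e5, 2, seed = 15)
  cf0 <- nh_autocorrelation(v0, 1, max_lag_ns = 40)
  expect_lt(abs(mean(cf0$value[cf0$lag_ns >= 8])), 0.05)
  expect_error(gen_internal_motion(1.2, 1, 0.01, 10, 1, seed = 1),
               class = "domain_error")
})

test_that("cone half-angle mapping matches the closed form", {
  for (S2 in c(0.1, 0.5, 0.9)) {
    b <- cone_half_angle(S2)
    x <- cos(b)
    expect_equal((x * (1 + x) / 2)^2, S2, tolerance = 1e-12)
  }
  expect_equal(cone_half_angle(1), 0)
})

test_that("two-state timeline reproduces Markov stationary and dwell statistics", {
  kb <- 0.05; ku <- 0.05
  tl <- gen_two_state_timeline(kb, ku, 12, n_frames = 4e4, seed = 16)
  hb <- tl$truth$hidden_bound
  # stationary fraction within 3 SE (dwell-count based)
  r <- rle(hb)
  f <- mean(hb)
  n_eff <- length(r$lengths)
  expect_lt(abs(f - kb / (kb + ku)), 3 * 0.5 / sqrt(n_eff))
  # mean bound dwell ~ 1/ku (geometric mean 1/(1-exp(-ku)) ~ 20.5)
  bd <- r$lengths[r$values]
  expect_gt(length(bd), 500)
  expect_equal(mean(bd), 1 / (1 - exp(-ku)), tolerance = 0.1)
  # dwell times exponential: KS non-rejection at alpha 0.01
  ks <- suppressWarnings(stats::ks.test(bd, "pexp", rate = ku))
  expect_gt(ks$p.value, 0.01)
  # single bound segment when unbinding is (effectively) off
  tl2 <- gen_two_state_timeline(0.05, 1e-9, 4, n_frames = 2000, seed = 17)
  expect_true(all(tl2$truth$hidden_bound))
})

test_that("bound-state contacts occur at p and unbound at the 2% background", {
  tl <- gen_two_state_timeline(0.02, 0.01, 36, p_contact_given_bound = 0.5,
                               n_frames = 2e4, seed = 18)
  hb <- tl$truth$hidden_bound
  pb <- mean(tl$contact[, hb]); pu <- mean(tl$contact[, !hb])
  expect_equal(pb, 0.5, tolerance = 0.02)
  expect_equal(pu, 0.01, tolerance = 0.25)
})

test_that("intensity decays are exact when noiseless and use the documented delay grids", {
  d <- gen_intensity_decays(c(A = 2), noise_sd = 0, i0 = 10, seed = 1)
  expect_equal(d$intensity, 10 * exp(-2 * d$delay_s), tolerance = 1e-12)
  g <- relaxation_delay_schedule("R1", "0mM")
  expect_equal(length(g), 13)
  expect_equal(min(g), 0.010)
  expect_equal(max(g), 1.500)
  expect_true(any(duplicated(g)))
  expect_equal(sum(duplicated(relaxation_delay_schedule("R2", "0mM"))), 3)
})

test_that("melt-curve generator produces logistic profiles with derivative peaks at the midpoints", {
  mc <- gen_melt_curve(transition_midpoints_C = 70, steepnesses = 2,
                       amplitudes = 1, noise_sd = 0, n_replicates = 1, seed = 1)
  nrm <- normalize_curve(mc$raw, mc$temp_C)
  expect_equal(min(nrm), 0)
  expect_equal(max(nrm), 1)
  expect_true(all(diff(nrm) >= -1e-12))
  mc2 <- gen_melt_curve(noise_sd = 0, n_replicates = 1, seed = 1)
  dv <- derivative_curve(normalize_curve(mc2$raw, mc2$temp_C), mc2$temp_C)
  # two local maxima of the constructed forward difference near 72 and 81
  pk <- dv$temp_C[which(diff(sign(diff(dv$value))) == -2) + 1]
  expect_equal(length(pk), 2)
  expect_lt(abs(pk[1] - 72), 1.01)
  expect_lt(abs(pk[2] - 81), 1.01)
  # zero-amplitude second transition leaves a single detected melting step
  mc3 <- gen_melt_curve(amplitudes = c(0.6, 0), noise_sd = 0,
                        n_replicates = 1, seed = 1)
  tm3 <- analyze_melt_curve(mc3)$tm
  expect_equal(length(tm3), 1)
  expect_lt(abs(tm3 - 72), 1.01)
  expect_error(gen_melt_curve(transition_midpoints_C = 120),
               class = "domain_error")
})

test_that("toy nucleosome follows its scripted binding schedule", {
  toy <- gen_toy_nucleosome(n_tail_beads = 5, n_dna_beads = 10,
                            binding_mode = "always_bound", n_frames = 20,
                            seed = 19)
  tl <- atomic_contacts(toy, copy = "A")
  expect_true(all(tl$contact))
  sched <- rep(c(TRUE, FALSE), length.out = 30)
  toy2 <- gen_toy_nucleosome(n_tail_beads = 5, n_dna_beads = 10,
                             binding_mode = sched, n_frames = 30, seed = 19)
  fr <- fraction_bound(atomic_contacts(toy2, copy = "A"))
  expect_identical(fr > 0.5, sched)
  # two copies are emitted and analyzable independently
  tlB <- atomic_contacts(toy2, copy = "B")
  expect_identical(dim(tlB$contact), dim(atomic_contacts(toy2, copy = "A")$contact))
})
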