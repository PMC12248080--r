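# contact detection, state calling, event kinetics, binding statistics

# two-bead system at a controlled separation
two_bead <- function(d) {
  co <- array(0, c(1, 2, 3))
  co[1, 2, 1] <- d
  tr <- make_ensemble(co, chain = c("A", "I"), resno = c(1, 1),
                      bp = c(NA, 1L))
  tr <- set_selection(tr, "tail", list(A = 1L))
  set_selection(tr, "dna", 2L)
}

test_that("contact cutoff is strictly less-than 4 Angstrom on heavy atoms", {
  expect_true(all(atomic_contacts(two_bead(3.9), copy = "A")$contact))
  expect_false(any(atomic_contacts(two_bead(4.0), copy = "A")$contact))
  expect_false(any(atomic_contacts(two_bead(4.0001), copy = "A")$contact))
  # hydrogens never count
  co <- array(0, c(1, 2, 3))
  trH <- make_ensemble(co, elesy = c("H", "P"), chain = c("A", "I"))
  trH <- set_selection(trH, "tail", list(A = 1L))
  trH <- set_selection(trH, "dna", 2L)
  expect_error(atomic_contacts(trH, copy = "A"), class = "selection_error")
})

test_that("contact counts match the all-pairs distance oracle frame by frame", {
  set.seed(20)
  nt <- 12; nd <- 18; nf <- 6
  co <- array(runif(nf * (nt + nd) * 3, 0, 18), c(nf, nt + nd, 3))
  tr <- make_ensemble(co, chain = c(rep("A", nt), rep("I", nd)),
                      resno = c(rep(1:4, each = 3), seq_len(nd)),
                      bp = c(rep(NA, nt), seq_len(nd)))
  tr <- set_selection(tr, "tail", list(A = seq_len(nt)))
  tr <- set_selection(tr, "dna", nt + seq_len(nd))
  tl <- atomic_contacts(tr, copy = "A", stride_ns = 1)
  for (f in seq_len(nf)) {
    oracle <- integer(4)
    for (i in seq_len(nt)) for (j in seq_len(nd)) {
      d <- sqrt(sum((co[f, i, ] - co[f, nt + j, ])^2))
      if (d < 4) oracle[(i - 1) %/% 3 + 1] <- oracle[(i - 1) %/% 3 + 1] + 1L
    }
    expect_identical(unname(tl$counts[, f]), oracle)
  }
})

test_that("bound fraction is the share of residues with at least one contact", {
  counts <- matrix(0L, 36, 3)
  counts[1:2, 2] <- 5L
  counts[, 3] <- 1L
  tl <- contact_timeline(counts, stride_ns = 1)
  expect_equal(fraction_bound(tl), c(0, 2 / 36, 1))
})

test_that("state calling treats the 10% threshold inclusively and monotonically", {
  fr <- c(0.10, 0.11, 0, 0.5)
  attr(fr, "stride_ns") <- 1
  st <- call_states(fr)
  expect_equal(unclass(st)[1:4], c("unbound", "bound", "unbound", "bound"),
               ignore_attr = TRUE)
  # raising the threshold never converts unbound -> bound
  set.seed(21)
  frac <- runif(50)
  attr(frac, "stride_ns") <- 1
  prev <- call_states(frac, 0.05)
  for (th in c(0.1, 0.2, 0.5)) {
    cur <- call_states(frac, th)
    expect_false(any(prev == "unbound" & cur == "bound"))
    prev <- cur
  }
  expect_error(call_states(fr, 0), class = "domain_error")
})

test_that("event detection tiles the timeline and separates filtering from transition counts", {
  st <- c("bound", "bound", "unbound", "unbound", "unbound", "bound")
  attr(st, "stride_ns") <- 1
  ev <- detect_events(st, min_duration_ns = 50)
  expect_equal(ev$events$state, c("bound", "unbound", "bound"))
  expect_equal(ev$events$duration_ns, c(2, 3, 1))
  expect_equal(sum(ev$events$duration_ns), 6)      # tiling, pre-filter
  expect_equal(ev$transitions, 1)
  expect_equal(length(residence_times(ev, "bound")), 0)  # all under 50 ns
  expect_equal(residence_times(ev, "bound", filtered = FALSE), c(2, 1))
  all_b <- rep("bound", 10); attr(all_b, "stride_ns") <- 1
  ev2 <- detect_events(all_b)
  expect_equal(nrow(ev2$events), 1)
  expect_equal(ev2$transitions, 0)
})

test_that("residence filtering reproduces the truncated-exponential mean on Markov data", {
  tl <- gen_two_state_timeline(0.02, 0.01, 36, n_frames = 2e5, seed = 22)
  ev <- detect_events(call_states(tl), min_duration_ns = 50)
  kept <- residence_times(ev, "bound")
  expect_gt(length(kept), 500)
  # memoryless dwell: E[X | X >= 50] = 50 + mean (geometric-discretized)
  expected <- 50 + 1 / (1 - exp(-0.01))
  se <- sd(kept) / sqrt(length(kept))
  expect_lt(abs(mean(kept) - expected), 4 * se + 1)
})

test_that("binding statistics match the frame-count definition by hand", {
  st <- c(rep("unbound", 400), rep("bound", 1600))
  bs <- binding_stats(st, temperature_K = 310)
  expect_equal(bs$Kd, 0.25)
  expect_equal(bs$dG0_kJ_mol, 8.314 * 310 * log(0.25) / 1000, tolerance = 1e-12)
  expect_equal(signif(bs$dG0_kJ_mol, 4), -3.573)
  eq <- binding_stats(c(rep("bound", 5), rep("unbound", 5)))
  expect_equal(eq$Kd, 1); expect_equal(eq$dG0_kJ_mol, 0)
  ab <- binding_stats(rep("bound", 10))
  expect_true(ab$undefined)
  expect_true(is.na(ab$Kd))
  expect_equal(ab$frames_bound, 10)
})

test_that("radius of gyration matches closed forms and a direct-sum oracle", {
  co <- array(0, c(1, 3, 3))
  tr <- make_ensemble(co)
  expect_equal(radius_of_gyration(tr, 1:3), 0)
  # two equal masses 10 A apart
  co2 <- array(0, c(1, 2, 3)); co2[1, 2, 1] <- 10
  expect_equal(radius_of_gyration(make_ensemble(co2), 1:2), 5)
  # unit-square of side s
  s <- 3.7
  co3 <- array(0, c(1, 4, 3))
  co3[1, , 1] <- c(0, s, s, 0); co3[1, , 2] <- c(0, 0, s, s)
  expect_equal(radius_of_gyration(make_ensemble(co3), 1:4), s / sqrt(2),
               tolerance = 1e-12)
  # mass-weighted oracle with mixed elements
  set.seed(23)
  co4 <- array(rnorm(2 * 5 * 3, sd = 4), c(2, 5, 3))
  tr4 <- make_ensemble(co4, elesy = c("C", "N", "O", "P", "S"))
  got <- radius_of_gyration(tr4, 1:5)
  m <- c(12.011, 14.007, 15.999, 30.974, 32.06)
  for (f in 1:2) {
    X <- co4[f, , ]
    com <- colSums(X * m / sum(m))
    expect_equal(got[f], sqrt(sum(m * rowSums(sweep(X, 2, com)^2)) / sum(m)),
                 tolerance = 1e-12)
  }
  expect_error(radius_of_gyration(tr4, integer(0)), class = "selection_error")
})

test_that("contact statistics aggregate runs and copies with SEMs", {
  mk <- function(seed) {
    set.seed(seed)
    toy <- gen_toy_nucleosome(n_tail_beads = 4, n_dna_beads = 8,
                              n_frames = 10, seed = seed)
    atomic_contacts(toy, copy = "A")
  }
  t1 <- mk(1)
  st1 <- contact_statistics(list(t1, t1))
  expect_equal(st1$per_residue$sem, rep(0, 4))       # identical copies
  expect_equal(st1$n, 2)
  st2 <- contact_statistics(list(mk(1), mk(2)))
  expect_equal(nrow(st2$per_bp), ncol(st2$heatmap))
  expect_true(all(st2$per_residue$mean >= 0))
  # single always-bound contact: that residue/bp cell is 1, others 0
  co <- array(0, c(3, 2, 3)); co[, 2, 1] <- 3.0
  tr <- make_ensemble(co, chain = c("A", "I"), resno = c(1, 1),
                      bp = c(NA, 5L))
  tr <- set_selection(tr, "tail", list(A = 1L))
  tr <- set_selection(tr, "dna", 2L)
  tl <- atomic_contacts(tr, copy = "A")
  st3 <- contact_statistics(tl)
  expect_equal(unname(st3$heatmap[1, 1]), 1)
  expect_equal(st3$per_residue$mean, 1)
})

test_that("recovered binding statistics agree with the generating Markov chain", {
  kb <- 0.02; ku <- 0.01
  tl <- gen_two_state_timeline(kb, ku, 36, n_frames = 2e5, seed = 24)
  st <- call_states(tl)
  f <- mean(st == "bound")
  # 3-SE band using the two-state chain autocorrelation
  p <- 1 - exp(-ku); q <- 1 - exp(-kb)
  rho <- 1 - p - q
  sef <- sqrt(f * (1 - f) * (1 + rho) / (1 - rho) / length(st))
  expect_lt(abs(f - kb / (kb + ku)), 3 * sef)
  bs <- binding_stats(st)
  expect_lt(abs(bs$Kd - ku / kb), 3 * sef / f^2)
})
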