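# Synthetic-data generators. Every pipeline stage in the package is exercised
# against data from these generators, whose ground truth (rates, midpoints,
# order parameters, hidden state sequences) is known exactly and carried on
# the returned objects. All generators are deterministic under a fixed seed;
# multi-stream generators derive per-stream child seeds from the dataset seed
# (see child_seed()).

#' Construct a unit-vector trajectory
#'
#' Stand-in for backbone NH bond orientations: an array of unit vectors per
#' frame and residue, plus the generating ground truth.
#'
#' @param vectors frames x residues x 3 array of unit vectors.
#' @param frame_interval_ns frame spacing, ns.
#' @param truth list of generating parameters (kept as ground truth).
#' @return object of class `vector_traj`.
#' @export
vector_trajectory <- function(vectors, frame_interval_ns, truth = list()) {
  stopifnot(length(dim(vectors)) == 3, dim(vectors)[3] == 3,
            frame_interval_ns > 0)
  nrm <- sqrt(vectors[, , 1]^2 + vectors[, , 2]^2 + vectors[, , 3]^2)
  if (max(abs(nrm - 1)) > 1e-9)
    stop_taildyn("vectors must have unit norm", "domain_error")
  structure(list(vectors = vectors, frame_interval_ns = frame_interval_ns,
                 truth = truth),
            class = "vector_traj")
}

#' @export
print.vector_traj <- function(x, ...) {
  d <- dim(x$vectors)
  cat(sprintf("<vector_traj> %d frames x %d vectors, dt = %g ns\n",
              d[1], d[2], x$frame_interval_ns))
  invisible(x)
}

# One isotropic rotational-Brownian step for an n x 3 matrix of unit vectors:
# random rotation about a uniformly random axis, angle ~ N(0, sigma).
rotate_step <- function(V, th, ax) {
  ax <- ax / sqrt(rowSums(ax^2))
  ct <- cos(th); st <- sin(th)
  axv <- cbind(ax[, 2] * V[, 3] - ax[, 3] * V[, 2],
               ax[, 3] * V[, 1] - ax[, 1] * V[, 3],
               ax[, 1] * V[, 2] - ax[, 2] * V[, 1])
  ad <- rowSums(ax * V)
  V2 <- V * ct + axv * st + ax * ad * (1 - ct)
  V2 / sqrt(rowSums(V2^2))
}

#' Generate unit vectors undergoing isotropic rotational diffusion
#'
#' Each vector performs rotational Brownian motion with diffusion coefficient
#' `D = 1/(6 tau_rot)`, so its second-Legendre orientational autocorrelation
#' decays as `exp(-t / tau_rot)` — the rigid-rotor law against which the
#' spectral-density pipeline is validated. The discrete step is a rotation
#' about a uniformly random axis by an angle drawn from
#' `N(0, sqrt(6 D dt)) = N(0, sqrt(dt / tau_rot))`, which makes each
#' body-frame angular-velocity component diffuse with variance `2 D dt`;
#' the leading discretization bias in the decay rate is `O(dt / tau_rot)`.
#'
#' @param tau_rot_ns overall rotational correlation time, ns (may be `Inf`
#'   for frozen vectors).
#' @param dt_ns time step, ns; must satisfy `dt <= tau_rot / 10`.
#' @param n_frames,n_vectors trajectory size.
#' @param seed integer seed.
#' @return a [vector_trajectory()] with `truth$tau_rot_ns` set.
#' @export
gen_rotational_diffusion <- function(tau_rot_ns, dt_ns, n_frames, n_vectors,
                                     seed) {
  if (!is.numeric(tau_rot_ns) || tau_rot_ns <= 0)
    stop_taildyn("tau_rot_ns must be > 0", "domain_error")
  if (is.finite(tau_rot_ns) && dt_ns > tau_rot_ns / 10)
    stop_taildyn("dt_ns too coarse: need dt <= tau_rot/10", "resolution_error")
  sigma <- if (is.finite(tau_rot_ns)) sqrt(dt_ns / tau_rot_ns) else 0
  U <- with_seed(seed, {
    V <- matrix(stats::rnorm(n_vectors * 3), n_vectors)
    V <- V / sqrt(rowSums(V^2))
    U <- array(NA_real_, c(n_frames, n_vectors, 3))
    U[1, , ] <- V
    block <- 10000L
    f <- 1L
    while (f < n_frames) {
      nb <- min(block, n_frames - f)
      Z <- matrix(stats::rnorm(nb * n_vectors * 4), ncol = 4)
      for (j in seq_len(nb)) {
        rows <- ((j - 1L) * n_vectors + 1L):(j * n_vectors)
        V <- rotate_step(V, Z[rows, 4] * sigma, Z[rows, 1:3, drop = FALSE])
        U[f + j, , ] <- V
      }
      f <- f + nb
    }
    U
  })
  vector_trajectory(U, dt_ns,
                    truth = list(model = "rotational_diffusion",
                                 tau_rot_ns = tau_rot_ns, seed = seed))
}

#' Cone half-angle matching a generalized order parameter
#'
#' Diffusion-in-a-cone mapping `S = cos(beta) (1 + cos(beta)) / 2`, solved
#' for the half-angle `beta` given `S^2`.
#'
#' @param S2 squared order parameter in `[0, 1]`.
#' @return cone half-angle in radians.
#' @export
cone_half_angle <- function(S2) {
  if (!is.numeric(S2) || any(S2 < 0) || any(S2 > 1))
    stop_taildyn("S2 must lie in [0, 1]", "domain_error")
  S <- sqrt(S2)
  acos((-1 + sqrt(1 + 8 * S)) / 2)
}

# Wobbling diffusion coefficient for which the diffusion-in-a-cone model has
# area-effective internal correlation time tau_e (Lipari-Szabo closed form).
cone_wobble_rate <- function(S2, tau_e_ns) {
  x <- cos(cone_half_angle(S2))
  if (x >= 1 - 1e-12) return(Inf)
  num <- -x^2 * (1 + x)^2 * (log((1 + x) / 2) + (1 - x) / 2) / (2 * (1 - x)) +
    (1 - x) * (6 + 8 * x - x^2 - 12 * x^3 - 7 * x^4) / 24
  num / ((1 - S2) * tau_e_ns)
}

#' Generate unit vectors with fast internal motion in a cone
#'
#' Vectors wobble (reflected Brownian motion) inside a cone whose half-angle
#' is chosen from `S2` via [cone_half_angle()], emulating internal tail
#' motion after the overall tumbling has been removed by core alignment. The
#' long-time plateau of the P2 autocorrelation is `S2`; the wobbling rate is
#' set from `tau_e_ns` through the Lipari-Szabo cone closed form, so the
#' initial decay time is approximately `tau_e_ns`.
#'
#' @param S2 target squared order parameter in `[0, 1]`.
#' @param tau_e_ns effective internal correlation time, ns (> 0).
#' @param dt_ns time step, ns.
#' @param n_frames,n_vectors trajectory size.
#' @param seed integer seed.
#' @return a [vector_trajectory()]; `truth` records `S2`, `tau_e_ns`, `beta`.
#' @export
gen_internal_motion <- function(S2, tau_e_ns, dt_ns, n_frames, n_vectors,
                                seed) {
  if (!is.numeric(S2) || S2 < 0 || S2 > 1)
    stop_taildyn("S2 must lie in [0, 1]", "domain_error")
  if (!is.numeric(tau_e_ns) || tau_e_ns <= 0)
    stop_taildyn("tau_e_ns must be > 0", "domain_error")
  beta <- cone_half_angle(S2)
  if (S2 >= 1 - 1e-12) {   # static limit
    U <- array(0, c(n_frames, n_vectors, 3)); U[, , 3] <- 1
    return(vector_trajectory(U, dt_ns,
                             truth = list(model = "cone", S2 = 1,
                                          tau_e_ns = tau_e_ns, seed = seed)))
  }
  Dw <- cone_wobble_rate(S2, tau_e_ns)           # rad^2 / ns
  s <- sqrt(2 * Dw * dt_ns)
  if (s > beta / 3)
    stop_taildyn("dt_ns too coarse for this cone (step exceeds beta/3)",
                 "resolution_error")
  U <- with_seed(seed, {
    cb <- cos(beta)
    ct0 <- 1 - stats::runif(n_vectors) * (1 - cb)   # uniform in cone
    th <- acos(ct0); ph <- stats::runif(n_vectors, 0, 2 * pi)
    V <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), ct0)
    U <- array(NA_real_, c(n_frames, n_vectors, 3))
    U[1, , ] <- V
    for (f in seq_len(n_frames - 1L)) {
      # tangent-plane Gaussian step
      e1 <- cbind(V[, 2], -V[, 1], 0)              # V x z
      n1 <- sqrt(rowSums(e1^2)); pole <- n1 < 1e-8
      if (any(pole)) { e1[pole, ] <- rep(c(1, 0, 0), each = sum(pole)); n1[pole] <- 1 }
      e1 <- e1 / n1
      e2 <- cbind(V[, 2] * e1[, 3] - V[, 3] * e1[, 2],
                  V[, 3] * e1[, 1] - V[, 1] * e1[, 3],
                  V[, 1] * e1[, 2] - V[, 2] * e1[, 1])
      V2 <- V + s * (stats::rnorm(n_vectors) * e1 + stats::rnorm(n_vectors) * e2)
      V2 <- V2 / sqrt(rowSums(V2^2))
      thn <- acos(pmin(1, pmax(-1, V2[, 3])))
      out <- thn > beta                            # reflect at the boundary
      if (any(out)) {
        thr <- abs(2 * beta - thn[out])
        p <- V2[out, 1:2, drop = FALSE]
        pn <- sqrt(rowSums(p^2)); pn[pn < 1e-12] <- 1
        p <- p / pn
        V2[out, 1] <- sin(thr) * p[, 1]
        V2[out, 2] <- sin(thr) * p[, 2]
        V2[out, 3] <- cos(thr)
      }
      V <- V2
      U[f + 1L, , ] <- V
    }
    U
  })
  vector_trajectory(U, dt_ns,
                    truth = list(model = "cone", S2 = S2, tau_e_ns = tau_e_ns,
                                 beta = beta, D_wobble = Dw, seed = seed))
}

#' Generate a two-state Markov bound/unbound contact timeline
#'
#' A hidden two-state Markov chain (bound/unbound, exponential dwell times
#' with rates `k_unbind`/`k_bind`) drives per-residue DNA contacts: in the
#' bound state each tail residue contacts DNA independently with probability
#' `p_contact_given_bound` per frame; in the unbound state with a 2% noise
#' floor of that probability, so that the <=10% full-tail state-calling rule
#' is exercised against nonzero background. The hidden state sequence is kept
#' as ground truth.
#'
#' The default `p_contact_given_bound = 0.5` keeps both misclassification
#' channels of the 10% rule negligible for a 36-residue tail (binomial tail
#' probabilities ~1e-7 bound-side, ~6e-4 unbound-side per frame).
#'
#' @param k_bind_per_ns,k_unbind_per_ns transition rates, 1/ns (> 0).
#' @param n_residues number of tail residues.
#' @param p_contact_given_bound per-residue per-frame contact probability in
#'   the bound state, in `(0, 1]`.
#' @param dt_ns frame stride, ns.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return a [contact_timeline()]; `truth` holds the hidden state sequence
#'   (`TRUE` = bound), rates and seed.
#' @export
gen_two_state_timeline <- function(k_bind_per_ns, k_unbind_per_ns,
                                   n_residues = 36,
                                   p_contact_given_bound = 0.5,
                                   dt_ns = 1, n_frames, seed) {
  if (k_bind_per_ns <= 0 || k_unbind_per_ns <= 0)
    stop_taildyn("rates must be > 0", "domain_error")
  if (p_contact_given_bound <= 0 || p_contact_given_bound > 1)
    stop_taildyn("p_contact_given_bound must be in (0, 1]", "domain_error")
  p_ub <- 1 - exp(-k_unbind_per_ns * dt_ns)   # bound -> unbound per frame
  p_bu <- 1 - exp(-k_bind_per_ns * dt_ns)     # unbound -> bound per frame
  states <- with_seed(child_seed(seed, 1), {
    st <- stats::runif(1) < k_bind_per_ns / (k_bind_per_ns + k_unbind_per_ns)
    vals <- logical(0); lens <- integer(0); total <- 0L
    while (total < n_frames) {
      n_new <- max(64L, ceiling((n_frames - total) * (p_ub + p_bu) / 2) + 16L)
      for (i in seq_len(n_new)) {
        d <- 1L + stats::rgeom(1, if (st) p_ub else p_bu)
        vals <- c(vals, st); lens <- c(lens, d); total <- total + d
        st <- !st
        if (total >= n_frames) break
      }
    }
    s <- inverse.rle(structure(list(lengths = lens, values = vals),
                               class = "rle"))
    s[seq_len(n_frames)]
  })
  p <- ifelse(states, p_contact_given_bound, 0.02 * p_contact_given_bound)
  counts <- with_seed(child_seed(seed, 2), {
    matrix(stats::rbinom(n_residues * n_frames, 1L, rep(p, each = n_residues)),
           nrow = n_residues)
  })
  contact_timeline(counts, stride_ns = dt_ns, residues = seq_len(n_residues),
                   copy = "sim",
                   truth = list(model = "two_state_markov",
                                k_bind_per_ns = k_bind_per_ns,
                                k_unbind_per_ns = k_unbind_per_ns,
                                p_contact_given_bound = p_contact_given_bound,
                                hidden_bound = states, seed = seed))
}

#' Relaxation delay schedules used in the 15N relaxation experiments
#'
#' The delay grids (in seconds, with the duplicated points retained as
#' independent observations) of the R1 and CPMG R2 experiments at 0 mM and
#' 100 mM NaCl.
#'
#' @param rate `"R1"` or `"R2"`.
#' @param salt `"0mM"` or `"100mM"`.
#' @return numeric vector of delays in seconds (repeats included).
#' @export
relaxation_delay_schedule <- function(rate = c("R1", "R2"),
                                      salt = c("0mM", "100mM")) {
  rate <- match.arg(rate); salt <- match.arg(salt)
  ms <- switch(paste(rate, salt),
    "R1 0mM" = c(10, 50, 50, 100, 200, 400, 500, 500, 800, 1000, 1250, 1250, 1500),
    "R1 100mM" = c(25, 200, 400, 400, 800, 1250, 1750),
    "R2 0mM" = c(15.68, 31.36, 31.36, 47.04, 78.4, 94.08, 94.08, 109.76,
                 125.44, 156.8, 188.16, 188.16, 203.4),
    "R2 100mM" = c(15.68, 31.36, 47.04, 47.04, 62.72, 94.08, 94.08, 109.76))
  ms / 1000
}

#' Generate single-exponential peak-intensity decays with Gaussian noise
#'
#' `I(t) = I0 exp(-R t) + N(0, noise_sd)`; duplicate delays receive
#' independent noise (they are what the repeat-scatter error estimate feeds
#' on).
#'
#' @param true_rates_per_s named numeric vector of decay rates, 1/s; names
#'   are residue identifiers.
#' @param delays_s delay grid in seconds (defaults to the 0 mM R1 schedule).
#' @param n_replicates independent replicate series per residue.
#' @param noise_sd Gaussian noise SD in intensity units.
#' @param i0 initial intensity.
#' @param seed integer seed.
#' @return data.frame with columns `residue`, `replicate`, `delay_s`,
#'   `is_repeat`, `intensity`; true rates kept in `attr(, "truth")`.
#' @export
gen_intensity_decays <- function(true_rates_per_s,
                                 delays_s = relaxation_delay_schedule("R1", "0mM"),
                                 n_replicates = 1, noise_sd = 0, i0 = 100,
                                 seed = 1) {
  if (any(true_rates_per_s < 0))
    stop_taildyn("rates must be >= 0", "domain_error")
  if (any(delays_s < 0))
    stop_taildyn("delays must be >= 0", "domain_error")
  res <- names(true_rates_per_s) %||% as.character(seq_along(true_rates_per_s))
  grid <- expand.grid(delay_s = delays_s, residue = res,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$is_repeat <- duplicated(delays_s)[match(grid$delay_s, delays_s)] |
    grid$delay_s %in% delays_s[duplicated(delays_s)]
  mu <- i0 * exp(-true_rates_per_s[grid$residue] * grid$delay_s)
  grid$intensity <- with_seed(seed, mu + stats::rnorm(nrow(grid), 0, noise_sd))
  grid <- grid[, c("residue", "replicate", "delay_s", "is_repeat", "intensity")]
  attr(grid, "truth") <- list(rates_per_s = true_rates_per_s, i0 = i0,
                              noise_sd = noise_sd, seed = seed)
  grid
}

#' Generate raw thermal-shift melt curves
#'
#' Raw fluorescence is a baseline plus a sum of logistic transitions,
#' `baseline + sum_k amplitude_k * plogis((T - Tm_k) / steepness_k)`, with
#' i.i.d. Gaussian noise per replicate; this emulates the one- or two-step
#' nucleosome disassembly profiles of the dye-binding assay. Ground-truth
#' midpoints are stored on the returned curve.
#'
#' @param transition_midpoints_C transition midpoints, degC (inside the grid).
#' @param steepnesses logistic widths, degC (recycled).
#' @param amplitudes transition amplitudes (recycled).
#' @param temp_grid_C strictly increasing temperature grid, degC.
#' @param noise_sd Gaussian noise SD (same units as the amplitudes).
#' @param n_replicates number of replicate curves.
#' @param baseline flat raw-fluorescence offset.
#' @param seed integer seed.
#' @return a [melt_curve()] carrying the raw replicate matrix and ground
#'   truth.
#' @export
gen_melt_curve <- function(transition_midpoints_C = c(72, 81),
                           steepnesses = 1, amplitudes = c(0.6, 0.4),
                           temp_grid_C = 25:95, noise_sd = 0,
                           n_replicates = 3, baseline = 0.05, seed = 1) {
  if (any(diff(temp_grid_C) <= 0))
    stop_taildyn("temperature grid must be strictly increasing", "grid_error")
  if (any(transition_midpoints_C < min(temp_grid_C)) ||
      any(transition_midpoints_C > max(temp_grid_C)))
    stop_taildyn("midpoints must lie inside the temperature grid", "domain_error")
  k <- length(transition_midpoints_C)
  steepnesses <- rep_len(steepnesses, k)
  amplitudes <- rep_len(amplitudes, k)
  sig <- baseline
  for (i in seq_len(k))
    sig <- sig + amplitudes[i] *
      stats::plogis((temp_grid_C - transition_midpoints_C[i]) / steepnesses[i])
  raw <- with_seed(seed, {
    vapply(seq_len(n_replicates),
           function(r) sig + stats::rnorm(length(temp_grid_C), 0, noise_sd),
           numeric(length(temp_grid_C)))
  })
  melt_curve(temp_grid_C, raw,
             truth = list(midpoints_C = transition_midpoints_C,
                          steepnesses = steepnesses, amplitudes = amplitudes,
                          noise_sd = noise_sd, seed = seed))
}

#' Generate a scripted toy nucleosome trajectory
#'
#' A pseudo-atomic fixture for the contact and network analyses: a static
#' double arc of "DNA" beads (two strands, shared base-pair indices), a small
#' static "core" of C-alpha beads, and one or two mobile "tail" chains whose
#' beads sit within contact range (< 4 A) of scripted DNA beads during
#' scripted bound windows and ~20 A away otherwise. No physics is emulated;
#' the bound/unbound schedule is the ground truth oracle.
#'
#' @param n_tail_beads beads per tail copy (>= 2).
#' @param n_dna_beads base pairs in the DNA arc (>= 2).
#' @param binding_mode `"always_bound"`, `"never_bound"`, `"alternating"`
#'   (100 ns bound / 100 ns unbound), or a logical vector of length
#'   `n_frames` (TRUE = bound).
#' @param n_frames,dt_ns trajectory size and stride.
#' @param two_copies emit a second tail copy (chain "B") on the opposite arc.
#' @param intra_contact optional `list(pair = c(i, j), fraction = f)`: in a
#'   seeded random fraction `f` of frames, tail bead `j` is placed 3 A from
#'   bead `i` (used to script a persistent intra-tail interaction).
#' @param seed integer seed.
#' @return a [trajectory_ensemble()] with selections `tail` (per copy),
#'   `core_ca` and `dna` attached, a `bp` column on the DNA atoms, and the
#'   schedule in `attr(, "truth")`.
#' @export
gen_toy_nucleosome <- function(n_tail_beads = 10, n_dna_beads = 24,
                               binding_mode = "always_bound",
                               n_frames = 200, dt_ns = 1, two_copies = TRUE,
                               intra_contact = NULL, seed = 1) {
  if (n_tail_beads < 2 || n_dna_beads < 2)
    stop_taildyn("bead counts must be >= 2", "domain_error")
  bound <- if (is.logical(binding_mode)) {
    if (length(binding_mode) != n_frames)
      stop_taildyn("logical binding_mode must have length n_frames", "domain_error")
    binding_mode
  } else switch(binding_mode,
    always_bound = rep(TRUE, n_frames),
    never_bound = rep(FALSE, n_frames),
    alternating = rep(rep(c(TRUE, FALSE), each = max(1L, round(100 / dt_ns))),
                      length.out = n_frames),
    stop_taildyn("unknown binding_mode", "domain_error"))

  # static DNA: two strands on concentric arcs, one bp index per position
  phi <- seq(0, 1.4 * pi, length.out = n_dna_beads)
  dna1 <- cbind(44 * cos(phi), 44 * sin(phi), 0)
  dna2 <- cbind(47 * cos(phi), 47 * sin(phi), 0)
  core <- rbind(c(0, 0, 8), c(6, 0, -4), c(-3, 5.2, -4), c(-3, -5.2, -4))
  n_copies <- if (two_copies) 2L else 1L

  atoms <- data.frame(
    eleno = integer(0), elety = character(0), elesy = character(0),
    resid = character(0), resno = integer(0), chain = character(0),
    bp = integer(0), stringsAsFactors = FALSE)
  add <- function(atoms, elety, elesy, resid, resno, chain, bp = NA_integer_) {
    n <- length(resno)
    rbind(atoms, data.frame(
      eleno = nrow(atoms) + seq_len(n), elety = rep_len(elety, n),
      elesy = rep_len(elesy, n), resid = rep_len(resid, n), resno = resno,
      chain = rep_len(chain, n), bp = rep_len(bp, n),
      stringsAsFactors = FALSE))
  }
  for (cp in seq_len(n_copies))
    atoms <- add(atoms, "CA", "C", "TLB", seq_len(n_tail_beads), LETTERS[cp])
  atoms <- add(atoms, "CA", "C", "COR", 1:4, "C")
  atoms <- add(atoms, "P", "P", "DN", seq_len(n_dna_beads), "I", seq_len(n_dna_beads))
  atoms <- add(atoms, "P", "P", "DN", seq_len(n_dna_beads), "J", seq_len(n_dna_beads))

  na <- nrow(atoms)
  coords <- array(NA_real_, c(n_frames, na, 3))
  tail_idx <- lapply(seq_len(n_copies),
                     function(cp) which(atoms$chain == LETTERS[cp]))
  core_idx <- which(atoms$chain == "C")
  dna_idx <- which(atoms$chain %in% c("I", "J"))
  static <- rbind(core, dna1, dna2)
  static_idx <- c(core_idx, dna_idx)

  # which DNA bead each tail bead tracks when bound (per copy: opposite ends)
  anchor <- lapply(seq_len(n_copies), function(cp) {
    if (cp == 1) (seq_len(n_tail_beads) - 1L) %% n_dna_beads + 1L
    else (n_dna_beads - seq_len(n_tail_beads)) %% n_dna_beads + 1L
  })

  jit <- with_seed(child_seed(seed, 3),
                   array(stats::runif(n_frames * n_copies * n_tail_beads * 3,
                                      -0.15, 0.15),
                         c(n_frames, n_copies * n_tail_beads, 3)))
  intra_frames <- logical(n_frames)
  if (!is.null(intra_contact)) {
    if (abs(diff(intra_contact$pair)) < 2)
      stop_taildyn("intra_contact pair must be non-adjacent", "domain_error")
    intra_frames <- with_seed(child_seed(seed, 4),
      seq_len(n_frames) %in% sample.int(n_frames,
                                        round(intra_contact$fraction * n_frames)))
  }

  for (f in seq_len(n_frames)) {
    coords[f, static_idx, ] <- static
    for (cp in seq_len(n_copies)) {
      base <- dna1[anchor[[cp]], , drop = FALSE]
      dir <- base / sqrt(rowSums(base^2))
      off <- if (bound[f]) 3.0 else 20
      pos <- base - dir * off          # inward of strand I
      pos[, 3] <- pos[, 3] + if (bound[f]) 0 else 6
      rows <- (cp - 1L) * n_tail_beads + seq_len(n_tail_beads)
      pos <- pos + jit[f, rows, , drop = TRUE]
      if (cp == 1 && intra_frames[f]) {
        i <- intra_contact$pair[1]; j <- intra_contact$pair[2]
        pos[j, ] <- pos[i, ] + c(3.0, 0, 0)
      }
      coords[f, tail_idx[[cp]], ] <- pos
    }
  }
  traj <- trajectory_ensemble(coords, atoms, dt_ns)
  traj <- set_selection(traj, "tail", stats::setNames(tail_idx,
                                                      LETTERS[seq_len(n_copies)]))
  traj <- set_selection(traj, "core_ca", core_idx)
  traj <- set_selection(traj, "dna", dna_idx)
  attr(traj, "truth") <- list(bound = bound, seed = seed,
                              intra_contact = intra_contact,
                              intra_frames = intra_frames,
                              n_copies = n_copies)
  traj
}
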