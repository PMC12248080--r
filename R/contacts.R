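# Tail-DNA contact detection and binding-kinetics statistics.
#
# A contact is a heavy-atom pair (one tail, one DNA atom) at distance
# strictly < 4 A, evaluated at a fixed stride (1 ns). The full tail is called
# unbound in a frame iff no more than 10% of its residues maintain at least
# one contact (inclusive threshold); maximal constant-state runs form
# binding/unbinding events; the frame-count ratio unbound/bound gives a
# dimensionless Kd and a standard binding free energy RT ln Kd at the
# simulation temperature.

#' Construct a contact timeline
#'
#' Boolean residue x frame contact matrix at fixed stride, plus the raw
#' per-cell atomic contact counts.
#'
#' @param counts integer matrix, residues x frames, of atomic contact counts.
#' @param stride_ns frame stride, ns (> 0).
#' @param residues residue identifiers (rownames).
#' @param copy tail-copy label.
#' @param res_bp_mean optional residues x base-pair matrix of per-frame mean
#'   atomic contacts (heat-map layer).
#' @param truth optional ground-truth list (synthetic data).
#' @return object of class `contact_timeline`.
#' @export
contact_timeline <- function(counts, stride_ns, residues = rownames(counts),
                             copy = "A", res_bp_mean = NULL, truth = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(stride_ns) || stride_ns <= 0)
    stop_taildyn("stride must be > 0", "domain_error")
  if (any(counts < 0)) stop_taildyn("counts must be >= 0", "domain_error")
  if (is.null(residues)) residues <- seq_len(nrow(counts))
  structure(list(counts = counts, contact = counts >= 1L,
                 stride_ns = stride_ns, residues = residues, copy = copy,
                 res_bp_mean = res_bp_mean, truth = truth),
            class = "contact_timeline")
}

#' @export
print.contact_timeline <- function(x, ...) {
  cat(sprintf("<contact_timeline> %d residues x %d frames @ %g ns (copy %s)\n",
              nrow(x$counts), ncol(x$counts), x$stride_ns, x$copy))
  invisible(x)
}

#' Detect tail-DNA atomic contacts along a trajectory
#'
#' Counts heavy-atom pairs at distance strictly below `cutoff_A` between each
#' tail residue and any DNA atom, for frames sampled every `stride_ns`.
#' Hydrogens are excluded; periodic images are not considered (the particle
#' is assumed whole in the box).
#'
#' @param traj a `traj_ensemble`.
#' @param tail_selection atom indices of one tail copy (or the name of a
#'   stored selection; a multi-part selection uses its first part unless
#'   `copy` names one).
#' @param dna_selection DNA atom indices or selection name.
#' @param cutoff_A contact cutoff, Angstrom (strict `<`).
#' @param stride_ns sampling stride, ns (multiple of the frame interval).
#' @param copy tail-copy label (also picks the part of a multi-part
#'   selection).
#' @return a [contact_timeline()]; per-residue x base-pair mean contact
#'   counts are attached when the DNA atoms carry a `bp` column.
#' @export
atomic_contacts <- function(traj, tail_selection = "tail",
                            dna_selection = "dna", cutoff_A = 4.0,
                            stride_ns = 1.0, copy = NULL) {
  if (is.character(tail_selection)) {
    sel <- traj$selections[[tail_selection]]
    if (is.list(sel)) sel <- sel[[copy %||% 1L]]
    tail_selection <- sel
  }
  if (is.character(dna_selection))
    dna_selection <- unlist(traj$selections[[dna_selection]], use.names = FALSE)
  if (!length(tail_selection) || !length(dna_selection))
    stop_taildyn("empty atom selection", "selection_error")
  a <- traj$atoms
  tail_selection <- tail_selection[a$heavy[tail_selection]]
  dna_selection <- dna_selection[a$heavy[dna_selection]]
  if (!length(tail_selection) || !length(dna_selection))
    stop_taildyn("selections contain no heavy atoms", "selection_error")

  dt <- traj$frame_interval_ns
  step <- stride_ns / dt
  if (abs(step - round(step)) > 1e-9 || step < 1)
    stop_taildyn("stride must be a positive multiple of the frame interval",
                 "domain_error")
  fidx <- seq(1L, n_frames(traj), by = round(step))

  res_key <- paste(a$chain[tail_selection], a$resno[tail_selection])
  res_fac <- factor(res_key, levels = unique(res_key))
  n_res <- nlevels(res_fac)
  bp <- a$bp[dna_selection] %||% rep(NA_integer_, length(dna_selection))
  have_bp <- !all(is.na(bp))
  if (have_bp) {
    bp_fac <- factor(bp)
    n_bp <- nlevels(bp_fac)
    rb_sum <- matrix(0, n_res, n_bp,
                     dimnames = list(unique(res_key), levels(bp_fac)))
  }

  counts <- matrix(0L, n_res, length(fidx),
                   dimnames = list(unique(res_key), NULL))
  cut2 <- cutoff_A^2
  for (j in seq_along(fidx)) {
    A <- traj$coords[fidx[j], tail_selection, , drop = TRUE]
    B <- traj$coords[fidx[j], dna_selection, , drop = TRUE]
    if (is.null(dim(A))) A <- matrix(A, ncol = 3)
    if (is.null(dim(B))) B <- matrix(B, ncol = 3)
    d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
    hit <- d2 < cut2                   # strict: d < cutoff
    counts[, j] <- as.integer(rowsum(rowSums(hit), res_fac, reorder = FALSE))
    if (have_bp) {
      per_bp <- t(rowsum(t(hit * 1), bp_fac, reorder = TRUE))
      rb_sum <- rb_sum + rowsum(per_bp, res_fac, reorder = FALSE)
    }
  }
  contact_timeline(counts, stride_ns = stride_ns, residues = unique(res_key),
                   copy = copy %||% "A",
                   res_bp_mean = if (have_bp) rb_sum / length(fidx) else NULL)
}

#' Contact statistics over runs and copies
#'
#' Mean atomic contact counts per tail residue and per DNA base pair, with
#' standard errors of the mean across independent timelines (runs x copies;
#' five runs with two tail copies give n = 10), plus the pooled
#' residue x base-pair heat map.
#'
#' @param timelines a single [contact_timeline()] or a list of them (one per
#'   run/copy), each carrying `res_bp_mean`.
#' @return list with data.frames `per_residue` (`residue`, `mean`, `sem`),
#'   `per_bp` (`bp`, `mean`, `sem`) and matrix `heatmap` (residue x bp, mean
#'   over timelines).
#' @export
contact_statistics <- function(timelines) {
  if (inherits(timelines, "contact_timeline")) timelines <- list(timelines)
  if (any(!vapply(timelines, function(x) !is.null(x$res_bp_mean), TRUE)))
    stop_taildyn("timeline lacks a base-pair map (no bp column on DNA atoms)",
                 "mapping_error")
  per_res <- vapply(timelines, function(tl) rowMeans(tl$counts),
                    numeric(nrow(timelines[[1]]$counts)))
  per_res <- matrix(per_res, nrow = nrow(timelines[[1]]$counts))
  n <- length(timelines)
  sem <- function(m) if (n > 1) apply(m, 1, stats::sd) / sqrt(n) else
    rep(0, nrow(m))
  maps <- lapply(timelines, `[[`, "res_bp_mean")
  heat <- Reduce(`+`, maps) / n
  per_bp <- vapply(maps, colSums, numeric(ncol(maps[[1]])))
  per_bp <- matrix(per_bp, nrow = ncol(maps[[1]]))
  list(
    per_residue = data.frame(residue = timelines[[1]]$residues,
                             mean = rowMeans(per_res), sem = sem(per_res),
                             stringsAsFactors = FALSE),
    per_bp = data.frame(bp = colnames(maps[[1]]), mean = rowMeans(per_bp),
                        sem = sem(per_bp), stringsAsFactors = FALSE),
    heatmap = heat, n = n)
}

#' Fraction of tail residues in DNA contact per frame
#'
#' @param timeline a [contact_timeline()].
#' @return numeric vector (one value per sampled frame) in `[0, 1]`:
#'   residues with >= 1 atomic contact over total tail residues.
#' @export
fraction_bound <- function(timeline) {
  if (!nrow(timeline$contact)) stop_taildyn("no residues", "selection_error")
  colMeans(timeline$contact)
}

#' Call bound/unbound states for the full tail
#'
#' A frame is unbound iff no more than `unbound_threshold` of the tail
#' residues maintain contacts with DNA — the threshold is inclusive, so a
#' fraction exactly at 10% is unbound.
#'
#' @param timeline a [contact_timeline()] (or a numeric vector of bound
#'   fractions with a `stride_ns` attribute).
#' @param unbound_threshold fraction in (0, 1).
#' @return character vector of `"bound"`/`"unbound"` per frame, with
#'   `stride_ns` attached as an attribute.
#' @export
call_states <- function(timeline, unbound_threshold = 0.10) {
  if (unbound_threshold <= 0 || unbound_threshold >= 1)
    stop_taildyn("threshold must be in (0, 1)", "domain_error")
  if (inherits(timeline, "contact_timeline")) {
    fr <- fraction_bound(timeline)
    stride <- timeline$stride_ns
  } else {
    fr <- as.numeric(timeline)
    stride <- attr(timeline, "stride_ns") %||% 1
  }
  st <- ifelse(fr <= unbound_threshold, "unbound", "bound")
  attr(st, "stride_ns") <- stride
  st
}

#' Segment a state sequence into binding/unbinding events
#'
#' Maximal constant-state runs become events tiling the timeline. Events
#' shorter than `min_duration_ns` are flagged as excluded from the reported
#' residence-time distribution (50 ns is taken as the time needed to
#' establish stable interactions), but the full tiling is retained and
#' unbound-to-bound transitions are counted without any duration filter —
#' transition counts and filtered residence times are separate quantities.
#'
#' @param states state sequence from [call_states()].
#' @param stride_ns frame stride, ns (default: the sequence's attribute).
#' @param min_duration_ns residence-time filter, ns.
#' @return object of class `binding_events`: `$events` data.frame (`state`,
#'   `start_ns`, `end_ns`, `duration_ns`, `kept`), `$transitions`
#'   (unbound->bound count), `$min_duration_ns`.
#' @export
detect_events <- function(states, stride_ns = NULL, min_duration_ns = 50) {
  if (!length(states)) stop_taildyn("empty state sequence", "domain_error")
  stride_ns <- stride_ns %||% attr(states, "stride_ns") %||% 1
  r <- rle(as.character(states))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  ev <- data.frame(state = r$values,
                   start_ns = starts * stride_ns,
                   end_ns = ends * stride_ns,
                   duration_ns = r$lengths * stride_ns,
                   stringsAsFactors = FALSE)
  ev$kept <- ev$duration_ns >= min_duration_ns
  trans <- sum(r$values[-length(r$values)] == "unbound" &
                 r$values[-1] == "bound")
  structure(list(events = ev, transitions = trans,
                 min_duration_ns = min_duration_ns, stride_ns = stride_ns),
            class = "binding_events")
}

#' @export
print.binding_events <- function(x, ...) {
  cat(sprintf("<binding_events> %d events (%d kept at >= %g ns), %d unbound->bound transitions\n",
              nrow(x$events), sum(x$events$kept), x$min_duration_ns,
              x$transitions))
  invisible(x)
}

#' Residence times from detected events
#'
#' @param events a `binding_events` object.
#' @param state `"bound"` or `"unbound"`.
#' @param filtered apply the minimum-duration filter (default TRUE).
#' @return numeric vector of residence times, ns.
#' @export
residence_times <- function(events, state = "bound", filtered = TRUE) {
  ev <- events$events
  ev <- ev[ev$state == state & (!filtered | ev$kept), , drop = FALSE]
  ev$duration_ns
}

#' Frame-count dissociation constant and standard binding free energy
#'
#' `Kd = frames unbound / frames bound` (dimensionless frame ratio) and
#' `dG0 = R T ln Kd` with R = 8.314 J/(mol K), reported in kJ/mol at the
#' simulation temperature (310 K). If either state has zero frames, Kd is
#' undefined and returned as `NA` together with the frame counts.
#'
#' @param states state sequence from [call_states()].
#' @param temperature_K temperature for dG0, K.
#' @return object of class `binding_stats`: `frames_bound`,
#'   `frames_unbound`, `Kd`, `dG0_kJ_mol`, `temperature_K`.
#' @export
binding_stats <- function(states, temperature_K = 310) {
  if (!length(states)) stop_taildyn("empty state sequence", "domain_error")
  nb <- sum(states == "bound"); nu <- sum(states == "unbound")
  if (nb == 0L || nu == 0L) {
    out <- list(frames_bound = nb, frames_unbound = nu, Kd = NA_real_,
                dG0_kJ_mol = NA_real_, temperature_K = temperature_K,
                undefined = TRUE)
  } else {
    Kd <- nu / nb
    out <- list(frames_bound = nb, frames_unbound = nu, Kd = Kd,
                dG0_kJ_mol = 8.314 * temperature_K * log(Kd) / 1000,
                temperature_K = temperature_K, undefined = FALSE)
  }
  structure(out, class = "binding_stats")
}

#' @export
print.binding_stats <- function(x, ...) {
  if (x$undefined)
    cat(sprintf("<binding_stats> Kd undefined (%d bound / %d unbound frames)\n",
                x$frames_bound, x$frames_unbound))
  else
    cat(sprintf("<binding_stats> Kd = %.4g (%d unbound / %d bound), dG0 = %.3f kJ/mol @ %g K\n",
                x$Kd, x$frames_unbound, x$frames_bound, x$dG0_kJ_mol,
                x$temperature_K))
  invisible(x)
}

#' Per-frame radius of gyration of a selection
#'
#' Mass-weighted Rg about the selection's center of mass, per frame, in
#' Angstrom.
#'
#' @param traj a `traj_ensemble`.
#' @param selection atom indices or stored selection name.
#' @param mass_weighted use atomic masses (default); otherwise unit masses.
#' @return numeric vector of Rg per frame, Angstrom.
#' @export
radius_of_gyration <- function(traj, selection, mass_weighted = TRUE) {
  if (is.character(selection))
    selection <- unlist(traj$selections[[selection]], use.names = FALSE)
  if (!length(selection)) stop_taildyn("empty selection", "selection_error")
  masses <- if (mass_weighted) atomic_mass(traj$atoms$elesy[selection])
            else rep(1, length(selection))
  w <- masses / sum(masses)
  vapply(seq_len(n_frames(traj)), function(f) {
    X <- traj$coords[f, selection, , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = 3)
    com <- colSums(X * w)
    sqrt(sum(w * rowSums(sweep(X, 2, com)^2)))
  }, 0)
}

# standard atomic masses for the elements that occur in protein/DNA systems
atomic_mass <- function(elesy) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
           S = 32.06)
  m <- tab[toupper(elesy)]
  if (any(is.na(m)))
    stop_taildyn(paste("no mass for element:",
                       paste(unique(elesy[is.na(m)]), collapse = ", ")),
                 "radius_table_error")
  unname(m)
}
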