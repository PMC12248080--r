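# Trajectory handling: loading, atom selection, superposition, windowing.
#
# Coordinates are stored in Angstrom, times in ns, throughout the package.
# Frames are conceptually 0-based: the time of stored frame k (1-based R
# index) is (k - 1) * frame_interval_ns after any equilibration cut, and the
# reference "initial structure" is the first stored frame.

#' Construct a trajectory ensemble
#'
#' The container every trajectory analysis consumes: a frames x atoms x 3
#' coordinate array (Angstrom), a fixed frame interval (ns), an atom table,
#' and named atom selections (e.g. tail residues per histone copy, core
#' C-alpha atoms, DNA heavy atoms).
#'
#' @param coords numeric array, frames x atoms x 3, in Angstrom.
#' @param atoms data.frame with one row per atom and columns `eleno`, `elety`
#'   (atom name), `elesy` (element symbol), `resid` (residue name), `resno`,
#'   `chain`. A logical `heavy` column is derived from `elesy` if absent; an
#'   optional integer `bp` column maps DNA nucleotides to base-pair positions
#'   (two nucleotides, one per strand, share one index).
#' @param frame_interval_ns time between consecutive frames, ns (> 0).
#' @param selections named list of integer atom-index vectors (optional;
#'   entries may themselves be lists of index vectors, e.g. one per tail copy).
#' @return an object of class `traj_ensemble`.
#' @seealso [load_trajectory()], [superpose_frames()], [discard_equilibration()]
#' @export
trajectory_ensemble <- function(coords, atoms, frame_interval_ns,
                                selections = list()) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop_taildyn("coords must be a frames x atoms x 3 array", "format_error")
  if (!is.data.frame(atoms) || nrow(atoms) != dim(coords)[2])
    stop_taildyn("atom table does not match coordinate atom count", "format_error")
  if (!is.numeric(frame_interval_ns) || frame_interval_ns <= 0)
    stop_taildyn("frame_interval_ns must be > 0", "domain_error")
  if (is.null(atoms$elesy) || any(!nzchar(atoms$elesy))) {
    guess <- toupper(substr(gsub("[^A-Za-z].*", "", atoms$elety), 1, 1))
    if (is.null(atoms$elesy)) atoms$elesy <- guess
    else atoms$elesy[!nzchar(atoms$elesy)] <- guess[!nzchar(atoms$elesy)]
  }
  if (is.null(atoms$heavy)) atoms$heavy <- toupper(atoms$elesy) != "H"
  flat <- unlist(selections, use.names = FALSE)
  if (length(flat) && (any(flat < 1) || any(flat > nrow(atoms))))
    stop_taildyn("selection refers to atoms outside the atom table",
                 "selection_error")
  structure(list(coords = coords, atoms = atoms,
                 frame_interval_ns = frame_interval_ns,
                 selections = selections),
            class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat(sprintf("<traj_ensemble> %d frames x %d atoms, dt = %g ns (%g ns total)\n",
              n_frames(x), nrow(x$atoms), x$frame_interval_ns,
              n_frames(x) * x$frame_interval_ns))
  if (length(x$selections))
    cat("  selections:", paste(names(x$selections), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `traj_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Frame times of a trajectory
#' @param traj a `traj_ensemble`.
#' @return numeric vector of frame times in ns; frame k (0-based) sits at
#'   k * frame interval.
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$frame_interval_ns

#' Load a trajectory from a PDB topology plus a DCD coordinate file
#'
#' The topology supplies the atom table (names, elements, residues, chains);
#' the binary container supplies the frames. Atom counts must agree.
#'
#' @param topology path to a PDB file.
#' @param coordinates path to a DCD trajectory file.
#' @param frame_interval_ns time between stored frames, ns.
#' @return a [trajectory_ensemble()] with heavy/hydrogen flags set from the
#'   element symbols and no selections (see [resolve_selections()]).
#' @export
load_trajectory <- function(topology, coordinates, frame_interval_ns) {
  if (!file.exists(topology))
    stop_taildyn(paste("cannot read topology:", topology), "io_error")
  if (!file.exists(coordinates))
    stop_taildyn(paste("cannot read coordinates:", coordinates), "io_error")
  pdb <- tryCatch(bio3d::read.pdb(topology),
                  error = function(e) stop_taildyn(
                    paste("topology not parseable as PDB:", conditionMessage(e)),
                    "io_error"))
  xyz <- tryCatch(bio3d::read.dcd(coordinates, verbose = FALSE),
                  error = function(e) stop_taildyn(
                    paste("unreadable trajectory container:", conditionMessage(e)),
                    "io_error"))
  na <- nrow(pdb$atom)
  if (ncol(xyz) != 3L * na)
    stop_taildyn(sprintf(
      "atom-count mismatch: topology has %d atoms, coordinates have %d",
      na, ncol(xyz) / 3), "format_error")
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, na, 3))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, 3L * na, by = 3L), drop = FALSE]
  atoms <- data.frame(eleno = pdb$atom$eleno, elety = pdb$atom$elety,
                      elesy = pdb$atom$elesy %||% "",
                      resid = pdb$atom$resid, resno = pdb$atom$resno,
                      chain = pdb$atom$chain, stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- ""
  trajectory_ensemble(coords, atoms, frame_interval_ns)
}

#' Write a trajectory as PDB topology plus DCD frames
#'
#' Counterpart of [load_trajectory()]; used by the synthetic-data generators
#' to emit fixtures in the formats the analysis entry points read. DCD stores
#' single-precision coordinates, so a round trip is lossless only to float32
#' resolution (~1e-5 relative).
#'
#' @param traj a `traj_ensemble`.
#' @param topology,coordinates output paths (PDB, DCD).
#' @return invisibly, the coordinate path.
#' @export
write_trajectory <- function(traj, topology, coordinates) {
  a <- traj$atoms
  bio3d::write.pdb(file = topology, xyz = as.numeric(t(traj$coords[1, , ])),
                   type = rep("ATOM", nrow(a)), eleno = a$eleno,
                   elety = a$elety, resid = a$resid, resno = a$resno,
                   chain = ifelse(nzchar(a$chain), a$chain, ""),
                   elesy = a$elesy)
  write_dcd(traj$coords, coordinates)
}

#' Write a coordinate array as a CHARMM-style DCD file
#'
#' @param coords frames x atoms x 3 array, Angstrom.
#' @param file output path.
#' @return invisibly, `file`.
#' @keywords internal
#' @export
write_dcd <- function(coords, file) {
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  con <- base::file(file, "wb")
  on.exit(close(con))
  rec <- function(writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  rec(function() {
    writeChar("CORD", con, 4, eos = NULL)
    writeBin(icntrl, con, size = 4, endian = "little")
  }, 84L)
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(sprintf("%-80s", "taildyn trajectory"), con, 80, eos = NULL)
  }, 84L)
  rec(function() writeBin(as.integer(na), con, size = 4, endian = "little"), 4L)
  for (f in seq_len(nf)) for (k in 1:3)
    rec(function() writeBin(as.numeric(coords[f, , k]), con, size = 4,
                            endian = "little"), 4L * na)
  invisible(file)
}

#' Select atoms by chain, residue, atom name, or element
#'
#' @param traj a `traj_ensemble`.
#' @param chain,resno,elety,elesy optional filters; `elety` accepts a regular
#'   expression, the others exact sets.
#' @param heavy_only drop hydrogens.
#' @return integer atom indices.
#' @export
select_atoms <- function(traj, chain = NULL, resno = NULL, elety = NULL,
                         elesy = NULL, heavy_only = FALSE) {
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & grepl(elety, a$elety)
  if (!is.null(elesy)) keep <- keep & toupper(a$elesy) %in% toupper(elesy)
  if (heavy_only) keep <- keep & a$heavy
  which(keep)
}

#' Attach a named selection to a trajectory
#' @param traj a `traj_ensemble`.
#' @param name selection name.
#' @param indices integer atom indices (or a list of index vectors, e.g. one
#'   per tail copy).
#' @return the modified trajectory.
#' @export
set_selection <- function(traj, name, indices) {
  flat <- unlist(indices, use.names = FALSE)
  if (!length(flat) || any(flat < 1) || any(flat > nrow(traj$atoms)))
    stop_taildyn("selection refers to atoms outside the atom table",
                 "selection_error")
  traj$selections[[name]] <- indices
  traj
}

#' Resolve selections from a configuration list or YAML file
#'
#' Config entries are residue ranges plus atom-name patterns, e.g.
#' `list(tail = list(copy1 = list(chain = "A", resno = 1:36)),
#'       core_ca = list(elety = "^CA$"), dna = list(chain = c("I", "J"),
#'       heavy_only = TRUE))`. Nested lists (without selector fields) produce
#' multi-part selections such as one tail per histone copy.
#'
#' @param traj a `traj_ensemble`.
#' @param config a named list, or path to a YAML file describing one.
#' @return the trajectory with selections attached.
#' @export
resolve_selections <- function(traj, config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_taildyn("the yaml package is required to read YAML configs", "io_error")
    config <- yaml::read_yaml(config)
  }
  selector_fields <- c("chain", "resno", "elety", "elesy", "heavy_only")
  resolve1 <- function(spec) {
    if (is.list(spec) && !any(names(spec) %in% selector_fields))
      return(lapply(spec, resolve1))
    idx <- do.call(select_atoms, c(list(traj = traj),
                                   spec[names(spec) %in% selector_fields]))
    if (!length(idx))
      stop_taildyn("selection resolves to an empty atom set", "selection_error")
    idx
  }
  for (nm in names(config)) traj <- set_selection(traj, nm, resolve1(config[[nm]]))
  traj
}

# Closed-form SVD (Kabsch) least-squares rigid-body fit of P onto Q.
# Reflections are rejected: only proper rotations are physical superpositions.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  if (s$d[2] <= max(s$d) * 1e-10)
    stop_taildyn("degenerate fit: fit atoms are (nearly) collinear",
                 "degenerate_fit_error")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, cp = cp, cq = cq)
}

#' Superpose all frames onto a reference frame
#'
#' Least-squares rigid-body fit (rotation + translation, Kabsch) of every
#' frame onto the reference over a fit selection — in the nucleosome pipeline
#' the C-alpha atoms of the globular histone cores, which removes the overall
#' tumbling/translation of the particle and leaves internal tail motion.
#' All atoms are transformed; RMSD is reported over the fit selection.
#'
#' @param traj a `traj_ensemble`.
#' @param reference_frame 1-based index of the reference ("initial structure"
#'   by default).
#' @param fit_selection integer atom indices, or the name of a stored
#'   selection; needs >= 3 non-collinear atoms.
#' @return an object of class `superposition`: `$trajectory` (transformed
#'   ensemble) and `$rmsd` (per-frame RMSD to the reference over the fit
#'   selection, Angstrom).
#' @export
superpose_frames <- function(traj, reference_frame = 1, fit_selection) {
  if (is.character(fit_selection))
    fit_selection <- unlist(traj$selections[[fit_selection]], use.names = FALSE)
  fit_selection <- as.integer(fit_selection)
  if (length(fit_selection) < 3)
    stop_taildyn("fit selection needs at least 3 atoms", "degenerate_fit_error")
  nf <- n_frames(traj)
  ref <- traj$coords[reference_frame, fit_selection, , drop = TRUE]
  # collinearity guard on the reference itself
  sv <- svd(sweep(ref, 2, colMeans(ref)))$d
  if (sv[2] <= max(sv) * 1e-8)
    stop_taildyn("degenerate fit: fit atoms are (nearly) collinear",
                 "degenerate_fit_error")
  out <- traj$coords
  rmsd <- numeric(nf)
  for (f in seq_len(nf)) {
    mob <- traj$coords[f, fit_selection, , drop = TRUE]
    k <- kabsch(mob, ref)
    all_c <- sweep(traj$coords[f, , , drop = TRUE], 2, k$cp)
    out[f, , ] <- sweep(all_c %*% t(k$R), 2, k$cq, `+`)
    fitd <- out[f, fit_selection, , drop = TRUE] - ref
    rmsd[f] <- sqrt(mean(rowSums(fitd^2)))
  }
  traj$coords <- out
  structure(list(trajectory = traj, rmsd = rmsd,
                 reference_frame = reference_frame,
                 fit_selection = fit_selection),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d frames fit on %d atoms; RMSD %.3f-%.3f A\n",
              length(x$rmsd), length(x$fit_selection),
              min(x$rmsd), max(x$rmsd)))
  invisible(x)
}

#' Discard equilibration frames
#'
#' Removes all frames with time < `cutoff_ns` (frame k, 0-based, sits at
#' k x interval). After the cut, times are re-zeroed so the retained frames
#' again start at 0.
#'
#' @param traj a `traj_ensemble`.
#' @param cutoff_ns equilibration time to drop, ns (>= 0).
#' @return the truncated ensemble; frame interval is preserved.
#' @export
discard_equilibration <- function(traj, cutoff_ns) {
  if (!is.numeric(cutoff_ns) || cutoff_ns < 0)
    stop_taildyn("cutoff_ns must be >= 0", "domain_error")
  keep <- frame_times(traj) >= cutoff_ns
  if (!any(keep))
    stop_taildyn("cutoff removes every frame", "empty_trajectory_error")
  traj$coords <- traj$coords[keep, , , drop = FALSE]
  traj
}
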