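# Residue-residue interaction networks from conformational ensembles: a
# geometric surrogate for full interaction-typing engines, restricted to the
# two classes actually displayed in tail contact maps — hydrogen bonds and
# van der Waals contacts. Edges carry a probability score, the fraction of
# ensemble frames in which the interaction is present.

# Bondi van der Waals radii (Angstrom)
vdw_radius <- function(elesy) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)
  r <- tab[toupper(elesy)]
  if (any(is.na(r)))
    stop_taildyn(paste("no van der Waals radius for element:",
                       paste(unique(elesy[is.na(r)]), collapse = ", ")),
                 "radius_table_error")
  unname(r)
}

#' Geometric criteria for interaction edges
#'
#' Van der Waals edge: any heavy-atom pair within the sum of Bondi radii plus
#' a tolerance (default 0.5 A). Hydrogen-bond edge: donor/acceptor N or O
#' heavy atoms within `hbond_dist_A`, and, when hydrogens are present in the
#' model, a donor-H...acceptor angle of at least `hbond_angle_deg`
#' (distance-only otherwise). All thresholds are configurable.
#'
#' @param vdw_tol_A tolerance added to the radius sum, Angstrom.
#' @param hbond_dist_A donor-acceptor distance cutoff, Angstrom.
#' @param hbond_angle_deg minimum donor-H...acceptor angle, degrees.
#' @return a criteria list consumed by [frame_edges()].
#' @export
edge_criteria <- function(vdw_tol_A = 0.5, hbond_dist_A = 3.5,
                          hbond_angle_deg = 120) {
  list(vdw_tol_A = vdw_tol_A, hbond_dist_A = hbond_dist_A,
       hbond_angle_deg = hbond_angle_deg)
}

#' Extract a conformational ensemble from trajectories
#'
#' Subsamples frames every `stride_ns` from each run and pools the tail
#' copies (the per-copy tail selections stored on each trajectory), yielding
#' the set of conformational states the network is built from — five 2000 ns
#' runs at 10 ns extraction with two copies give 2000 states.
#'
#' @param trajs a `traj_ensemble` or list of them (one per run), each with a
#'   multi-part `tail` selection.
#' @param stride_ns extraction stride, ns (>= frame interval, integer
#'   multiple).
#' @param combine_copies pool tail copies into one ensemble (default); when
#'   `FALSE`, a list of per-copy ensembles is returned.
#' @return object of class `conformation_ensemble`: `$conformations` (each a
#'   list with `xyz` and `atoms`), `$n_states`, `$stride_ns`.
#' @export
extract_ensemble <- function(trajs, stride_ns = 10, combine_copies = TRUE) {
  if (inherits(trajs, "traj_ensemble")) trajs <- list(trajs)
  dt <- trajs[[1]]$frame_interval_ns
  step <- stride_ns / dt
  if (step < 1 - 1e-9)
    stop_taildyn("stride finer than the frame interval", "stride_error")
  if (abs(step - round(step)) > 1e-9)
    stop_taildyn("stride must be an integer multiple of the frame interval",
                 "stride_error")
  step <- round(step)
  copies <- names(trajs[[1]]$selections$tail) %||%
    as.character(seq_along(trajs[[1]]$selections$tail))
  per_copy <- stats::setNames(vector("list", length(copies)), copies)
  for (tr in trajs) {
    fidx <- seq(step, n_frames(tr), by = step)
    for (ci in seq_along(copies)) {
      sel <- tr$selections$tail[[ci]]
      at <- tr$atoms[sel, , drop = FALSE]
      per_copy[[ci]] <- c(per_copy[[ci]], lapply(fidx, function(f) {
        xyz <- tr$coords[f, sel, , drop = TRUE]
        if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
        list(xyz = xyz, atoms = at)
      }))
    }
  }
  mk <- function(confs, label) structure(
    list(conformations = confs, n_states = length(confs),
         stride_ns = stride_ns, copies = label),
    class = "conformation_ensemble")
  if (combine_copies) mk(do.call(c, per_copy), copies)
  else lapply(copies, function(cp) mk(per_copy[[cp]], cp))
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf("<conformation_ensemble> %d states @ %g ns extraction (copies: %s)\n",
              x$n_states, x$stride_ns, paste(x$copies, collapse = ", ")))
  invisible(x)
}

#' Interaction edges present in one conformation
#'
#' Applies the geometric criteria to a single conformation and returns the
#' residue-pair edges by class. Self-pairs are never edges; adjacent-residue
#' pairs are kept here (they are masked only in reported contact maps).
#'
#' @param conformation list with `xyz` (atoms x 3) and `atoms` (table with
#'   `elesy`, `resno`, `heavy`).
#' @param criteria from [edge_criteria()].
#' @return data.frame with `res_i`, `res_j` (res_i < res_j) and `class`
#'   (`"vdw"`, `"hbond"`).
#' @export
frame_edges <- function(conformation, criteria = edge_criteria()) {
  at <- conformation$atoms
  xyz <- conformation$xyz
  heavy <- which(at$heavy)
  X <- xyz[heavy, , drop = FALSE]
  el <- at$elesy[heavy]
  resno <- at$resno[heavy]
  rad <- vdw_radius(el)
  n <- nrow(X)
  if (n < 2)
    return(data.frame(res_i = integer(0), res_j = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  D <- as.matrix(stats::dist(X))
  diff_res <- outer(resno, resno, `!=`)
  upper <- upper.tri(D)

  vdw_hit <- upper & diff_res & (D <= outer(rad, rad, `+`) + criteria$vdw_tol_A)

  dono <- toupper(el) %in% c("N", "O")
  hb_hit <- upper & diff_res & (D <= criteria$hbond_dist_A) &
    outer(dono, dono, `&`)
  if (any(hb_hit)) {
    hyd <- which(!at$heavy & toupper(at$elesy) == "H")
    if (length(hyd)) {
      XH <- xyz[hyd, , drop = FALSE]
      hres <- at$resno[hyd]
      cosmin <- cos(pi * (180 - criteria$hbond_angle_deg) / 180)
      idx <- which(hb_hit, arr.ind = TRUE)
      for (k in seq_len(nrow(idx))) {
        ok_pair <- FALSE
        for (ord in list(c(idx[k, 1], idx[k, 2]), c(idx[k, 2], idx[k, 1]))) {
          don <- ord[1]; acc <- ord[2]
          hh <- hyd[hres == resno[don]]
          if (!length(hh)) next
          XHd <- xyz[hh, , drop = FALSE]
          dh <- sqrt(rowSums(sweep(XHd, 2, X[don, ])^2))
          hh_on <- which(dh < 1.25)
          for (m in hh_on) {
            v1 <- X[don, ] - XHd[m, ]; v2 <- X[acc, ] - XHd[m, ]
            ca <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
            # angle donor-H...acceptor >= threshold <=> cos <= cos(threshold)
            if (ca <= cos(pi * criteria$hbond_angle_deg / 180)) {
              ok_pair <- TRUE; break
            }
          }
          if (ok_pair) break
        }
        if (!ok_pair) hb_hit[idx[k, 1], idx[k, 2]] <- FALSE
      }
    }
  }

  pair_df <- function(hit, cls) {
    if (!any(hit))
      return(data.frame(res_i = integer(0), res_j = integer(0),
                        class = character(0), stringsAsFactors = FALSE))
    ij <- which(hit, arr.ind = TRUE)
    ri <- pmin(resno[ij[, 1]], resno[ij[, 2]])
    rj <- pmax(resno[ij[, 1]], resno[ij[, 2]])
    u <- !duplicated(paste(ri, rj))
    data.frame(res_i = ri[u], res_j = rj[u], class = cls,
               stringsAsFactors = FALSE)
  }
  rbind(pair_df(vdw_hit, "vdw"), pair_df(hb_hit, "hbond"))
}

#' Edge probabilities over a conformational ensemble
#'
#' For every residue pair and interaction class, the probability score is the
#' fraction of ensemble frames in which the edge is present. Pairs never in
#' contact are absent from the graph (sparsity convention), not probability-0
#' entries.
#'
#' @param ensemble a `conformation_ensemble` from [extract_ensemble()].
#' @param criteria from [edge_criteria()].
#' @return object of class `interaction_graph`: `$edges` data.frame
#'   (`res_i`, `res_j`, `class`, `probability`), `$n_states`, `$stride_ns`.
#' @export
edge_probabilities <- function(ensemble, criteria = edge_criteria()) {
  if (!length(ensemble$conformations))
    stop_taildyn("empty ensemble", "domain_error")
  tallies <- new.env(parent = emptyenv())
  for (conf in ensemble$conformations) {
    ed <- frame_edges(conf, criteria)
    if (!nrow(ed)) next
    keys <- paste(ed$res_i, ed$res_j, ed$class, sep = "|")
    for (k in keys) assign(k, (get0(k, envir = tallies) %||% 0) + 1,
                           envir = tallies)
  }
  keys <- ls(tallies)
  if (!length(keys)) {
    edges <- data.frame(res_i = integer(0), res_j = integer(0),
                        class = character(0), probability = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    edges <- data.frame(res_i = as.integer(parts[, 1]),
                        res_j = as.integer(parts[, 2]),
                        class = parts[, 3],
                        probability = vapply(keys, get0, 0, envir = tallies) /
                          ensemble$n_states,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$res_i, edges$res_j, edges$class), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, n_states = ensemble$n_states,
                 stride_ns = ensemble$stride_ns),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d edges over %d states\n",
              nrow(x$edges), x$n_states))
  invisible(x)
}

#' Node degrees of an interaction graph
#'
#' The degree of a node is the sum of the probability scores of all edges
#' incident on it, across interaction classes; nodes are returned ranked in
#' descending degree. Highly connected nodes are residues with many
#' non-covalent partners in the ensemble.
#'
#' @param graph an `interaction_graph`.
#' @return data.frame `residue`, `degree`, sorted descending.
#' @export
node_degree <- function(graph) {
  e <- graph$edges
  nodes <- sort(unique(c(e$res_i, e$res_j)))
  deg <- vapply(nodes, function(r)
    sum(e$probability[e$res_i == r | e$res_j == r]), 0)
  out <- data.frame(residue = nodes, degree = deg)
  out[order(-out$degree, out$residue), , drop = FALSE]
}

#' Residue-residue contact probability map
#'
#' Symmetric residue x residue matrix of edge probabilities for one
#' interaction class. Cells for adjacent residues (|i - j| <= 1, including
#' the diagonal) are masked as `NA` — trivially-in-contact neighbours are
#' ignored in reported maps — and never-interacting pairs are 0 (rendered
#' white).
#'
#' @param graph an `interaction_graph`.
#' @param class `"vdw"` or `"hbond"`.
#' @param residues residue range for the matrix axes; defaults to the span
#'   of residues appearing in the graph.
#' @return numeric matrix with dimnames = residues.
#' @export
contact_probability_map <- function(graph, class = c("vdw", "hbond"),
                                    residues = NULL) {
  class <- match.arg(class)
  e <- graph$edges[graph$edges$class == class, , drop = FALSE]
  if (is.null(residues)) {
    rng <- range(c(graph$edges$res_i, graph$edges$res_j, 1L))
    residues <- seq(rng[1], rng[2])
  }
  n <- length(residues)
  M <- matrix(0, n, n, dimnames = list(residues, residues))
  for (k in seq_len(nrow(e))) {
    i <- match(e$res_i[k], residues); j <- match(e$res_j[k], residues)
    if (is.na(i) || is.na(j)) next
    M[i, j] <- M[j, i] <- e$probability[k]
  }
  adj <- abs(outer(residues, residues, `-`)) <= 1
  M[adj] <- NA_real_
  M
}
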