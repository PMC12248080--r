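# fixture builders shared across test files; everything is generated in code

# minimal trajectory ensemble from a frames x atoms x 3 array
make_ensemble <- function(coords, elesy = "C", chain = "A", resno = NULL,
                          dt = 1, elety = "CA", bp = NULL) {
  na <- dim(coords)[2]
  atoms <- data.frame(
    eleno = seq_len(na),
    elety = rep_len(elety, na),
    elesy = rep_len(elesy, na),
    resid = "RES",
    resno = resno %||% seq_len(na),
    chain = rep_len(chain, na),
    stringsAsFactors = FALSE)
  if (!is.null(bp)) atoms$bp <- bp
  trajectory_ensemble(coords, atoms, dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# synthetic correlation function object
make_corr <- function(lag_ns, value, tumbling_applied = FALSE,
                      tau_rot_ns = NA_real_) {
  taildyn:::new_corr_fn(lag_ns, value, 1L, 1L,
                        tumbling_applied = tumbling_applied,
                        tau_rot_ns = tau_rot_ns)
}

# random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# single conformation for network tests
make_conformation <- function(xyz, elesy, resno, heavy = NULL) {
  atoms <- data.frame(
    eleno = seq_len(nrow(xyz)), elety = elesy, elesy = elesy,
    resid = "RES", resno = resno, chain = "A",
    heavy = heavy %||% (toupper(elesy) != "H"), stringsAsFactors = FALSE)
  list(xyz = xyz, atoms = atoms)
}
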