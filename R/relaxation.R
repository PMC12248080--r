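# Experiment-side NMR analysis: chemical shift perturbations from peak
# positions, R1/R2 from intensity decays, and effective rotational
# correlation times from R2/R1 with first-order error propagation.

#' Combined 1H/15N chemical shift perturbation
#'
#' The weighted Euclidean displacement of an amide peak between two
#' conditions, `sqrt(dH^2 + 0.154 dN^2)` (ppm), the usual nitrogen scaling
#' reflecting the narrower 1H shift range.
#'
#' @param delta_H_ppm,delta_N_ppm 1H and 15N shift differences, ppm
#'   (vectorized).
#' @return combined shift perturbation, ppm.
#' @export
compute_csp <- function(delta_H_ppm, delta_N_ppm) {
  if (any(!is.finite(delta_H_ppm)) || any(!is.finite(delta_N_ppm)))
    stop_taildyn("shift differences must be finite", "domain_error")
  sqrt(delta_H_ppm^2 + 0.154 * delta_N_ppm^2)
}

#' Fit a single-exponential decay without offset
#'
#' Least-squares fit of `I(t) = I0 exp(-R t)` (two parameters, no offset) to
#' amide peak intensities over a relaxation delay grid, as used to extract
#' R1 and R2. Fitting is done on the intensities themselves (not their
#' logarithm). Two uncertainty estimates are reported: `sigma` from the fit
#' covariance (residual-based) and `sigma_repeat` from the scatter of
#' duplicated delay points propagated through the fit Jacobian (`NA` when the
#' grid has no repeats).
#'
#' @param series data.frame with columns `delay_s` and `intensity`, or a
#'   numeric vector of delays when `intensities` is given separately.
#' @param intensities optional numeric vector paired with `series` as delays.
#' @return list with `rate_per_s`, `sigma`, `sigma_repeat`, `i0`, `fitted`.
#' @export
fit_decay_rate <- function(series, intensities = NULL) {
  if (is.data.frame(series)) {
    t <- series$delay_s; y <- series$intensity
  } else {
    t <- as.numeric(series); y <- as.numeric(intensities)
  }
  if (length(t) != length(y) || length(t) < 4)
    stop_taildyn("need >= 4 (delay, intensity) points", "domain_error")
  if (length(unique(t)) < 4)
    stop_taildyn("need >= 4 distinct delays", "domain_error")
  if (any(!is.finite(t)) || any(!is.finite(y)))
    stop_taildyn("delays and intensities must be finite", "domain_error")

  rep_sd <- NA_real_
  if (anyDuplicated(t)) {
    sp <- split(y, t)
    sp <- sp[lengths(sp) > 1]
    ss <- sum(vapply(sp, function(v) sum((v - mean(v))^2), 0))
    df <- sum(lengths(sp) - 1L)
    if (df > 0) rep_sd <- sqrt(ss / df)
  }

  if (diff(range(y)) == 0) {          # flat series: R = 0 exactly
    return(list(rate_per_s = 0, sigma = 0,
                sigma_repeat = if (is.na(rep_sd)) NA_real_ else 0,
                i0 = y[1], fitted = y))
  }

  ypos <- pmax(y, max(abs(y)) * 1e-6)
  init <- stats::coef(stats::lm(log(ypos) ~ t))
  start <- list(I0 = exp(init[[1]]), R = max(-init[[2]], 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * exp(-R * t), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_taildyn(
      paste("exponential fit did not converge:", conditionMessage(e)),
      "fit_error"))
  co <- summary(fit)$coefficients
  i0 <- co["I0", "Estimate"]; R <- co["R", "Estimate"]
  sigma_cov <- co["R", "Std. Error"]

  sigma_rep <- NA_real_
  if (!is.na(rep_sd)) {
    J <- cbind(exp(-R * t), -i0 * t * exp(-R * t))
    V <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(V)) sigma_rep <- rep_sd * sqrt(V[2, 2])
  }
  list(rate_per_s = R, sigma = sigma_cov, sigma_repeat = sigma_rep,
       i0 = i0, fitted = stats::fitted(fit))
}

#' Effective rotational correlation time from R2/R1
#'
#' `tau_c = sqrt(6 R2/R1 - 7) / (4 pi nu_N)`, the standard high-field
#' estimator of the per-residue effective correlation time, with `nu_N` the
#' 15N resonance frequency in Hz (60.8e6 on a 600 MHz spectrometer).
#' Uncertainties in R1 and R2 are propagated first to the ratio and then
#' through the square root (first order).
#'
#' @param R1,R2 relaxation rates, 1/s (vectorized).
#' @param sigma_R1,sigma_R2 rate uncertainties, 1/s.
#' @param nu_N_Hz 15N resonance frequency, Hz.
#' @return list with `tau_c_ns` and `sigma_ns` (both in ns). For scalar input
#'   a negative discriminant (6 R2/R1 - 7 < 0, tumbling too fast for the
#'   estimator) is an error; for vector input such entries are returned as
#'   `NA` with a warning.
#' @export
tau_c_from_rates <- function(R1, R2, sigma_R1 = 0, sigma_R2 = 0,
                             nu_N_Hz = 60.8e6) {
  if (any(R1 <= 0, na.rm = TRUE))
    stop_taildyn("R1 must be > 0", "domain_error")
  ratio <- R2 / R1
  disc <- 6 * ratio - 7
  bad <- !is.na(disc) & disc < 0
  if (any(bad)) {
    if (length(disc) == 1)
      stop_taildyn("6 R2/R1 - 7 < 0: tumbling too fast for this estimator",
                   "fast_tumbling_error")
    warning("6 R2/R1 - 7 < 0 for ", sum(bad),
            " entries; tau_c returned as NA there")
    disc[bad] <- NA_real_
  }
  tau_s <- sqrt(disc) / (4 * pi * nu_N_Hz)
  s_ratio <- ratio * sqrt((sigma_R1 / R1)^2 + (sigma_R2 / R2)^2)
  sigma_s <- ifelse(disc > 0,
                    3 * s_ratio / (4 * pi * nu_N_Hz * sqrt(disc)),
                    ifelse(disc == 0, Inf, NA_real_))
  list(tau_c_ns = tau_s * 1e9, sigma_ns = sigma_s * 1e9)
}

#' Per-residue chemical shift perturbation profile between two conditions
#'
#' Combines two peak tables (e.g. wild type vs mutant) into a per-residue
#' CSP profile via [compute_csp()]. Residues present in only one table are
#' flagged rather than silently zeroed — prolines have no backbone amide and
#' exchange-broadened peaks go missing, and both must stay visible as gaps.
#'
#' @param table_a,table_b data.frames with columns `residue`, `h_ppm`,
#'   `n_ppm` (see [read_peak_table()]).
#' @return data.frame with `residue`, `csp_ppm` and `status`
#'   (`"ok"`, `"missing_in_a"`, `"missing_in_b"`).
#' @export
csp_profile <- function(table_a, table_b) {
  shared <- intersect(table_a$residue, table_b$residue)
  if (!length(shared))
    stop_taildyn("the two peak tables share no residues", "alignment_error")
  if (anyDuplicated(table_a$residue) || anyDuplicated(table_b$residue))
    stop_taildyn("residue identifiers must be unique per condition",
                 "format_error")
  all_res <- union(table_a$residue, table_b$residue)
  ia <- match(all_res, table_a$residue)
  ib <- match(all_res, table_b$residue)
  status <- ifelse(is.na(ia), "missing_in_a",
                   ifelse(is.na(ib), "missing_in_b", "ok"))
  csp <- rep(NA_real_, length(all_res))
  ok <- status == "ok"
  csp[ok] <- compute_csp(table_a$h_ppm[ia[ok]] - table_b$h_ppm[ib[ok]],
                         table_a$n_ppm[ia[ok]] - table_b$n_ppm[ib[ok]])
  out <- data.frame(residue = all_res, csp_ppm = csp, status = status,
                    stringsAsFactors = FALSE)
  out[order(suppressWarnings(as.numeric(out$residue)), out$residue), ,
      drop = FALSE]
}

#' Read a peak table (residue, 1H ppm, 15N ppm) from delimited text
#' @param file path; comma- or tab-delimited with a header naming columns
#'   `residue`, `h_ppm`, `n_ppm`.
#' @return data.frame.
#' @export
read_peak_table <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 1)
    tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("residue", "h_ppm", "n_ppm")
  if (!all(need %in% names(tab)))
    stop_taildyn("peak table needs columns residue, h_ppm, n_ppm",
                 "format_error")
  tab
}

#' Read an intensity-decay table (residue, delay_s, intensity)
#' @param file path; comma- or tab-delimited with a header.
#' @return data.frame.
#' @export
read_decay_table <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 1)
    tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("residue", "delay_s", "intensity")
  if (!all(need %in% names(tab)))
    stop_taildyn("decay table needs columns residue, delay_s, intensity",
                 "format_error")
  tab
}

#' Per-residue relaxation analysis from decay tables
#'
#' Fits R1 and R2 per residue from two decay tables and derives R2/R1 and
#' tau_c with propagated uncertainties — the experiment-side record that the
#' trajectory-side predictions are compared against.
#'
#' @param r1_table,r2_table data.frames with columns `residue`, `delay_s`,
#'   `intensity` (one series per residue).
#' @param nu_N_Hz 15N resonance frequency, Hz.
#' @return data.frame with one row per residue: `R1`, `sigma_R1`, `R2`,
#'   `sigma_R2`, `ratio`, `sigma_ratio`, `tau_c_ns`, `sigma_tau_ns`,
#'   `nu_N_Hz`.
#' @export
relaxation_record <- function(r1_table, r2_table, nu_N_Hz = 60.8e6) {
  res <- intersect(unique(r1_table$residue), unique(r2_table$residue))
  if (!length(res))
    stop_taildyn("tables share no residues", "alignment_error")
  one <- function(tab, r) fit_decay_rate(tab[tab$residue == r, , drop = FALSE])
  out <- lapply(res, function(r) {
    f1 <- one(r1_table, r); f2 <- one(r2_table, r)
    ratio <- f2$rate_per_s / f1$rate_per_s
    s_ratio <- ratio * sqrt((f1$sigma / f1$rate_per_s)^2 +
                            (f2$sigma / f2$rate_per_s)^2)
    tc <- tryCatch(tau_c_from_rates(f1$rate_per_s, f2$rate_per_s,
                                    f1$sigma, f2$sigma, nu_N_Hz),
                   error = function(e) list(tau_c_ns = NA_real_,
                                            sigma_ns = NA_real_))
    data.frame(residue = r, R1 = f1$rate_per_s, sigma_R1 = f1$sigma,
               R2 = f2$rate_per_s, sigma_R2 = f2$sigma,
               ratio = ratio, sigma_ratio = s_ratio,
               tau_c_ns = tc$tau_c_ns, sigma_tau_ns = tc$sigma_ns,
               nu_N_Hz = nu_N_Hz, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
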