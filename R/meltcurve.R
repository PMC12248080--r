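# Thermal shift assay analysis: min/max normalization per replicate,
# forward-difference derivative assigned to the upper temperature, peak
# detection with a prominence floor, replicate aggregation.

#' Construct a melt curve
#'
#' @param temp_C ascending temperature grid, degC.
#' @param raw raw fluorescence (RFU): numeric vector or matrix with one
#'   column per replicate.
#' @param truth optional ground-truth list (synthetic curves).
#' @return object of class `melt_curve`.
#' @export
melt_curve <- function(temp_C, raw, truth = NULL) {
  raw <- as.matrix(raw)
  if (any(diff(temp_C) <= 0))
    stop_taildyn("temperature grid must be strictly ascending", "grid_error")
  if (nrow(raw) != length(temp_C))
    stop_taildyn("raw fluorescence rows must match the temperature grid",
                 "grid_error")
  structure(list(temp_C = temp_C, raw = raw, truth = truth),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> %d temperatures (%g-%g degC), %d replicate(s)\n",
              length(x$temp_C), min(x$temp_C), max(x$temp_C), ncol(x$raw)))
  if (!is.null(x$tm)) cat("  detected Tm:", paste(x$tm, collapse = ", "), "degC\n")
  invisible(x)
}

#' Min/max-normalize melt curves
#'
#' `(RFU - RFU_min) / (RFU_max - RFU_min)` per replicate, with the minimum
#' and maximum taken over that replicate's full temperature range — so every
#' normalized replicate spans exactly 0 to 1.
#'
#' @param raw numeric vector or matrix (temperatures x replicates).
#' @param temp_C matching temperature grid (only used for validation).
#' @return normalized series, same shape as `raw`.
#' @export
normalize_curve <- function(raw, temp_C = NULL) {
  m <- as.matrix(raw)
  if (nrow(m) < 3)
    stop_taildyn("need at least 3 temperature points", "grid_error")
  if (!is.null(temp_C) && any(diff(temp_C) <= 0))
    stop_taildyn("temperature grid must be strictly ascending", "grid_error")
  out <- apply(m, 2, function(v) {
    rng <- range(v)
    if (diff(rng) == 0)
      stop_taildyn("constant curve: degenerate fluorescence range",
                   "degenerate_range_error")
    (v - rng[1]) / diff(rng)
  })
  if (is.null(dim(raw))) out[, 1] else out
}

#' Forward-difference derivative of a normalized melt curve
#'
#' `(f(T[i+1]) - f(T[i])) / (T[i+1] - T[i])`, with each value assigned to the
#' upper temperature `T[i+1]` — note this convention can shift detected peak
#' positions by one grid step upwards.
#'
#' @param normalized numeric vector or matrix (temperatures x replicates).
#' @param temp_C ascending temperature grid.
#' @return list with `temp_C` (grid without its first point) and `value`
#'   (same shape as the input minus one row).
#' @export
derivative_curve <- function(normalized, temp_C) {
  if (any(diff(temp_C) <= 0))
    stop_taildyn("temperature grid must be strictly ascending", "grid_error")
  m <- as.matrix(normalized)
  if (nrow(m) != length(temp_C))
    stop_taildyn("series length must match the temperature grid", "grid_error")
  dv <- apply(m, 2, function(v) diff(v) / diff(temp_C))
  list(temp_C = temp_C[-1],
       value = if (is.null(dim(normalized))) dv[, 1] else dv)
}

# boxcar smoothing with shrinking windows at the edges
boxcar <- function(v, window) {
  if (window <= 1) return(v)
  n <- length(v)
  h <- window %/% 2
  vapply(seq_len(n), function(i)
    mean(v[max(1, i - h):min(n, i + h)]), 0)
}

#' Detect melting temperatures from a derivative curve
#'
#' Local maxima of the derivative whose prominence (height above the higher
#' of the two flanking minima, descending until a higher point) reaches
#' `min_prominence`. The derivative is lightly boxcar-smoothed before peak
#' picking (instrument noise otherwise seeds spurious single-point maxima);
#' Tm values are reported on the original grid, ascending. The default
#' prominence floor — 20% of the smoothed derivative's global maximum — also
#' suppresses a strongly attenuated second transition, reproducing the
#' one-peak readout of high-salt disassembly profiles. No qualifying peak
#' yields an empty result, not an error.
#'
#' @param derivative list from [derivative_curve()] (or a numeric vector
#'   when `temp_C` is supplied).
#' @param min_prominence absolute prominence floor; default
#'   `0.2 * max(smoothed derivative)`.
#' @param temp_C temperatures for a bare numeric `derivative`.
#' @param smooth_window boxcar window in grid steps (default 5; 1 disables).
#' @return numeric vector of melting temperatures, degC, ascending.
#' @export
find_tm <- function(derivative, min_prominence = NULL, temp_C = NULL,
                    smooth_window = 5) {
  if (is.list(derivative)) {
    temps <- derivative$temp_C
    dv <- derivative$value
  } else {
    temps <- temp_C
    dv <- derivative
  }
  if (is.matrix(dv)) dv <- rowMeans(dv)
  if (!length(dv)) stop_taildyn("empty derivative series", "domain_error")
  # shrink the window for short series so smoothing never flattens the peak
  eff_window <- min(smooth_window, 2 * (length(dv) %/% 8) + 1)
  dv <- boxcar(dv, eff_window)
  if (is.null(min_prominence)) min_prominence <- 0.2 * max(dv)
  n <- length(dv)
  if (n < 3) return(numeric(0))
  tm <- numeric(0)
  for (i in 2:(n - 1)) {
    if (!(dv[i] >= dv[i - 1] && dv[i] > dv[i + 1])) next
    left <- dv[1:i]; right <- dv[i:n]
    hiL <- which(left > dv[i]); hiR <- which(right > dv[i])
    minL <- if (length(hiL)) min(left[max(hiL):i]) else min(left)
    minR <- if (length(hiR)) min(right[1:min(hiR)]) else min(right)
    if (dv[i] - max(minL, minR) >= min_prominence) tm <- c(tm, temps[i])
  }
  sort(tm)
}

#' Aggregate replicate melt curves
#'
#' Pointwise mean and SD of the normalized replicates on a shared grid, with
#' melting temperatures detected on the derivative of the mean curve.
#'
#' @param curves a [melt_curve()] with >= 2 replicates, or a list of
#'   single-replicate `melt_curve`s on identical grids.
#' @param ... passed to [find_tm()].
#' @return list with `temp_C`, `mean`, `sd` (normalized scale),
#'   `derivative` (of the mean) and `tm`.
#' @export
aggregate_replicates <- function(curves, ...) {
  if (inherits(curves, "melt_curve")) {
    temps <- curves$temp_C; raw <- curves$raw
  } else {
    grids <- lapply(curves, `[[`, "temp_C")
    if (!all(vapply(grids[-1], identical, TRUE, grids[[1]])))
      stop_taildyn("replicates are on different temperature grids",
                   "grid_error")
    temps <- grids[[1]]
    raw <- do.call(cbind, lapply(curves, `[[`, "raw"))
  }
  if (ncol(raw) < 2)
    stop_taildyn("need at least 2 replicates", "domain_error")
  nrm <- normalize_curve(raw, temps)
  mu <- rowMeans(nrm)
  dv <- derivative_curve(mu, temps)
  list(temp_C = temps, mean = mu, sd = apply(nrm, 1, stats::sd),
       derivative = dv, tm = find_tm(dv, ...))
}

#' Full single-object melt-curve analysis
#'
#' Normalizes each replicate, computes derivatives, detects per-replicate
#' and pooled Tm values, and returns the enriched `melt_curve`.
#'
#' @param mc a [melt_curve()].
#' @param ... passed to [find_tm()].
#' @return the `melt_curve` with `$normalized`, `$derivative`, `$tm`
#'   (pooled) and `$tm_replicates` filled in.
#' @export
analyze_melt_curve <- function(mc, ...) {
  mc$normalized <- normalize_curve(mc$raw, mc$temp_C)
  mc$derivative <- derivative_curve(mc$normalized, mc$temp_C)
  nrep <- ncol(mc$raw)
  mc$tm_replicates <- lapply(seq_len(nrep), function(r)
    find_tm(list(temp_C = mc$derivative$temp_C,
                 value = as.matrix(mc$derivative$value)[, r]), ...))
  mc$tm <- if (nrep >= 2) aggregate_replicates(mc, ...)$tm
           else mc$tm_replicates[[1]]
  mc
}

#' Read a melt-curve table (temperature plus replicate RFU columns)
#' @param file delimited text with header: first column `temperature_C`,
#'   remaining columns one replicate each.
#' @return a [melt_curve()].
#' @export
read_melt_table <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 1) tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop_taildyn("melt table needs a temperature column plus >= 1 replicate",
                 "format_error")
  melt_curve(tab[[1]], as.matrix(tab[, -1, drop = FALSE]))
}
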