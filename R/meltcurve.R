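## Saturation-dye melt-curve simulation over the 65-90 degC instrument ramp,
## Savitzky-Golay-smoothed negative-derivative curves, and prominence-based
## peak calling.  Each melt transition is a two-state logistic in helicity;
## multi-peak species are modelled as weighted mixtures of transitions
## without claiming a mechanism.

#' Melt-curve simulation configuration
#'
#' The analysis grid default of 0.01 degrees Celsius makes the instrument's
#' +/- 0.02 degree resolution representable (the instrument's 0.1 degC/s is
#' a ramp rate, not a data-grid mandate).  `transition_width` is the
#' logistic width in degrees Celsius, or `"vantHoff"` to derive each
#' component's width from its enthalpy as `R Tm^2 / |dH|` (two-state van 't
#' Hoff linearization; components must then carry a `dh` in kcal/mol).
#'
#' @param t_start,t_end Ramp window, degrees Celsius.
#' @param t_step Grid step, degrees Celsius.
#' @param noise_sd Gaussian fluorescence noise SD (0 = noiseless).
#' @param seed Integer seed for the noise stream (ignored when
#'   `noise_sd = 0`).
#' The default logistic width of 0.15 degC gives derivative melt peaks with
#' a full width at half maximum near 0.5 degC, the scale instrument
#' derivative plots show for ~100 bp amplicons.
#'
#' @param transition_width Logistic width (degC) or `"vantHoff"`.
#' @param baseline Constant fluorescence offset.
#' @return Object of class `MeltConfig`.
#' @export
melt_config <- function(t_start = 65, t_end = 90, t_step = 0.01,
                        noise_sd = 0, seed = 1L, transition_width = 0.15,
                        baseline = 0) {
  if (!(t_start < t_end)) stop("t_start must be < t_end", call. = FALSE)
  if (t_step <= 0) stop("t_step must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.character(transition_width)) {
    transition_width <- match.arg(transition_width, "vantHoff")
  } else if (transition_width <= 0) {
    stop("transition_width must be > 0", call. = FALSE)
  }
  structure(
    list(t_start = t_start, t_end = t_end, t_step = t_step,
         noise_sd = noise_sd, seed = as.integer(seed),
         transition_width = transition_width, baseline = baseline),
    class = "MeltConfig"
  )
}

#' Melt curve container
#'
#' @param temps Strictly ascending constant-step temperature grid (degC).
#' @param fluor Fluorescence (or negative-derivative) series, same length.
#' @return Object of class `MeltCurve`.
#' @export
melt_curve <- function(temps, fluor) {
  if (length(temps) != length(fluor)) {
    stop("temps and fluor must have equal length", call. = FALSE)
  }
  if (length(temps) >= 2L) {
    steps <- diff(temps)
    if (any(steps <= 0) || max(steps) - min(steps) > 1e-8) {
      stop("temps must be strictly ascending with constant step", call. = FALSE)
    }
  }
  structure(list(temps = temps, fluor = fluor), class = "MeltCurve")
}

#' @export
print.MeltCurve <- function(x, ...) {
  cat(sprintf("<MeltCurve> %d points, %.2f-%.2f degC\n",
              length(x$temps), x$temps[1L], x$temps[length(x$temps)]))
  invisible(x)
}

.as_components <- function(components) {
  if (is.data.frame(components)) return(components)
  do.call(rbind, lapply(components, function(cmp) {
    data.frame(tm = cmp[[1L]], weight = cmp[[2L]],
               dh = if (length(cmp) >= 3L) cmp[[3L]] else NA_real_)
  }))
}

#' Simulate a saturation-dye melt curve
#'
#' Fluorescence tracks total helicity: each component contributes
#' `weight * 1 / (1 + exp((T - tm) / w))`, which passes exactly through half
#' its weight at `tm`.  A constant baseline and optional seeded Gaussian
#' noise are added.  The same configuration and seed always produce an
#' identical curve.
#'
#' @param components data.frame with columns `tm` (degC), `weight` (> 0) and
#'   optionally `dh` (kcal/mol, used in van 't Hoff mode), or a list of
#'   `c(tm, weight)` vectors.
#' @param config A [melt_config()].
#' @return A [melt_curve()].
#' @examples
#' cv <- simulate_melt(data.frame(tm = 76.22, weight = 1), melt_config())
#' @export
simulate_melt <- function(components, config = melt_config()) {
  cmp <- .as_components(components)
  if (any(cmp$weight <= 0)) stop("weights must be > 0", call. = FALSE)
  if (any(cmp$tm <= config$t_start | cmp$tm >= config$t_end)) {
    stop("parameter error: component tm outside the ramp window", call. = FALSE)
  }
  temps <- seq(config$t_start, config$t_end, by = config$t_step)
  widths <- if (identical(config$transition_width, "vantHoff")) {
    if (is.null(cmp$dh) || anyNA(cmp$dh)) {
      stop("vantHoff mode requires a dh (kcal/mol) per component",
           call. = FALSE)
    }
    .gas_constant * (cmp$tm + 273.15)^2 / abs(cmp$dh * 1000)
  } else {
    rep_len(config$transition_width, nrow(cmp))
  }
  fluor <- rep(config$baseline, length(temps))
  for (i in seq_len(nrow(cmp))) {
    fluor <- fluor + cmp$weight[i] / (1 + exp((temps - cmp$tm[i]) / widths[i]))
  }
  if (config$noise_sd > 0) {
    fluor <- fluor + .with_seed(config$seed,
                                rnorm(length(temps), sd = config$noise_sd))
  }
  melt_curve(temps, fluor)
}

#' Negative-derivative melt curve
#'
#' Savitzky-Golay local-polynomial smoothing, central finite differences
#' (negated, -dF/dT), and a second Savitzky-Golay pass on the derivative.
#' The post-differentiation pass is what keeps white fluorescence noise -
#' which naive differencing amplifies by the reciprocal grid step - below
#' the peak-calling prominence floor; on noiseless input both passes are
#' exact for polynomials up to `smooth_degree` and leave peak positions of
#' symmetric transitions unshifted.  Grid points where any stencil is
#' incomplete are dropped from the output.
#'
#' @param curve A [melt_curve()].
#' @param smooth_window Odd window length (points) used by both smoothing
#'   passes; the default 51 points spans 0.51 degC on the default 0.01 degC
#'   grid, matched to the ~0.5 degC width of a derivative melt peak.
#' @param smooth_degree Polynomial degree.
#' @return A [melt_curve()] whose `fluor` holds -dF/dT.
#' @export
derivative_curve <- function(curve, smooth_window = 51L, smooth_degree = 3L) {
  stopifnot(inherits(curve, "MeltCurve"))
  n <- length(curve$temps)
  smooth_window <- as.integer(smooth_window)
  if (smooth_window %% 2L == 0L || smooth_window < 5L) {
    stop("smooth_window must be odd and >= 5", call. = FALSE)
  }
  half <- (smooth_window - 1L) %/% 2L
  if (n < 2L * smooth_window + 2L) {
    stop("parameter error: smooth_window larger than the series supports",
         call. = FALSE)
  }
  step <- curve$temps[2L] - curve$temps[1L]
  smoothed <- signal::sgolayfilt(curve$fluor, p = smooth_degree,
                                 n = smooth_window)
  keep <- (half + 1L):(n - half)
  d <- -(smoothed[keep + 1L] - smoothed[keep - 1L]) / (2 * step)
  d <- signal::sgolayfilt(d, p = smooth_degree, n = smooth_window)
  keep2 <- (half + 1L):(length(d) - half)
  melt_curve(curve$temps[keep][keep2], d[keep2])
}

## prominence of a local maximum: height minus the higher of the two valley
## minima walking out to the nearest strictly higher point (or series edge)
.peak_prominences <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    left <- if (i == 1L) h else {
      seg <- y[seq_len(i - 1L)]
      higher <- which(seg > h)
      lo <- if (length(higher)) (max(higher) + 1L) else 1L
      min(y[lo:i])
    }
    right <- if (i == length(y)) h else {
      seg <- y[(i + 1L):length(y)]
      higher <- which(seg > h)
      hi <- if (length(higher)) (i + min(higher) - 1L) else length(y)
      min(y[i:hi])
    }
    h - max(left, right)
  }, numeric(1L))
}

#' Call melt peaks from a derivative curve
#'
#' Local maxima of the negative-derivative curve with prominence at least
#' `min_prominence_frac` of the most prominent peak are reported, ascending
#' by temperature at grid resolution.  Peaks closer than `merge_radius`
#' (default 0.1 degC, below which the instrument never reports distinct
#' peaks) are merged into the higher one.  A flat curve yields an empty
#' peak set.
#'
#' @param deriv_curve Output of [derivative_curve()].
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   maximum prominence.
#' @param merge_radius Merge radius, degrees Celsius.
#' @return Object of class `PeakSet`: data.frame with columns `tm`,
#'   `height`, `prominence`.
#' @export
call_peaks <- function(deriv_curve, min_prominence_frac = 0.05,
                       merge_radius = 0.1) {
  stopifnot(inherits(deriv_curve, "MeltCurve"))
  y <- deriv_curve$fluor
  x <- deriv_curve$temps
  empty <- structure(
    data.frame(tm = numeric(0), height = numeric(0), prominence = numeric(0)),
    class = c("PeakSet", "data.frame"))
  if (length(y) < 3L || diff(range(y)) == 0) return(empty)
  ## local maxima; plateaus collapse to their first point
  dy <- diff(y)
  s <- sign(dy)
  s[s == 0] <- 1  # treat flat steps as rising so plateau ends count once
  idx <- which(diff(s) < 0) + 1L
  if (length(idx) == 0L) return(empty)
  prom <- .peak_prominences(y, idx)
  keep <- prom >= min_prominence_frac * max(prom)
  idx <- idx[keep]; prom <- prom[keep]
  if (length(idx) == 0L) return(empty)
  ## merge peaks closer than merge_radius, keeping the higher one
  ord <- order(x[idx])
  idx <- idx[ord]; prom <- prom[ord]
  repeat {
    if (length(idx) < 2L) break
    gaps <- diff(x[idx])
    close <- which(gaps < merge_radius - 1e-12)
    if (length(close) == 0L) break
    k <- close[1L]
    drop <- if (y[idx[k]] >= y[idx[k + 1L]]) k + 1L else k
    idx <- idx[-drop]; prom <- prom[-drop]
  }
  structure(
    data.frame(tm = x[idx], height = y[idx], prominence = prom),
    class = c("PeakSet", "data.frame"))
}

#' Read / write melt-curve CSV
#'
#' CSV with header `temperature_c,fluorescence`.
#'
#' @param curve A [melt_curve()].
#' @param path File path.
#' @return [read_curve_csv()] returns a `MeltCurve`; [write_curve_csv()]
#'   returns `path` invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  df <- data.frame(temperature_c = curve$temps, fluorescence = curve$fluor)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- read.delim(path, sep = ",")
  melt_curve(df$temperature_c, df$fluorescence)
}
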