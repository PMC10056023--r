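#' Design a Butterworth filter
#'
#' Designs an order-`N` digital Butterworth filter whose low-pass
#' prototype has the squared magnitude response
#' \deqn{|H(j\omega)|^2 = \frac{1}{1 + (\omega/\omega_c)^{2N}}}
#' so the half-power (-3 dB) point always falls exactly at the cutoff.
#' The default configuration for PPG denoising is a second-order 0.6 Hz
#' high-pass: the adult respiratory band (roughly 0.15-0.5 Hz) that
#' drives baseline wander lies below the cutoff, the pulse band (up to
#' about 20 Hz) above it. A band-pass mode (0.6-20 Hz) is provided for
#' the stricter reading of the pulse band.
#'
#' @param N Filter order (>= 1).
#' @param cutoff Cutoff frequency in Hz: one edge for `highpass`, two for
#'   `bandpass`.
#' @param fs Sampling rate in Hz.
#' @param band_mode `"highpass"` or `"bandpass"`.
#' @param zero_phase Apply the filter forward and backward
#'   ([apply_filter()]) so fiducial timings are not phase-shifted. The
#'   amplitude response is then the squared single-pass magnitude.
#' @return A `filter_spec` object holding the design parameters and the
#'   `signal::butter` coefficients.
#' @export
design_butterworth <- function(N = 2, cutoff = 0.6, fs = 100,
                               band_mode = c("highpass", "bandpass"),
                               zero_phase = TRUE) {
  band_mode <- match.arg(band_mode)
  stopifnot(N >= 1, fs > 0)
  if (band_mode == "bandpass" && length(cutoff) == 1L)
    cutoff <- c(cutoff, 20)
  if (any(cutoff <= 0) || any(cutoff >= fs / 2))
    stop("design_butterworth: cutoff must lie in (0, fs/2)")
  type <- if (band_mode == "highpass") "high" else "pass"
  ba <- signal::butter(N, cutoff / (fs / 2), type = type)
  structure(list(N = as.integer(N), cutoff = cutoff, fs = fs,
                 band_mode = band_mode, zero_phase = isTRUE(zero_phase),
                 b = ba$b, a = ba$a),
            class = "filter_spec")
}

#' Analytic Butterworth magnitude response
#'
#' Closed-form squared magnitude of the analogue Butterworth design at
#' frequency `f`: `1/(1 + (f/fc)^(2N))` for the low-pass prototype,
#' transformed by `f -> fc/f` for high-pass and by the standard band-pass
#' substitution for band-pass mode. Used as the independent oracle for
#' [apply_filter()] gains.
#'
#' @param spec A `filter_spec`.
#' @param f Frequencies in Hz.
#' @param prototype If `TRUE`, evaluate the low-pass prototype response
#'   regardless of `spec$band_mode` (treating `f/cutoff[1]` as the
#'   prototype frequency ratio).
#' @return Squared magnitude response at `f` (single pass).
#' @export
butterworth_response <- function(spec, f, prototype = FALSE) {
  stopifnot(inherits(spec, "filter_spec"))
  N <- spec$N
  if (prototype) return(1 / (1 + (f / spec$cutoff[1])^(2 * N)))
  if (spec$band_mode == "highpass") {
    r <- ifelse(f == 0, Inf, spec$cutoff[1] / f)
    1 / (1 + r^(2 * N))
  } else {
    f1 <- spec$cutoff[1]; f2 <- spec$cutoff[2]
    bw <- f2 - f1; f0sq <- f1 * f2
    r <- ifelse(f == 0, Inf, abs((f^2 - f0sq) / (bw * f)))
    1 / (1 + r^(2 * N))
  }
}

#' Amplitude gain of the applied filter at given frequencies
#'
#' @param spec A `filter_spec`.
#' @param f Frequencies in Hz.
#' @return Expected amplitude ratio out/in for a sinusoid at `f`,
#'   accounting for the zero-phase double pass.
#' @export
filter_gain <- function(spec, f) {
  g <- sqrt(butterworth_response(spec, f))
  if (spec$zero_phase) g^2 else g
}

#' Apply a designed filter to a signal
#'
#' Zero-phase (forward-backward) application by default; the output has
#' the same length as the input.
#'
#' @param x Numeric signal.
#' @param spec A `filter_spec` from [design_butterworth()].
#' @return Filtered signal, same length as `x`.
#' @export
apply_filter <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  warmup <- 3 * (length(spec$a) - 1)
  if (length(x) <= max(warmup, 9))
    stop("apply_filter: signal shorter than the filter warm-up length")
  n <- length(x)
  # odd-reflection padding keeps start/end transients out of the signal;
  # pad length covers a few time constants of the lowest band edge
  pad <- min(n - 1L, max(warmup, round(3 * spec$fs / min(spec$cutoff))))
  left <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  arma <- signal::Arma(b = spec$b, a = spec$a)
  y <- if (spec$zero_phase) signal::filtfilt(arma, xp)
       else signal::filter(arma, xp)
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Centered moving-average smoother
#'
#' Plain length-preserving moving average with an odd window; near the
#' edges the window shrinks symmetrically so the output stays unbiased
#' for linear trends.
#'
#' @param x Numeric signal.
#' @param window Odd window length in samples (default 5, i.e. 50 ms at
#'   100 Hz).
#' @return Smoothed signal, same length as `x`.
#' @export
smooth_signal <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("smooth_signal: window must be odd and >= 1")
  if (window == 1L) return(as.numeric(x))
  n <- length(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  out
}

#' Detect per-cycle troughs
#'
#' Finds the onset trough of every pulse cycle. The dominant cardiac
#' frequency is estimated from the spectral peak in 0.5-3 Hz; candidate
#' local minima of a detrended copy of the signal are then thinned with a
#' refractory period of half the dominant cycle, keeping the deepest
#' minimum in each conflict.
#'
#' @param x Numeric signal (raw or preprocessed; detrending is internal).
#' @param fs Sampling rate in Hz.
#' @return Strictly increasing integer sample indices of the troughs;
#'   empty (with a warning) when no oscillatory content is found.
#' @export
detect_troughs <- function(x, fs) {
  n <- length(x)
  if (n < 3L || stats::sd(x) < .Machine$double.eps^0.5) {
    warning("detect_troughs: no oscillatory content detected")
    return(integer(0))
  }
  f_dom <- dominant_frequency(x, fs, band = c(0.5, 3))
  if (is.na(f_dom)) {
    warning("detect_troughs: no oscillatory content detected")
    return(integer(0))
  }
  period <- fs / f_dom
  # detrend with a one-cycle moving average so baseline drift cannot
  # mask or fake troughs
  w <- max(3L, round(period))
  if (w %% 2L == 0L) w <- w + 1L
  d <- x - smooth_signal(x, min(w, if (n %% 2L) n else n - 1L))
  cand <- local_minima(d)
  # dicrotic notches are shallow minima; cycle-onset troughs are deep
  cand <- cand[d[cand] < -0.25 * stats::sd(d)]
  if (!length(cand)) {
    warning("detect_troughs: no oscillatory content detected")
    return(integer(0))
  }
  refractory <- round(0.6 * period)
  keep <- logical(length(cand))
  ord <- order(d[cand])            # deepest first
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(cand[i] - taken) >= refractory)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  sel <- sort(cand[keep])
  # refine each candidate to the local minimum of the signal itself so
  # trough values (the spline knots) sit on the waveform valley floor
  w2 <- max(2L, round(0.15 * period))
  refined <- vapply(sel, function(i) {
    lo <- max(1L, i - w2); hi <- min(n, i + w2)
    seg <- lo:hi
    seg[which.min(x[seg])]
  }, integer(1))
  refined <- sort(unique(refined))
  # keep genuine local minima of the signal only (drops detrending edge
  # artifacts, e.g. on monotonic inputs)
  ok <- refined > 1L & refined < n
  ri <- refined[ok]
  ok[ok] <- x[ri] <= x[ri - 1L] & x[ri] <= x[ri + 1L]
  refined <- refined[ok]
  if (!length(refined))
    warning("detect_troughs: no oscillatory content detected")
  refined
}

#' Dominant frequency by FFT peak
#' @keywords internal
dominant_frequency <- function(x, fs, band = c(0.5, 3)) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[seq_len(max(1L, n %/% 2L))]
  fr <- (seq_along(sp) - 1L) * fs / n
  sel <- fr >= band[1] & fr <= band[2]
  if (!any(sel) || max(sp[sel]) <= 0) return(NA_real_)
  fr[sel][which.max(sp[sel])]
}

#' Fit a trough-anchored cubic-spline baseline
#'
#' Takes every `knot_stride`-th trough as a knot (the default, 2, uses
#' the trough of every second cycle) and fits a natural cubic spline
#' through the signal values at those knots. The per-interval cubic
#' coefficients \eqn{P_i(t) = a_i + b_i(t-t_i) + c_i(t-t_i)^2 +
#' d_i(t-t_i)^3} are returned together with the fitted curve over the
#' full signal extent; the segments before the first and after the last
#' knot are evaluated from the boundary interval polynomials.
#'
#' @param x Numeric signal.
#' @param troughs Trough indices from [detect_troughs()].
#' @param knot_stride Take every `knot_stride`-th trough as a knot.
#' @return A `baseline_fit`: `knots` (indices), `values`, coefficient
#'   matrix `coef` (columns a, b, c, d per interval), fitted `curve`
#'   over `seq_along(x)`, and `fallback_linear` flag. With fewer than 4
#'   knots a linear fit is returned instead, flagged.
#' @export
fit_baseline_spline <- function(x, troughs, knot_stride = 2L) {
  knots <- troughs[seq(1L, length(troughs), by = max(1L, as.integer(knot_stride)))]
  n <- length(x)
  if (length(knots) < 4L) {
    if (length(knots) < 2L)
      stop("fit_baseline_spline: need at least 2 troughs")
    fit <- stats::lm.fit(cbind(1, knots), x[knots])
    curve <- fit$coefficients[1] + fit$coefficients[2] * seq_len(n)
    return(structure(list(knots = knots, values = x[knots], coef = NULL,
                          curve = curve, fallback_linear = TRUE),
                     class = "baseline_fit"))
  }
  sf <- stats::splinefun(knots, x[knots], method = "natural")
  nk <- length(knots)
  # per-interval coefficients from exact derivatives at the left knot
  left <- knots[-nk]
  mid <- (knots[-nk] + knots[-1L]) / 2
  coef <- cbind(a = sf(left), b = sf(left, deriv = 1),
                c = sf(left, deriv = 2) / 2, d = sf(mid, deriv = 3) / 6)
  curve <- eval_spline_coef(knots, coef, seq_len(n))
  structure(list(knots = knots, values = x[knots], coef = coef,
                 curve = curve, fallback_linear = FALSE),
            class = "baseline_fit")
}

# Evaluate the piecewise cubic given knots and per-interval (a,b,c,d);
# points outside the knot range use the adjacent boundary polynomial.
eval_spline_coef <- function(knots, coef, t) {
  iv <- findInterval(t, knots, rightmost.closed = TRUE)
  iv <- pmin(pmax(iv, 1L), nrow(coef))
  dt <- t - knots[iv]
  coef[iv, "a"] + coef[iv, "b"] * dt + coef[iv, "c"] * dt^2 +
    coef[iv, "d"] * dt^3
}

#' Subtract a fitted baseline from a signal
#'
#' Subtracting the spline anchored at cycle troughs places all corrected
#' troughs at a common level (zero at the knots), which is the reference
#' the amplitude features x, y, z are measured from.
#'
#' @param x Numeric signal.
#' @param fit A `baseline_fit` covering `seq_along(x)`.
#' @return Baseline-corrected signal.
#' @export
remove_baseline <- function(x, fit) {
  stopifnot(inherits(fit, "baseline_fit"))
  if (length(fit$curve) != length(x))
    stop("remove_baseline: fit does not cover the signal extent")
  x - fit$curve
}

#' Full preprocessing chain for one record
#'
#' Butterworth filtering, moving-average smoothing, trough detection and
#' cubic-spline baseline removal, in that order.
#'
#' @param record A `ppg_record`.
#' @param filter_spec Optional `filter_spec`; default is the package
#'   default second-order 0.6 Hz high-pass at the record's sampling rate.
#' @param smooth_window Odd moving-average window (samples).
#' @param knot_stride Trough stride for the baseline knots.
#' @return The record with processed samples (`processed = TRUE`), plus
#'   attributes `troughs` and `baseline_fit`.
#' @export
preprocess_record <- function(record, filter_spec = NULL,
                              smooth_window = 5L, knot_stride = 2L) {
  stopifnot(inherits(record, "ppg_record"))
  if (is.null(filter_spec))
    filter_spec <- design_butterworth(2, 0.6, record$fs, "highpass")
  y <- apply_filter(record$samples, filter_spec)
  y <- smooth_signal(y, smooth_window)
  tr <- detect_troughs(y, record$fs)
  if (length(tr) >= 2L) {
    fit <- fit_baseline_spline(y, tr, knot_stride)
    y <- remove_baseline(y, fit)
  } else fit <- NULL
  out <- record
  out$samples <- y
  out$processed <- TRUE
  attr(out, "troughs") <- tr
  attr(out, "baseline_fit") <- fit
  out
}
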