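#' Segment a record into fixed-length windows
#'
#' Cuts the record into consecutive non-overlapping windows of
#' `window_s` seconds (default 10 s, i.e. 1000 samples at 100 Hz — one
#' classification instance). A trailing remainder shorter than one
#' window is dropped.
#'
#' @param record A `ppg_record`.
#' @param window_s Window length in seconds.
#' @return List of `window` objects, each holding `samples`,
#'   `subject_id`, `label`, `session` and the source `offset` (samples).
#'   Empty list (with a warning) when the record is shorter than one
#'   window.
#' @export
segment_windows <- function(record, window_s = 10) {
  stopifnot(inherits(record, "ppg_record"))
  wlen <- round(window_s * record$fs)
  n <- length(record$samples)
  if (n < wlen) {
    warning("segment_windows: record shorter than one window")
    return(list())
  }
  k <- n %/% wlen
  lapply(seq_len(k), function(i) {
    off <- (i - 1L) * wlen
    structure(list(samples = record$samples[(off + 1L):(off + wlen)],
                   fs = record$fs, subject_id = record$subject_id,
                   label = record$label, session = record$session,
                   offset = off, window_index = i),
              class = "ppg_window")
  })
}

window_samples <- function(window) {
  if (inherits(window, "ppg_window")) window$samples else as.numeric(window)
}

#' Detect per-beat fiducial points in a window
#'
#' For every beat delimited by consecutive troughs: the systolic peak is
#' the global maximum between the troughs; the dicrotic notch is the most
#' prominent local minimum after the systolic peak; the dicrotic-wave
#' peak is the first local maximum after the notch. Landmarks that do not
#' exist (typical of stiffened, hypertensive vasculature where the
#' reflected wave attenuates or disappears) are flagged missing — never
#' fabricated.
#'
#' @param window A `ppg_window` or numeric vector (preprocessed,
#'   baseline-corrected samples).
#' @param troughs Trough indices within the window; detected with
#'   [detect_troughs()] when omitted.
#' @param fs Sampling rate (needed only when `window` is a bare vector
#'   and `troughs` is missing).
#' @param min_prominence Minimum notch prominence relative to the beat
#'   amplitude (default 3%); shallower wiggles are treated as noise.
#' @param fid_smooth Extra moving-average window (odd, samples) applied
#'   before landmark search. The dicrotic notch/wave complex is a broad
#'   feature (tens of milliseconds) while residual noise wiggles are
#'   sample-scale, so smoothing separates the two; landmarks and
#'   amplitudes are read from the smoothed copy.
#' @return List of `beat_fiducials`: indices/amplitudes for trough,
#'   systolic, notch, dicrotic, plus `notch_missing`/`dicrotic_missing`
#'   flags and the index of the next trough (`trough_next_idx`).
#' @export
detect_fiducials <- function(window, troughs = NULL, fs = NULL,
                             min_prominence = 0.03, fid_smooth = 7L) {
  x <- window_samples(window)
  if (is.null(fs)) fs <- if (inherits(window, "ppg_window")) window$fs else 100
  if (fid_smooth > 1L) x <- smooth_signal(x, fid_smooth)
  if (is.null(troughs)) {
    troughs <- suppressWarnings(detect_troughs(x, fs))
  }
  if (length(troughs) < 2L) return(list())
  out <- list()
  for (b in seq_len(length(troughs) - 1L)) {
    lo <- troughs[b]; hi <- troughs[b + 1L]
    seg <- x[lo:hi]
    sys_rel <- which.max(seg)
    sys_idx <- lo + sys_rel - 1L
    amp <- x[sys_idx] - x[lo]
    fid <- list(trough_idx = lo, trough_amp = x[lo],
                trough_next_idx = hi,
                systolic_idx = sys_idx, systolic_amp = x[sys_idx],
                notch_idx = NA_integer_, notch_amp = NA_real_,
                dicrotic_idx = NA_integer_, dicrotic_amp = NA_real_,
                notch_missing = TRUE, dicrotic_missing = TRUE)
    if (amp > 0 && sys_rel < length(seg) - 2L) {
      tail_seg <- seg[sys_rel:length(seg)]
      mins <- local_minima(tail_seg)
      maxs <- local_maxima(tail_seg)
      best <- NULL; best_prom <- -Inf
      for (m in mins) {
        nxt <- maxs[maxs > m]
        if (!length(nxt)) next
        prom <- tail_seg[nxt[1L]] - tail_seg[m]
        if (prom > best_prom) { best_prom <- prom; best <- c(m, nxt[1L]) }
      }
      if (!is.null(best) && best_prom >= min_prominence * amp) {
        fid$notch_idx <- lo + sys_rel - 1L + best[1L] - 1L
        fid$notch_amp <- x[fid$notch_idx]
        fid$dicrotic_idx <- lo + sys_rel - 1L + best[2L] - 1L
        fid$dicrotic_amp <- x[fid$dicrotic_idx]
        fid$notch_missing <- FALSE
        fid$dicrotic_missing <- FALSE
      }
    }
    out[[b]] <- structure(fid, class = "beat_fiducials")
  }
  out
}

#' Was a window discarded by feature extraction?
#'
#' @param x Result of [extract_features()].
#' @return `TRUE` when `x` is a discard sentinel; the reason code is in
#'   `attr(x, "discard_reason")`.
#' @export
is_discarded <- function(x) inherits(x, "ppg_discard")

#' @export
discard_reason <- function(x) {
  if (is_discarded(x)) attr(x, "discard_reason") else NA_character_
}

feature_names <- c("x", "y", "z", "y_over_x", "xy_over_x",
                   "tpp", "t1", "t2", "t3", "t4", "dT",
                   "t1_over_tpp", "t2_over_tpp", "t3_over_tpp",
                   "dT_over_tpp", "Fre1", "Fre2", "Fre3", "e1", "e2")

#' The 20 pulse-wave feature names
#'
#' Amplitudes (signal units): `x` dominant-wave, `y` dicrotic-wave, `z`
#' dicrotic-notch, all measured from the beat's onset-trough level, plus
#' the ratios `y/x` and `(x-y)/x`. Durations (s): `tpp` peak-to-peak of
#' adjacent beats, `t1`/`t2`/`t3` trough to systolic peak / notch /
#' dicrotic peak, `t4` trough-to-trough, `dT` systolic-to-dicrotic peak,
#' and the four ratios to `tpp`. Frequencies (Hz): `Fre1`-`Fre3`, the
#' three dominant spectral peaks. Entropies (bits): `e1` amplitude
#' (Shannon) entropy, `e2` spectral (information) entropy.
#'
#' @return Character vector of length 20.
#' @export
ppg_feature_names <- function() feature_names

#' Extract the 20-dimensional feature vector from one window
#'
#' Beat-level quantities are computed for every complete beat (all four
#' landmarks present plus a following beat for `tpp`/`t4`) and averaged
#' over the window. Windows with fewer than two complete beats are
#' discarded with a reason code — the behaviour seen in hypertensive
#' signals whose reflected wave cannot be located.
#'
#' @param window A `ppg_window` or numeric vector.
#' @param fiducials Optional precomputed [detect_fiducials()] result.
#' @param fs Sampling rate in Hz (taken from the window when available).
#' @param n_bins Histogram bins for the amplitude entropy.
#' @return On success, a named numeric vector of the 20 features (see
#'   [ppg_feature_names()]) with attribute `n_beats`. On failure, a
#'   `ppg_discard` sentinel (see [is_discarded()]) whose
#'   `discard_reason` attribute is one of `"no_beats"`,
#'   `"missing_notch"`, `"missing_dicrotic"`, `"too_few_complete_beats"`.
#' @export
extract_features <- function(window, fiducials = NULL, fs = NULL,
                             n_bins = 16L) {
  x <- window_samples(window)
  if (is.null(fs)) fs <- if (inherits(window, "ppg_window")) window$fs else 100
  if (is.null(fiducials)) fiducials <- detect_fiducials(window, fs = fs)
  discard <- function(reason)
    structure(NA, discard_reason = reason, class = "ppg_discard")
  if (!length(fiducials)) return(discard("no_beats"))

  # drop implausibly short/long beats (window-edge artifacts): the
  # inter-trough duration must stay within 25% of the window median
  t4_all <- vapply(fiducials, function(f)
    f$trough_next_idx - f$trough_idx, numeric(1))
  plausible <- abs(t4_all - stats::median(t4_all)) <=
    0.25 * stats::median(t4_all)
  fiducials <- fiducials[plausible]
  if (!length(fiducials)) return(discard("no_beats"))

  complete <- vapply(fiducials, function(f)
    !f$notch_missing && !f$dicrotic_missing, logical(1))
  if (sum(complete) < 2L) {
    n_notch <- sum(vapply(fiducials, function(f) f$notch_missing, logical(1)))
    n_dic <- sum(vapply(fiducials, function(f) f$dicrotic_missing, logical(1)))
    reason <- if (n_notch >= n_dic && n_notch > 0) "missing_notch"
      else if (n_dic > 0) "missing_dicrotic" else "too_few_complete_beats"
    if (n_notch == 0 && n_dic == 0) reason <- "too_few_complete_beats"
    return(discard(reason))
  }

  fids <- fiducials[complete]
  per_beat <- vapply(seq_along(fids), function(i) {
    f <- fids[[i]]
    xa <- f$systolic_amp - f$trough_amp
    ya <- f$dicrotic_amp - f$trough_amp
    za <- f$notch_amp - f$trough_amp
    c(x = xa, y = ya, z = za,
      t1 = (f$systolic_idx - f$trough_idx) / fs,
      t2 = (f$notch_idx - f$trough_idx) / fs,
      t3 = (f$dicrotic_idx - f$trough_idx) / fs,
      t4 = (f$trough_next_idx - f$trough_idx) / fs,
      dT = (f$dicrotic_idx - f$systolic_idx) / fs)
  }, numeric(8))

  # tpp needs the NEXT beat's systolic peak, complete or not
  all_sys <- vapply(fiducials, function(f) f$systolic_idx, integer(1))
  tr_of <- vapply(fiducials, function(f) f$trough_idx, integer(1))
  tpp <- vapply(fids, function(f) {
    nxt <- all_sys[tr_of == f$trough_next_idx]
    if (length(nxt)) (nxt[1L] - f$systolic_idx) / fs else NA_real_
  }, numeric(1))
  tpp_mean <- mean(tpp, na.rm = TRUE)
  if (!is.finite(tpp_mean)) tpp_mean <- mean(per_beat["t4", ])

  m <- rowMeans(per_beat)
  freqs <- fft_peaks(x, fs)
  ent <- entropy_features(x, fs = fs, n_bins = n_bins)
  feats <- c(m[["x"]], m[["y"]], m[["z"]],
             m[["y"]] / m[["x"]], (m[["x"]] - m[["y"]]) / m[["x"]],
             tpp_mean, m[["t1"]], m[["t2"]], m[["t3"]], m[["t4"]], m[["dT"]],
             m[["t1"]] / tpp_mean, m[["t2"]] / tpp_mean,
             m[["t3"]] / tpp_mean, m[["dT"]] / tpp_mean,
             freqs[["Fre1"]], freqs[["Fre2"]], freqs[["Fre3"]],
             ent[["e1"]], ent[["e2"]])
  names(feats) <- feature_names
  if (any(!is.finite(feats))) return(discard("too_few_complete_beats"))
  attr(feats, "n_beats") <- sum(complete)
  feats
}

#' Dominant spectral peaks of a window
#'
#' Frequencies of the three largest local maxima of the magnitude
#' spectrum in (0, 10] Hz — the band that carries essentially all pulse
#' energy — ordered by descending magnitude.
#'
#' @param window A `ppg_window` or numeric vector (>= 256 samples).
#' @param fs Sampling rate in Hz.
#' @param f_max Upper edge of the searched band (Hz).
#' @return Named vector `Fre1`, `Fre2`, `Fre3` (Hz); `NA` entries when
#'   the spectrum has fewer than three peaks.
#' @export
fft_peaks <- function(window, fs = NULL, f_max = 10) {
  x <- window_samples(window)
  if (is.null(fs)) fs <- if (inherits(window, "ppg_window")) window$fs else 100
  if (length(x) < 256L) stop("fft_peaks: window must have >= 256 samples")
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[seq_len(n %/% 2L)]
  fr <- (seq_along(sp) - 1L) * fs / n
  sel <- which(fr > 0 & fr <= f_max)
  peaks <- sel[sel %in% (local_maxima(sp))]
  out <- c(Fre1 = NA_real_, Fre2 = NA_real_, Fre3 = NA_real_)
  if (length(peaks)) {
    ord <- peaks[order(sp[peaks], decreasing = TRUE)]
    top <- utils::head(ord, 3L)
    out[seq_along(top)] <- fr[top]
  }
  out
}

#' Amplitude and spectral entropy of a window
#'
#' `e1` is the Shannon entropy of the normalised amplitude histogram
#' (`n_bins` fixed-width bins over the window's range); `e2` is the
#' information (spectral) entropy of the normalised power spectrum over
#' positive frequencies. Both in bits.
#'
#' @param window A `ppg_window` or numeric vector.
#' @param fs Sampling rate (unused for `e1`; kept for interface
#'   symmetry).
#' @param n_bins Number of histogram bins (default 16, so `e1 <= 4`).
#' @return Named vector `e1`, `e2`; a constant window yields `e1 = 0`
#'   and `e2 = NA` (undefined), with a warning.
#' @export
entropy_features <- function(window, fs = NULL, n_bins = 16L) {
  x <- window_samples(window)
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    warning("entropy_features: constant window; spectral entropy undefined")
    return(c(e1 = 0, e2 = NA_real_))
  }
  brk <- seq(min(x), max(x), length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(x, brk, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  e1 <- -sum(p * log2(p))
  n <- length(x)
  psd <- Mod(stats::fft(x - mean(x))[2:(n %/% 2L)])^2
  q <- psd / sum(psd)
  q <- q[q > 0]
  e2 <- -sum(q * log2(q))
  c(e1 = e1, e2 = e2)
}

#' Estimate heart rate from trough spacing
#'
#' `60 / median inter-trough interval`; needs at least three troughs.
#'
#' @param x A `ppg_record`, `ppg_window` or numeric vector.
#' @param fs Sampling rate in Hz (taken from the object when available).
#' @return Heart rate in bpm, or `NA` (with a warning) when fewer than
#'   three troughs are found.
#' @export
estimate_heart_rate <- function(x, fs = NULL) {
  if (inherits(x, "ppg_record")) { fs <- x$fs; x <- x$samples }
  else if (inherits(x, "ppg_window")) { fs <- x$fs; x <- x$samples }
  if (is.null(fs)) fs <- 100
  tr <- suppressWarnings(detect_troughs(x, fs))
  if (length(tr) < 3L) {
    warning("estimate_heart_rate: fewer than 3 troughs detected")
    return(NA_real_)
  }
  # sub-sample refinement: parabolic interpolation through each trough
  # and its neighbours removes the integer-sample quantisation
  pos <- vapply(tr, function(i) {
    if (i <= 1L || i >= length(x)) return(as.numeric(i))
    den <- x[i - 1L] - 2 * x[i] + x[i + 1L]
    if (den <= 0) return(as.numeric(i))
    i + min(0.5, max(-0.5, 0.5 * (x[i - 1L] - x[i + 1L]) / den))
  }, numeric(1))
  60 / (stats::median(diff(pos)) / fs)
}

#' Build the feature table for a cohort
#'
#' Preprocesses every record, segments it into windows, and extracts the
#' 20-dimensional feature vector per window. Windows whose fiducials are
#' incomplete are collected into a discard log with reason codes.
#'
#' @param cohort A `ppg_cohort` from [generate_cohort()].
#' @param window_s Window length in seconds.
#' @param preprocess Apply [preprocess_record()] first (default TRUE).
#' @return List with `features` (data frame: 20 feature columns plus
#'   `subject_id`, `label`, `session`, `window_index`) and `discards`
#'   (data frame with reason codes).
#' @export
build_feature_table <- function(cohort, window_s = 10, preprocess = TRUE) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  rows <- list(); disc <- list()
  for (res in cohort$records) {
    rec <- if (preprocess) preprocess_record(res$record) else res$record
    for (w in segment_windows(rec, window_s)) {
      f <- extract_features(w)
      if (is_discarded(f)) {
        disc[[length(disc) + 1L]] <- data.frame(
          subject_id = w$subject_id, session = w$session,
          window_index = w$window_index,
          reason = discard_reason(f), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = w$subject_id, label = w$label, session = w$session,
          window_index = w$window_index, t(f), stringsAsFactors = FALSE)
      }
    }
  }
  features <- if (length(rows)) do.call(rbind, rows) else NULL
  discards <- if (length(disc)) do.call(rbind, disc) else
    data.frame(subject_id = character(), session = integer(),
               window_index = integer(), reason = character())
  list(features = features, discards = discards)
}
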