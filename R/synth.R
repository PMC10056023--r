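#' Beat morphology template
#'
#' Describes one pulse-wave beat as a sum of three Gaussian-shaped
#' components on a per-beat time axis: a dominant systolic bump, a
#' dicrotic (reflected-wave) bump, and a broad low-amplitude envelope
#' that fills out the diastolic decay. The dicrotic notch is not a
#' component of its own: it is the trough that emerges between the
#' systolic and dicrotic bumps. `notch_time`/`notch_amp` record the
#' nominal notch location implied by the component layout; realised
#' landmark positions are always read off the sampled beat.
#'
#' In vessels stiffened by hypertension the reflected wave attenuates or
#' disappears, so hypertensive templates carry a reduced `dicrotic_amp`
#' or `dicrotic_present = FALSE`.
#'
#' @param systolic_amp Peak amplitude of the systolic component
#'   (arbitrary signal units; the record is generated around this scale).
#' @param systolic_time Time of the systolic component centre, seconds
#'   from beat onset.
#' @param notch_amp,notch_time Nominal dicrotic-notch amplitude/time.
#' @param dicrotic_amp,dicrotic_time Dicrotic component amplitude/time.
#' @param envelope_amp,envelope_time Broad envelope component
#'   amplitude/time.
#' @param component_widths Named numeric vector with elements `systolic`,
#'   `dicrotic`, `envelope`: Gaussian standard deviations in seconds.
#' @param dicrotic_present Logical; when `FALSE` the dicrotic component
#'   is omitted entirely and the beat has a single maximum.
#'
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(systolic_amp = 1.0,
                          systolic_time = 0.18,
                          notch_amp = 0.25,
                          notch_time = 0.36,
                          dicrotic_amp = 0.40,
                          dicrotic_time = 0.46,
                          envelope_amp = 0.12,
                          envelope_time = 0.30,
                          component_widths = c(systolic = 0.085,
                                               dicrotic = 0.080,
                                               envelope = 0.250),
                          dicrotic_present = TRUE) {
  tpl <- structure(
    list(systolic_amp = systolic_amp, systolic_time = systolic_time,
         notch_amp = notch_amp, notch_time = notch_time,
         dicrotic_amp = dicrotic_amp, dicrotic_time = dicrotic_time,
         envelope_amp = envelope_amp, envelope_time = envelope_time,
         component_widths = component_widths,
         dicrotic_present = isTRUE(dicrotic_present)),
    class = "beat_template")
  validate_beat_template(tpl)
  tpl
}

validate_beat_template <- function(tpl) {
  amps <- c(tpl$systolic_amp, tpl$dicrotic_amp, tpl$envelope_amp)
  if (any(!is.finite(amps)) || any(amps < 0))
    stop("beat_template: amplitudes must be finite and non-negative")
  if (any(tpl$component_widths <= 0))
    stop("beat_template: component widths must be positive")
  if (tpl$dicrotic_present) {
    if (!(tpl$systolic_time < tpl$notch_time &&
          tpl$notch_time < tpl$dicrotic_time))
      stop("beat_template: requires systolic_time < notch_time < dicrotic_time")
    if (!(tpl$systolic_amp > tpl$dicrotic_amp && tpl$dicrotic_amp > 0))
      stop("beat_template: requires systolic_amp > dicrotic_amp > 0")
  }
  invisible(tpl)
}

gaussian_bump <- function(t, centre, width, amp) {
  amp * exp(-0.5 * ((t - centre) / width)^2)
}

#' Evaluate the clean beat waveform at arbitrary times
#'
#' @param tpl A [beat_template()].
#' @param t Numeric vector of times (s) from beat onset.
#' @return Numeric vector of amplitudes.
#' @keywords internal
beat_waveform <- function(tpl, t) {
  w <- tpl$component_widths
  y <- gaussian_bump(t, tpl$systolic_time, w[["systolic"]], tpl$systolic_amp) +
    gaussian_bump(t, tpl$envelope_time, w[["envelope"]], tpl$envelope_amp)
  if (tpl$dicrotic_present)
    y <- y + gaussian_bump(t, tpl$dicrotic_time, w[["dicrotic"]], tpl$dicrotic_amp)
  y
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

#' Sample one beat and locate its landmarks
#'
#' Samples the template waveform at `fs` over one beat period and scans
#' the sampled beat for its realised landmarks (systolic peak, dicrotic
#' notch, dicrotic-wave peak). Landmarks are indices into the sampled
#' beat, so they are exact extrema of what was generated.
#'
#' @param tpl A [beat_template()].
#' @param fs Sampling rate in Hz.
#' @param period_s Beat period in seconds (default 0.8 s, i.e. 75 bpm).
#' @return List with `samples` and a `landmarks` list holding
#'   `systolic_idx/amp`, `notch_idx/amp`, `dicrotic_idx/amp` (`NA` with a
#'   missing flag when the beat has no notch/dicrotic wave).
#' @export
generate_beat <- function(tpl, fs, period_s = 0.8) {
  stopifnot(fs > 0, period_s > 0)
  validate_beat_template(tpl)
  n <- round(period_s * fs)
  t <- (seq_len(n) - 1L) / fs
  y <- beat_waveform(tpl, t)
  list(samples = y, landmarks = scan_beat_landmarks(y), period_s = period_s)
}

# Landmarks from a sampled clean beat: systolic = global max; notch =
# deepest local minimum after the systolic peak that is followed by a
# local maximum (the dicrotic wave); both flagged missing otherwise.
scan_beat_landmarks <- function(y) {
  sys_idx <- which.max(y)
  out <- list(systolic_idx = sys_idx, systolic_amp = y[sys_idx],
              notch_idx = NA_integer_, notch_amp = NA_real_,
              dicrotic_idx = NA_integer_, dicrotic_amp = NA_real_,
              notch_missing = TRUE, dicrotic_missing = TRUE)
  mins <- local_minima(y)
  maxs <- local_maxima(y)
  mins <- mins[mins > sys_idx]
  for (m in mins) {
    peak_after <- maxs[maxs > m]
    if (length(peak_after)) {
      out$notch_idx <- m
      out$notch_amp <- y[m]
      out$dicrotic_idx <- peak_after[1L]
      out$dicrotic_amp <- y[peak_after[1L]]
      out$notch_missing <- FALSE
      out$dicrotic_missing <- FALSE
      break
    }
  }
  out
}

#' Subject generation profile
#'
#' Everything needed to synthesise one subject's recordings: class label,
#' mean heart rate with beat-to-beat jitter, beat morphology, respiratory
#' baseline drift and additive noise levels, and an RNG seed.
#'
#' @param subject_id Character or integer identifier.
#' @param class_label `"healthy"` or `"hypertensive"`.
#' @param heart_rate_bpm Mean heart rate (beats per minute); must lie in
#'   `hr_band`.
#' @param hr_jitter_sd Standard deviation of the lognormal multiplicative
#'   beat-period jitter (default 3%).
#' @param template A [beat_template()].
#' @param drift_freq Respiratory drift frequency in Hz; the adult
#'   respiratory band is roughly 0.15-0.5 Hz and the default must lie
#'   inside it.
#' @param drift_amp Drift amplitude relative to the systolic amplitude.
#' @param noise_sd Gaussian noise standard deviation, same relative units.
#' @param mains_amp Amplitude of an optional 50 Hz interference tone.
#' @param rng_seed Integer seed making the subject's records reproducible.
#' @param hr_band Allowed heart-rate band (bpm), default 50-110.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id,
                            class_label = c("healthy", "hypertensive"),
                            heart_rate_bpm = 72,
                            hr_jitter_sd = 0.03,
                            template = beat_template(),
                            drift_freq = 0.25,
                            drift_amp = 0.30,
                            noise_sd = 0.05,
                            mains_amp = 0,
                            rng_seed = 1L,
                            hr_band = c(50, 110)) {
  class_label <- match.arg(class_label)
  if (heart_rate_bpm < hr_band[1] || heart_rate_bpm > hr_band[2])
    stop("subject_profile: heart_rate_bpm outside the plausible band [",
         hr_band[1], ", ", hr_band[2], "]")
  if (drift_freq <= 0) stop("subject_profile: drift_freq must be positive")
  validate_beat_template(template)
  structure(
    list(subject_id = as.character(subject_id), class_label = class_label,
         heart_rate_bpm = heart_rate_bpm, hr_jitter_sd = hr_jitter_sd,
         template = template, drift_freq = drift_freq,
         drift_amp = drift_amp, noise_sd = noise_sd, mains_amp = mains_amp,
         rng_seed = as.integer(rng_seed)),
    class = "subject_profile")
}

new_ppg_record <- function(samples, fs, subject_id, label, session,
                           processed = FALSE) {
  structure(list(samples = as.numeric(samples), fs = fs,
                 subject_id = subject_id, label = label,
                 session = session, processed = processed),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> subject %s (%s), session %s: %d samples @ %g Hz%s\n",
              x$subject_id, x$label, x$session, length(x$samples), x$fs,
              if (x$processed) " [preprocessed]" else ""))
  invisible(x)
}

#' Generate one subject-session PPG record with ground truth
#'
#' Concatenates beat-period-jittered beats sampled from the subject's
#' template, then adds a sinusoidal respiratory baseline drift and white
#' Gaussian noise (plus an optional 50 Hz tone). All per-beat landmark
#' positions, the trough positions between beats, and the exact baseline
#' curve are returned as ground truth. Fully reproducible from
#' `profile$rng_seed`.
#'
#' @param profile A [subject_profile()].
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate (Hz), default 100.
#' @param session Session tag stored in the record.
#' @return List with `record` (a `ppg_record`) and `ground_truth`: global
#'   sample indices `trough_idx`, `systolic_idx`, `notch_idx`,
#'   `dicrotic_idx` (NA where a beat lacks the landmark), amplitudes of
#'   the clean signal at those indices, the `baseline` curve, the clean
#'   (noise- and drift-free) signal, and the realised per-beat periods.
#' @export
generate_record <- function(profile, duration_s, fs = 100, session = 1L) {
  stopifnot(inherits(profile, "subject_profile"), duration_s > 0, fs > 0)
  n_target <- round(duration_s * fs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(profile$rng_seed)

  base_period <- 60 / profile$heart_rate_bpm
  clean <- numeric(0)
  onsets <- integer(0)      # beat start indices (1-based, global)
  landmarks <- list()
  periods <- numeric(0)
  while (length(clean) < n_target + round(2 * base_period * fs)) {
    period <- base_period * stats::rlnorm(1, 0, profile$hr_jitter_sd)
    beat <- generate_beat(profile$template, fs, period)
    onsets <- c(onsets, length(clean) + 1L)
    landmarks[[length(landmarks) + 1L]] <- beat$landmarks
    periods <- c(periods, period)
    clean <- c(clean, beat$samples)
  }

  offset <- onsets - 1L
  g <- function(field) {
    idx <- vapply(landmarks, function(l) as.integer(l[[field]]), integer(1))
    ifelse(is.na(idx), NA_integer_, idx + offset)
  }
  systolic_idx <- g("systolic_idx")
  notch_idx <- g("notch_idx")
  dicrotic_idx <- g("dicrotic_idx")

  # Realised troughs: argmin of the clean signal between consecutive
  # systolic peaks (consistent with what any extrema scan would find).
  trough_idx <- integer(0)
  sp <- systolic_idx[!is.na(systolic_idx)]
  if (length(sp) >= 2L) {
    trough_idx <- vapply(seq_len(length(sp) - 1L), function(i) {
      seg <- sp[i]:sp[i + 1L]
      seg[which.min(clean[seg])]
    }, integer(1))
  }

  keep_beat <- systolic_idx <= n_target
  clean <- clean[seq_len(n_target)]
  t <- (seq_len(n_target) - 1L) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  baseline <- profile$drift_amp * sin(2 * pi * profile$drift_freq * t + phase)
  noise <- stats::rnorm(n_target, 0, profile$noise_sd)
  mains <- if (profile$mains_amp > 0)
    profile$mains_amp * sin(2 * pi * 50 * t) else 0
  samples <- clean + baseline + noise + mains

  in_range <- function(idx) ifelse(!is.na(idx) & idx <= n_target, idx, NA_integer_)
  gt <- list(
    trough_idx = trough_idx[trough_idx <= n_target],
    systolic_idx = in_range(systolic_idx)[keep_beat],
    notch_idx = in_range(notch_idx)[keep_beat],
    dicrotic_idx = in_range(dicrotic_idx)[keep_beat],
    onset_idx = onsets[keep_beat],
    periods_s = periods[keep_beat],
    baseline = baseline,
    clean = clean,
    heart_rate_bpm = profile$heart_rate_bpm)
  gt$systolic_amp <- clean[gt$systolic_idx]
  gt$trough_amp <- clean[gt$trough_idx]

  rec <- new_ppg_record(samples, fs, profile$subject_id,
                        profile$class_label, session)
  list(record = rec, ground_truth = gt)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a class-balanced synthetic PPG cohort
#'
#' Emulates a two-group study design: `n_per_class` healthy and
#' `n_per_class` hypertensive subjects, `sessions` records each. Healthy
#' subjects carry a clear dicrotic wave; hypertensive subjects draw an
#' attenuated dicrotic amplitude and, with probability
#' `p_dicrotic_absent`, lose the reflected wave entirely. The
#' `separation` knob (0-1) scales the morphological contrast between the
#' classes so task difficulty is tunable; 1 gives the clearly separable
#' default.
#'
#' @param n_per_class Subjects per class (default 15, i.e. a 30-subject
#'   cohort).
#' @param sessions Records per subject (default 3).
#' @param duration_s Record length in seconds (default 1800, i.e. 30 min).
#' @param fs Sampling rate in Hz (default 100).
#' @param seed Integer master seed; all subject and record seeds derive
#'   from it.
#' @param separation Class-contrast scale in `[0, 1]`.
#' @param p_dicrotic_absent Probability that a hypertensive subject's
#'   reflected wave is absent rather than merely attenuated.
#' @param noise_sd,drift_amp Noise and drift levels passed to each
#'   [subject_profile()].
#' @return An object of class `ppg_cohort`: a list with `records` (each a
#'   `generate_record()` result) and a `manifest` data frame
#'   (subject_id, session, label, fs, heart_rate_bpm, dicrotic_present).
#' @export
generate_cohort <- function(n_per_class = 15, sessions = 3,
                            duration_s = 1800, fs = 100, seed = 1L,
                            separation = 1, p_dicrotic_absent = 0.5,
                            noise_sd = 0.03, drift_amp = 0.30) {
  stopifnot(n_per_class >= 1, sessions >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n_sub <- 2L * n_per_class
  labels <- rep(c("healthy", "hypertensive"), each = n_per_class)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_sub)

  profiles <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    hyp <- labels[i] == "hypertensive"
    hr <- min(108, max(52, stats::rnorm(1, if (hyp) 76 else 70, 6)))
    dic_amp <- if (hyp) {
      max(0.03, 0.40 - 0.12 * separation + stats::rnorm(1, 0, 0.02))
    } else max(0.2, 0.40 + stats::rnorm(1, 0, 0.03))
    dic_present <- if (hyp) stats::runif(1) >= p_dicrotic_absent else TRUE
    widths <- c(systolic = 0.085 * (1 + (if (hyp) 0.20 * separation else 0) +
                                      stats::rnorm(1, 0, 0.03)),
                dicrotic = 0.080 * (1 + stats::rnorm(1, 0, 0.03)),
                envelope = 0.250)
    tpl <- beat_template(
      systolic_amp = 1.0,
      systolic_time = 0.18 + stats::rnorm(1, 0, 0.008),
      notch_time = 0.36 + (if (hyp) 0.02 * separation else 0),
      dicrotic_amp = dic_amp,
      dicrotic_time = 0.46 + (if (hyp) 0.04 * separation else 0) +
        stats::rnorm(1, 0, 0.008),
      component_widths = widths,
      dicrotic_present = dic_present)
    profiles[[i]] <- subject_profile(
      subject_id = sprintf("S%02d", i), class_label = labels[i],
      heart_rate_bpm = hr, template = tpl,
      drift_freq = stats::runif(1, 0.15, 0.5),
      drift_amp = drift_amp, noise_sd = noise_sd,
      rng_seed = sub_seeds[i])
  }

  rec_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_sub * sessions),
                      nrow = n_sub)
  records <- list()
  manifest <- list()
  for (i in seq_len(n_sub)) {
    for (s in seq_len(sessions)) {
      pr <- profiles[[i]]
      pr$rng_seed <- rec_seeds[i, s]
      res <- generate_record(pr, duration_s, fs, session = s)
      records[[length(records) + 1L]] <- res
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject_id = pr$subject_id, session = s, label = pr$class_label,
        fs = fs, heart_rate_bpm = pr$heart_rate_bpm,
        dicrotic_present = pr$template$dicrotic_present,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(records = records,
                 manifest = do.call(rbind, manifest),
                 profiles = profiles,
                 params = list(n_per_class = n_per_class, sessions = sessions,
                               duration_s = duration_s, fs = fs, seed = seed,
                               separation = separation,
                               p_dicrotic_absent = p_dicrotic_absent,
                               noise_sd = noise_sd, drift_amp = drift_amp)),
            class = "ppg_cohort")
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cat(sprintf("<ppg_cohort> %d records: %d subjects x %d sessions, %g s @ %g Hz\n",
              length(x$records), 2 * x$params$n_per_class,
              x$params$sessions, x$params$duration_s, x$params$fs))
  invisible(x)
}
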