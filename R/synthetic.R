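#' Beat template for synthetic PPG pulses
#'
#' A single cardiac cycle is modelled as the sum of two Gaussian waves: a
#' systolic wave centred at `crest_time_s` after the pulse foot and a
#' diastolic (reflected) wave centred `sys_dia_delay_s` later. The four
#' morphological features of the analysis have exact counterparts here:
#' systolic amplitude = `sys_amp`, diastolic amplitude = `dia_amp`, crest
#' time = `crest_time_s`, and the stiffness index is the reciprocal of
#' `sys_dia_delay_s`.
#'
#' The defaults describe a slow-rising pulse with a late, well-separated
#' reflection wave, as seen in elderly patients with severe aortic
#' stenosis (pulsus parvus et tardus, smoothed dicrotic notch) — the
#' population whose waveforms this generator emulates.
#'
#' @param sys_amp Systolic wave amplitude (arbitrary units, > 0).
#' @param dia_amp Diastolic wave amplitude (same units, >= 0; at most
#'   `sys_amp`).
#' @param crest_time_s Foot-to-systolic-peak time in seconds.
#' @param sys_dia_delay_s Systolic-to-diastolic peak delay in seconds.
#' @param sys_width_s,dia_width_s Gaussian standard deviations of the two
#'   waves, seconds.
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(sys_amp = 1.0, dia_amp = 0.25,
                          crest_time_s = 0.37, sys_dia_delay_s = 0.44,
                          sys_width_s = 0.18, dia_width_s = 0.11) {
  if (sys_amp <= 0) abort_invalid_template("`sys_amp` must be > 0")
  if (dia_amp < 0) abort_invalid_template("`dia_amp` must be >= 0")
  if (dia_amp > sys_amp) {
    abort_invalid_template("`dia_amp` must not exceed `sys_amp` (the diastolic wave is the smaller reflection)")
  }
  if (crest_time_s <= 0 || sys_dia_delay_s <= 0 || sys_width_s <= 0 || dia_width_s <= 0) {
    abort_invalid_template("all template times must be > 0")
  }
  structure(
    list(sys_amp = sys_amp, dia_amp = dia_amp, crest_time_s = crest_time_s,
         sys_dia_delay_s = sys_dia_delay_s, sys_width_s = sys_width_s,
         dia_width_s = dia_width_s),
    class = "beat_template"
  )
}

# shortest inter-beat interval a template can be rendered into: both wave
# centres must lie inside the beat
min_renderable_ibi <- function(template) {
  if (template$dia_amp > 0) {
    template$crest_time_s + template$sys_dia_delay_s
  } else {
    template$crest_time_s
  }
}

#' Rhythm specification
#'
#' Inter-beat intervals (IBIs) are drawn i.i.d. around `60 / mean_hr_bpm`
#' seconds. In sinus mode they are Gaussian with standard deviation
#' `ibi_sd_s`; in atrial-fibrillation mode (`af_mode = TRUE`) they are
#' uniform over mean +/- 35%, a serially uncorrelated high-variance draw
#' that produces the extreme heart-rate variability characteristic of AF
#' without modelling true AF electrophysiology.
#'
#' @param mean_hr_bpm Mean heart rate, beats per minute, in (30, 200).
#' @param ibi_sd_s IBI standard deviation in seconds (sinus mode).
#' @param af_mode Logical; use the AF-like IBI draw.
#' @return An object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(mean_hr_bpm = 60, ibi_sd_s = 0.03, af_mode = FALSE) {
  if (mean_hr_bpm <= 30 || mean_hr_bpm >= 200) {
    abort_invalid_parameter("`mean_hr_bpm` must be in (30, 200)")
  }
  if (ibi_sd_s < 0) abort_invalid_parameter("`ibi_sd_s` must be >= 0")
  structure(
    list(mean_hr_bpm = mean_hr_bpm, ibi_sd_s = ibi_sd_s,
         af_mode = isTRUE(af_mode)),
    class = "rhythm_spec"
  )
}

#' Noise specification
#'
#' Additive disturbances on top of the beat train: sinusoidal baseline
#' wander (respiratory-band, below the 1-Hz filter cutoff so the
#' band-pass provably removes it), white sensor noise, and optional
#' large-amplitude artifact bursts emulating motion.
#'
#' @param baseline_wander_amp Wander amplitude in signal units (>= 0).
#' @param baseline_wander_freq_hz Wander frequency in Hz, in (0, 0.8).
#' @param white_noise_sd White-noise standard deviation in signal units.
#' @param artifact_burst_rate_per_min Expected number of 0.5-2 s
#'   high-amplitude bursts per minute (Poisson).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_wander_amp = 0.25,
                       baseline_wander_freq_hz = 0.25,
                       white_noise_sd = 0.02,
                       artifact_burst_rate_per_min = 0) {
  if (baseline_wander_amp < 0 || white_noise_sd < 0 || artifact_burst_rate_per_min < 0) {
    abort_invalid_parameter("noise amplitudes and rates must be >= 0")
  }
  if (baseline_wander_amp > 0 &&
      (baseline_wander_freq_hz <= 0 || baseline_wander_freq_hz >= 0.8)) {
    abort_invalid_parameter("`baseline_wander_freq_hz` must be in (0, 0.8)")
  }
  structure(
    list(baseline_wander_amp = baseline_wander_amp,
         baseline_wander_freq_hz = baseline_wander_freq_hz,
         white_noise_sd = white_noise_sd,
         artifact_burst_rate_per_min = artifact_burst_rate_per_min),
    class = "noise_spec"
  )
}

#' Silent noise specification (no wander, no noise, no bursts)
#' @return A [noise_spec] with all amplitudes zero.
#' @export
noise_none <- function() {
  noise_spec(baseline_wander_amp = 0, white_noise_sd = 0,
             artifact_burst_rate_per_min = 0)
}

#' Render one beat
#'
#' Evaluates the two-Gaussian pulse model on a uniform sample grid
#' spanning one inter-beat interval. Time 0 is the pulse foot (beat
#' onset).
#'
#' @param template A [beat_template].
#' @param ibi_s Inter-beat interval in seconds.
#' @param fs_hz Sampling rate in Hz.
#' @return Numeric vector of `round(ibi_s * fs_hz)` samples.
#' @export
render_beat <- function(template, ibi_s, fs_hz) {
  stopifnot(inherits(template, "beat_template"))
  if (fs_hz <= 0) abort_invalid_parameter("`fs_hz` must be > 0")
  if (ibi_s <= min_renderable_ibi(template)) {
    abort_invalid_template(sprintf(
      "inter-beat interval %.3f s too short for template (needs > %.3f s)",
      ibi_s, min_renderable_ibi(template)))
  }
  n <- round(ibi_s * fs_hz)
  t <- (seq_len(n) - 1L) / fs_hz
  eval_beat(template, t)
}

# two-Gaussian pulse evaluated at times t (seconds since beat onset)
eval_beat <- function(template, t) {
  template$sys_amp *
    exp(-((t - template$crest_time_s)^2) / (2 * template$sys_width_s^2)) +
    template$dia_amp *
    exp(-((t - template$crest_time_s - template$sys_dia_delay_s)^2) /
          (2 * template$dia_width_s^2))
}

#' Render a full synthetic PPG recording
#'
#' Concatenates beats with inter-beat intervals drawn per the rhythm
#' specification, anchored on a continuous time axis (so rounding does
#' not accumulate), then adds baseline wander, white noise, and artifact
#' bursts. Returns both the recording and the exact ground-truth fiducial
#' positions of every rendered beat.
#'
#' In AF mode the uniform IBI draw is floored at the template's minimum
#' renderable interval, so very short diastoles never clip the diastolic
#' wave centre.
#'
#' @param template A [beat_template].
#' @param rhythm A [rhythm_spec].
#' @param noise A [noise_spec].
#' @param duration_s Recording length in seconds (>= 10).
#' @param fs_hz Sampling rate in Hz (default 128, the wearable's green
#'   channel rate).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list with elements `record` (a [ppg_record]) and `fiducials`,
#'   a data frame with one row per beat: `onset_s`, `sys_s`, `dia_s`
#'   (seconds) and 1-based sample indices `onset_idx`, `sys_idx`,
#'   `dia_idx` (`dia_*` is `NA` when `dia_amp == 0`).
#' @export
render_recording <- function(template, rhythm = rhythm_spec(),
                             noise = noise_spec(), duration_s = 70,
                             fs_hz = 128, seed = 1L) {
  stopifnot(inherits(template, "beat_template"), inherits(rhythm, "rhythm_spec"),
            inherits(noise, "noise_spec"))
  if (duration_s < 10) abort_invalid_parameter("`duration_s` must be >= 10")
  with_seed(seed, {
    mean_ibi <- 60 / rhythm$mean_hr_bpm
    floor_ibi <- min_renderable_ibi(template) * 1.001
    n_draw <- ceiling(duration_s / (mean_ibi * 0.6)) + 2L
    ibis <- if (rhythm$af_mode) {
      stats::runif(n_draw, 0.65 * mean_ibi, 1.35 * mean_ibi)
    } else if (rhythm$ibi_sd_s > 0) {
      stats::rnorm(n_draw, mean_ibi, rhythm$ibi_sd_s)
    } else {
      rep(mean_ibi, n_draw)
    }
    ibis <- pmax(ibis, floor_ibi)
    if (mean_ibi <= floor_ibi) {
      abort_invalid_template("mean inter-beat interval too short for template")
    }
    onsets <- cumsum(c(0, ibis))
    onsets <- onsets[onsets < duration_s]
    n_samp <- round(duration_s * fs_hz)
    y <- numeric(n_samp)
    bounds <- round(c(onsets, duration_s) * fs_hz)  # beat k: samples bounds[k]..bounds[k+1]-1 (0-based)
    for (k in seq_along(onsets)) {
      i0 <- bounds[k]; i1 <- min(bounds[k + 1L], n_samp) - 1L
      if (i1 < i0) next
      t_rel <- (i0:i1) / fs_hz - onsets[k]
      y[(i0 + 1L):(i1 + 1L)] <- y[(i0 + 1L):(i1 + 1L)] + eval_beat(template, t_rel)
    }
    tt <- (seq_len(n_samp) - 1L) / fs_hz
    if (noise$baseline_wander_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      y <- y + noise$baseline_wander_amp *
        sin(2 * pi * noise$baseline_wander_freq_hz * tt + phase)
    }
    if (noise$white_noise_sd > 0) {
      y <- y + stats::rnorm(n_samp, 0, noise$white_noise_sd)
    }
    if (noise$artifact_burst_rate_per_min > 0) {
      n_burst <- stats::rpois(1, noise$artifact_burst_rate_per_min * duration_s / 60)
      for (b in seq_len(n_burst)) {
        b_start <- stats::runif(1, 0, max(duration_s - 2, 0))
        b_dur <- stats::runif(1, 0.5, 2)
        idx <- which(tt >= b_start & tt < b_start + b_dur)
        y[idx] <- y[idx] + stats::runif(length(idx), -8, 8) * template$sys_amp
      }
    }
    sys_s <- onsets + template$crest_time_s
    dia_s <- if (template$dia_amp > 0) sys_s + template$sys_dia_delay_s else rep(NA_real_, length(onsets))
    fiducials <- data.frame(
      beat = seq_along(onsets),
      onset_s = onsets, sys_s = sys_s, dia_s = dia_s,
      onset_idx = round(onsets * fs_hz) + 1L,
      sys_idx = round(sys_s * fs_hz) + 1L,
      dia_idx = ifelse(is.na(dia_s), NA_integer_, round(dia_s * fs_hz) + 1L)
    )
    list(record = ppg_record(y, fs_hz), fiducials = fiducials)
  })
}

#' Cohort specification
#'
#' Parameters of a synthetic study cohort: the number of subjects, the
#' prevalence of the high filling-pressure class (wedge pressure >= 12
#' mmHg), the pressure ranges the two classes are drawn from, and the
#' strength of the coupling between class and waveform morphology.
#'
#' `effect_size` is measured in within-class standard deviations of the
#' morphology parameters: the high class's mean template is shifted by
#' `effect_size` between-subject SDs (lower systolic amplitude, longer
#' crest time, shorter systolic-to-diastolic delay). These directions are
#' conventions chosen to create separability for validation, not
#' physiological claims. `effect_size = 0` makes the two classes
#' exchangeable.
#'
#' @param n_subjects Number of subjects (default 14, a 7/7 split).
#' @param prevalence_high Fraction of subjects in the high class.
#' @param pcwp_low_range_mmHg,pcwp_high_range_mmHg Pressure ranges the
#'   class labels are drawn uniformly from; the low range must lie in
#'   \[0, 12) and the high range in \[12, 40\].
#' @param effect_size Class-morphology coupling, in within-class SDs.
#' @param af_rate Probability that a subject has the AF-like rhythm.
#' @param pcwp_link `"class"` (default): morphology depends on class
#'   only, pressure is uniform within class — no continuous dose-response.
#'   `"linear"`: template shifts scale linearly with the pressure itself,
#'   for testing continuous regression recovery.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 14, prevalence_high = 0.5,
                        pcwp_low_range_mmHg = c(4, 11.9),
                        pcwp_high_range_mmHg = c(12, 20),
                        effect_size = 2.0, af_rate = 0,
                        pcwp_link = c("class", "linear"), seed = 1L) {
  pcwp_link <- match.arg(pcwp_link)
  if (n_subjects < 2) abort_degenerate("a cohort needs at least 2 subjects")
  if (prevalence_high < 0 || prevalence_high > 1) {
    abort_invalid_parameter("`prevalence_high` must be in [0, 1]")
  }
  lo <- pcwp_low_range_mmHg; hi <- pcwp_high_range_mmHg
  if (lo[1] < 0 || lo[2] >= 12 || lo[1] > lo[2]) {
    abort_invalid_parameter("`pcwp_low_range_mmHg` must lie within [0, 12)")
  }
  if (hi[1] < 12 || hi[2] > 40 || hi[1] > hi[2]) {
    abort_invalid_parameter("`pcwp_high_range_mmHg` must lie within [12, 40]")
  }
  if (effect_size < 0) abort_invalid_parameter("`effect_size` must be >= 0")
  structure(
    list(n_subjects = as.integer(n_subjects), prevalence_high = prevalence_high,
         pcwp_low_range_mmHg = lo, pcwp_high_range_mmHg = hi,
         effect_size = effect_size, af_rate = af_rate,
         pcwp_link = pcwp_link, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Between-subject SDs of the template parameters: the scale in which
# effect_size is expressed. One place, so cohort generation and any
# power reasoning agree.
cohort_param_sd <- function() {
  c(sys_amp = 0.08, dia_amp = 0.02, crest_time_s = 0.020,
    sys_dia_delay_s = 0.020)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject beat templates around class-conditional means,
#' pressures uniformly within each class's range, rhythm (with AF-like
#' subjects at the given rate), and optionally renders each subject's
#' waveform. Everything is deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec].
#' @param render Logical; render waveforms (default) or return
#'   ground-truth features only (fast path for calibration studies).
#' @param duration_s Rendered recording length, seconds.
#' @param fs_hz Sampling rate, Hz.
#' @param noise A [noise_spec] applied to every subject.
#' @return An object of class `ppg_cohort`: a list of subjects, each with
#'   `subject_id`, `pcwp_mmHg`, `pcwp_class`, `af`, `template`, `rhythm`,
#'   `gt` (named vector of ground-truth features), and — when rendered —
#'   `record` and `fiducials`.
#' @export
generate_cohort <- function(spec, render = TRUE, duration_s = 80,
                            fs_hz = 128, noise = noise_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  n_high <- round(n * spec$prevalence_high)
  n_low <- n - n_high
  if (min(n_high, n_low) < 2) {
    abort_degenerate(sprintf(
      "degenerate cohort: %d low / %d high subjects (need >= 2 per class)",
      n_low, n_high))
  }
  sds <- cohort_param_sd()
  base <- beat_template()
  with_seed(spec$seed, {
    classes <- sample(rep(c("low", "high"), c(n_low, n_high)))
    pcwp <- ifelse(classes == "high",
                   stats::runif(n, spec$pcwp_high_range_mmHg[1], spec$pcwp_high_range_mmHg[2]),
                   stats::runif(n, spec$pcwp_low_range_mmHg[1], spec$pcwp_low_range_mmHg[2]))
    af <- stats::runif(n) < spec$af_rate
    # elderly aortic-stenosis cohort under beta-blockade and sedation:
    # a narrow rate band around 60 bpm, so that class differences are
    # carried by pulse morphology rather than rate; capped per subject
    # below so the template fits each drawn inter-beat interval and the
    # diastolic wave stays inside the half-interval search window
    hr <- pmin(pmax(stats::rnorm(n, 60, 0.8), 58), 62)
    # class-driven morphology shift, in units of between-subject SD
    z <- if (spec$pcwp_link == "linear") {
      (pcwp - 12) / 6  # one class width ~ 6 mmHg
    } else {
      as.numeric(classes == "high")
    }
    shift <- spec$effect_size * z
    subject_seeds <- sample.int(.Machine$integer.max, n)
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      tmpl <- beat_template(
        sys_amp = max(0.2, stats::rnorm(1, base$sys_amp - shift[i] * sds["sys_amp"], sds["sys_amp"])),
        dia_amp = stats::rnorm(1, base$dia_amp, sds["dia_amp"]),
        crest_time_s = min(max(stats::rnorm(1, base$crest_time_s + shift[i] * sds["crest_time_s"], sds["crest_time_s"]), 0.30), 0.44),
        sys_dia_delay_s = min(max(stats::rnorm(1, base$sys_dia_delay_s - shift[i] * sds["sys_dia_delay_s"], sds["sys_dia_delay_s"]), 0.37), 0.48),
        sys_width_s = base$sys_width_s, dia_width_s = base$dia_width_s
      )
      # diastolic wave stays a modest, broad shoulder: large enough to
      # locate, small enough that the systolic detector never takes it
      # for a beat
      tmpl$dia_amp <- min(max(tmpl$dia_amp, 0.20), 0.30, 0.9 * tmpl$sys_amp)
      # cap the rate so the subject's template fits inside nearly every
      # drawn inter-beat interval and the diastolic peak lies inside the
      # half-interval search window with ~5% margin
      hr_i <- min(hr[i], 0.9 * 60 / min_renderable_ibi(tmpl),
                  28.5 / tmpl$sys_dia_delay_s)
      rhy <- rhythm_spec(mean_hr_bpm = hr_i, ibi_sd_s = 0.03, af_mode = af[i])
      mean_ibi <- 60 / hr_i
      hr[i] <- hr_i
      gt_hrv <- if (af[i]) {
        # SD of the floored uniform mean +/- 35% draw
        flo <- min_renderable_ibi(tmpl) * 1.001
        a <- max(0.65 * mean_ibi, flo); b <- 1.35 * mean_ibi
        (b - a) / sqrt(12)
      } else {
        rhy$ibi_sd_s
      }
      gt <- c(hr_bpm = hr[i], hrv_s = gt_hrv, sa = tmpl$sys_amp,
              da = tmpl$dia_amp, ct_s = tmpl$crest_time_s,
              lasi_inv_s = 1 / tmpl$sys_dia_delay_s)
      subj <- list(
        subject_id = sprintf("S%02d", i), pcwp_mmHg = pcwp[i],
        pcwp_class = classes[i], af = af[i], template = tmpl,
        rhythm = rhy, gt = gt, seed = subject_seeds[i]
      )
      if (render) {
        rr <- render_recording(tmpl, rhy, noise, duration_s = duration_s,
                               fs_hz = fs_hz, seed = subject_seeds[i])
        subj$record <- rr$record
        subj$fiducials <- rr$fiducials
      }
      subjects[[i]] <- subj
    }
    structure(subjects, class = "ppg_cohort", spec = spec)
  })
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cl <- vapply(x, function(s) s$pcwp_class, character(1))
  cat(sprintf("<ppg_cohort> %d subjects (%d low / %d high PCWP), %d AF-like\n",
              length(x), sum(cl == "low"), sum(cl == "high"),
              sum(vapply(x, function(s) s$af, logical(1)))))
  invisible(x)
}

#' Ground-truth feature table of a cohort
#'
#' @param cohort A `ppg_cohort`.
#' @return A data frame with one row per subject: `subject_id`, the six
#'   ground-truth features, `pcwp_mmHg`, `pcwp_class`, `af_flag`.
#' @export
cohort_ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  out <- do.call(rbind, lapply(cohort, function(s) {
    data.frame(subject_id = s$subject_id, t(s$gt), pcwp_mmHg = s$pcwp_mmHg,
               pcwp_class = s$pcwp_class, af_flag = s$af)
  }))
  rownames(out) <- NULL
  out
}

#' Write a cohort to disk
#'
#' Writes one waveform CSV per subject (`<subject_id>.csv`, columns
#' `time_s`, `amplitude`) plus a manifest CSV with the pressure labels
#' and ground-truth feature columns prefixed `gt_`.
#'
#' @param cohort A rendered `ppg_cohort`.
#' @param dir Output directory (created if missing).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    if (is.null(s$record)) {
      abort_invalid_parameter("cohort was generated with render = FALSE; nothing to write")
    }
    wf <- file.path(dir, paste0(s$subject_id, ".csv"))
    write_waveform_csv(s$record, wf)
    gt <- as.list(s$gt)
    names(gt) <- paste0("gt_", names(gt))
    data.frame(subject_id = s$subject_id, waveform_path = basename(wf),
               pcwp_mmHg = s$pcwp_mmHg, af_flag = s$af, gt,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}
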