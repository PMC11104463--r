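#' Detect systolic peaks
#'
#' Finds local maxima of the filtered signal with a minimum prominence of
#' `min_prominence_frac` times the median beat amplitude — estimated
#' robustly as the median per-second peak-to-trough range of the signal —
#' and a minimum separation of `min_separation_s` (0.33 s by default,
#' i.e. a ~180 bpm ceiling). When two candidates are closer than the
#' minimum separation the larger one is kept. The prominence floor is
#' what rejects secondary (diastolic/reflected) waves riding on the
#' pulse; only the dominant systolic crest of each beat survives it.
#'
#' @param x A [ppg_record] or numeric vector of filtered samples.
#' @param fs_hz Sampling rate in Hz (ignored when `x` is a record).
#' @param min_separation_s Minimum peak separation, seconds.
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   median beat amplitude (median per-second peak-to-trough range).
#' @return Strictly increasing integer vector of peak sample indices
#'   (1-based).
#' @export
detect_systolic_peaks <- function(x, fs_hz = NULL, min_separation_s = 0.33,
                                  min_prominence_frac = 0.3) {
  y <- if (inherits(x, "ppg_record")) x$samples else as.numeric(x)
  if (inherits(x, "ppg_record")) fs_hz <- x$fs_hz
  if (is.null(fs_hz) || fs_hz <= 0) abort_invalid_parameter("`fs_hz` required")
  if (length(y) < 2 * fs_hz) {
    abort_insufficient_data("need at least 2 s of signal for peak detection")
  }
  cand <- local_maxima(y)
  if (length(cand) < 2L) {
    abort_insufficient_beats("fewer than 2 candidate peaks found")
  }
  # enforce separation greedily from the tallest candidate down
  min_sep <- round(min_separation_s * fs_hz)
  keep <- logical(length(cand))
  ord <- order(y[cand], decreasing = TRUE)
  taken <- integer(0)
  for (j in ord) {
    p <- cand[j]
    if (!length(taken) || all(abs(taken - p) >= min_sep)) {
      keep[j] <- TRUE
      taken <- c(taken, p)
    }
  }
  pk <- sort(cand[keep])
  prom <- peak_prominence(y, pk)
  thr <- min_prominence_frac * median_beat_amplitude(y, fs_hz)
  pk <- pk[prom >= thr]
  if (length(pk) < 2L) {
    abort_insufficient_beats("fewer than 2 systolic peaks detected")
  }
  pk
}

# robust per-window amplitude scale: the median, over whole seconds, of
# the within-second peak-to-trough range. With at least one beat per
# second (HR >= 60) this tracks the typical systolic swing; at lower
# rates it underestimates mildly, which only loosens the floor.
median_beat_amplitude <- function(y, fs_hz) {
  n_sec <- floor(length(y) / fs_hz)
  if (n_sec < 2) return(diff(range(y)))
  rng <- vapply(seq_len(n_sec), function(k) {
    diff(range(y[(round((k - 1) * fs_hz) + 1L):min(round(k * fs_hz), length(y))]))
  }, numeric(1))
  stats::median(rng)
}

# topographic prominence of each peak: height above the higher of the two
# valley floors separating it from the nearest taller terrain (or the
# signal edge)
peak_prominence <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(p) {
    h <- y[p]
    if (p <= 1L || p >= n) return(0)
    left <- y[seq_len(p - 1L)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l)) {
      if (max(higher_l) + 1L > p - 1L) h else min(left[(max(higher_l) + 1L):(p - 1L)])
    } else {
      min(left)
    }
    right <- y[(p + 1L):n]
    higher_r <- which(right > h)
    rmin <- if (length(higher_r)) {
      if (min(higher_r) - 1L < 1L) h else min(right[seq_len(min(higher_r) - 1L)])
    } else {
      min(right)
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Locate pulse feet and diastolic peaks
#'
#' For each systolic peak after the first, the pulse foot is the signal
#' minimum on the interval from the previous systolic peak (exclusive) to
#' the current one (inclusive). The diastolic peak is the highest local
#' maximum within half an inter-beat interval after the systolic peak,
#' among maxima with prominence of at least 5% of the beat amplitude
#' (sub-percent noise ripples on the systolic decay are not candidate
#' waves); when no such maximum exists (smoothed dicrotic notch), the
#' inflection point of the decay — the flattest point, where the first
#' derivative attains its maximum between the second derivative's zero
#' crossings — is used instead; beats with neither are kept but marked
#' `quality_ok = FALSE`.
#'
#' All fiducials also carry a sub-sample position (`*_pos`, fractional
#' samples, parabolic refinement) used by the timing features.
#'
#' @param x A [ppg_record] or numeric vector of filtered samples.
#' @param sys_peaks Integer vector from [detect_systolic_peaks()].
#' @param fs_hz Sampling rate in Hz (ignored when `x` is a record).
#' @return A data frame of beats: `foot_idx`, `sys_peak_idx`,
#'   `dia_peak_idx` (NA when absent), `foot_pos`, `sys_pos`, `dia_pos`,
#'   `quality_ok`.
#' @export
locate_foot_and_diastolic <- function(x, sys_peaks, fs_hz = NULL) {
  y <- if (inherits(x, "ppg_record")) x$samples else as.numeric(x)
  if (inherits(x, "ppg_record")) fs_hz <- x$fs_hz
  if (length(sys_peaks) < 2L) {
    abort_insufficient_beats("need at least 2 systolic peaks")
  }
  med_ibi <- stats::median(diff(sys_peaks))
  n <- length(y)
  if (is.null(fs_hz) || !is.finite(fs_hz)) fs_hz <- med_ibi  # scale fallback
  amp_scale <- median_beat_amplitude(y, fs_hz)
  rows <- lapply(2:length(sys_peaks), function(k) {
    prev <- sys_peaks[k - 1L]; cur <- sys_peaks[k]
    seg <- (prev + 1L):cur
    foot <- seg[which.min(y[seg])]
    ibi <- if (k < length(sys_peaks)) sys_peaks[k + 1L] - cur else med_ibi
    hi <- min(cur + round(0.5 * ibi), n)
    dia <- NA_integer_
    quality <- TRUE
    if (hi > cur + 2L) {
      sub <- y[cur:hi]
      lm <- local_maxima(sub)
      if (length(lm)) {
        lm_abs <- cur + lm - 1L
        lm_abs <- lm_abs[peak_prominence(y, lm_abs) >= 0.05 * amp_scale]
        lm <- lm_abs - cur + 1L
      }
      if (length(lm)) {
        dia <- cur + lm[which.max(sub[lm])] - 1L
      } else {
        infl <- shoulder_candidates(sub)
        if (length(infl)) {
          dia <- cur + infl[1L] - 1L
        } else {
          quality <- FALSE
        }
      }
    } else {
      quality <- FALSE
    }
    if (foot >= cur) quality <- FALSE
    data.frame(
      foot_idx = foot, sys_peak_idx = cur, dia_peak_idx = dia,
      foot_pos = refine_trough(y, foot), sys_pos = refine_peak(y, cur),
      dia_pos = if (is.na(dia)) NA_real_ else refine_peak(y, dia),
      quality_ok = quality
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Shoulder points of a decaying pulse tail: interior local maxima of the
# first derivative, i.e. where the decay decelerates and re-accelerates
# around a reflected wave that never rises to a local maximum of the
# signal itself. A featureless (e.g. pure Gaussian) decay has no such
# point, so beats without any diastolic wave yield no candidate. Returned
# sorted by decreasing first-derivative value (flattest shoulder first).
shoulder_candidates <- function(seg) {
  if (length(seg) < 5L) return(integer(0))
  d1 <- diff(seg)
  lm <- local_maxima(d1)
  lm <- lm[lm > 2L & lm < length(seg) - 2L]
  if (!length(lm)) return(integer(0))
  lm[order(d1[lm], decreasing = TRUE)] + 1L
}
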