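# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: AUC by exhaustive pairwise comparison,
# Mann-Whitney p by full enumeration of rank assignments, and the filter
# response from the transfer function directly.

# (wins + half-ties) / (n1 * n0) over every positive-negative pair
brute_force_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1)
# assignments of the pooled ranks to group A (valid for untied data)
enumerate_mwu_p <- function(a, b) {
  stopifnot(!anyDuplicated(c(a, b)))
  na <- length(a)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(na + length(b), na)
  u_all <- apply(idx, 2, function(i) sum(i) - na * (na + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# amplitude gain of forward-backward Butterworth band-pass filtering at
# frequency f_hz: zero-phase filtering applies the squared single-pass
# magnitude response |H(f)|^2
filtfilt_gain <- function(f_hz, fs_hz, low_hz = 1, high_hz = 5, order = 2) {
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs_hz / 2), type = "pass")
  w <- 2 * pi * f_hz / fs_hz
  zb <- exp(-1i * w * (seq_along(bf$b) - 1))
  za <- exp(-1i * w * (seq_along(bf$a) - 1))
  Mod(sum(bf$b * zb) / sum(bf$a * za))^2
}

# render -> band-pass -> trim: the standard chain on a clean recording
clean_filtered_segment <- function(template = beat_template(),
                                   hr_bpm = 60, ibi_sd_s = 0,
                                   duration_s = 70, seed = 1) {
  rr <- render_recording(template, rhythm_spec(hr_bpm, ibi_sd_s),
                         noise_none(), duration_s = duration_s,
                         fs_hz = 128, seed = seed)
  list(filtered = trim_transient(bandpass(rr$record), 10),
       raw = rr$record, fiducials = rr$fiducials)
}
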