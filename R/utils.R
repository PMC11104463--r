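#' @keywords internal
"_PACKAGE"

# Classed error helpers: every user-facing failure mode gets a condition
# class so callers (and the pipeline's per-subject exclusion logic) can
# distinguish data problems from programming errors.
abort_pw <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "pulsewedge_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_insufficient_data <- function(msg) abort_pw(msg, "pulsewedge_insufficient_data")
abort_insufficient_beats <- function(msg) abort_pw(msg, "pulsewedge_insufficient_beats")
abort_invalid_parameter <- function(msg) abort_pw(msg, "pulsewedge_invalid_parameter")
abort_invalid_template <- function(msg) abort_pw(msg, "pulsewedge_invalid_template")
abort_degenerate <- function(msg) abort_pw(msg, "pulsewedge_degenerate")

# Run code with a private RNG stream, restoring the caller's .Random.seed.
# All stochastic functions in the package route their randomness through
# this helper so identical seeds give bit-identical output and no global
# RNG state leaks.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Parabolic (three-point) interpolation of an extremum's sub-sample
# location. `i` indexes a local maximum of `y`; the return value is the
# vertex abscissa of the parabola through (i-1, i, i+1), in samples.
# At 128 Hz a one-sample grid is coarse relative to crest time, so all
# timing fiducials are refined this way before conversion to seconds.
refine_peak <- function(y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(as.numeric(i))
  a <- y[i - 1L]; b <- y[i]; c <- y[i + 1L]
  den <- a - 2 * b + c
  if (!is.finite(den) || den == 0) return(as.numeric(i))
  off <- 0.5 * (a - c) / den
  # a true extremum's vertex lies within half a sample; flat or
  # inflection-like neighbourhoods give meaningless large offsets
  if (abs(off) > 0.5) off <- 0
  as.numeric(i) + off
}

refine_trough <- function(y, i) refine_peak(-y, i)

# strictly-interior local maxima of a numeric vector
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  d <- diff(y)
  # flat-top plateaus: treat first sample of the plateau as the maximum
  s <- sign(d)
  s[s == 0] <- 1
  which(diff(s) == -2) + 1L
}
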