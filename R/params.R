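#' Model parameters for the two-population streaming network
#'
#' Bundles every scalar parameter of the delayed Wilson-Cowan pair driven by
#' an alternating two-tone sequence: the coupling strengths, time constants,
#' inhibitory delay, activity threshold, and the stimulus timing.  The
#' cross-frequency input strength `d` can either be given directly or derived
#' from the unitless tone-frequency difference `df` through
#' `d = c * (1 - df^(1/m))`.
#'
#' @param a excitatory coupling strength between the units (dimensionless,
#'   >= 0).
#' @param b inhibitory coupling strength (dimensionless, >= 0).
#' @param c on-frequency input strength (>= 0); drives a unit during its own
#'   tone.
#' @param d cross-frequency input strength (>= 0, at most `c`); drives a unit
#'   during the other tone.  Give either `d` or `df`.
#' @param df unitless tone-frequency difference in \[0, 1\]; mapped to `d` via
#'   [df_to_d()].
#' @param tau unit (firing-rate) time constant in seconds (> 0).
#' @param tau_i inhibitory synaptic decay time constant in seconds (> 0);
#'   typically much larger than `tau` (slow-fast regime).
#' @param D inhibitory delay in seconds (>= 0).
#' @param theta activity threshold of the gain, in (0, 1).
#' @param TD tone duration in seconds (> 0).
#' @param TR tone repetition time in seconds (> 0); give either `TR` or `PR`.
#' @param PR presentation rate in Hz (`PR = 1/TR`).
#' @param m positive integer exponent of the `df` to `d` mapping.
#' @param slope sigmoid steepness lambda (> 0); only used by the smooth gain.
#'
#' @return An object of class `"two_tone_params"`: a named list of the
#'   parameters above (with `d`, `TR` resolved and `PR`, `df` stored when
#'   supplied).
#' @seealso [validate_params()], [preset_params()], [df_to_d()]
#' @examples
#' p <- model_params(a = 2, b = 2.8, c = 5.5, df = 0.02, tau = 0.025,
#'                   tau_i = 0.25, D = 0.015, theta = 0.5, TD = 0.022, PR = 6)
#' validate_params(p)
#' @export
model_params <- function(a, b, c, d = NULL, df = NULL, tau = 0.025,
                         tau_i = 0.25, D = 0.015, theta = 0.5, TD = 0.022,
                         TR = NULL, PR = NULL, m = 6L, slope = 30) {
  if (is.null(TR) && is.null(PR))
    stop("supply either `TR` (seconds) or `PR` (Hz)")
  if (is.null(TR)) TR <- 1 / PR
  if (is.null(PR)) PR <- 1 / TR
  if (is.null(d) && is.null(df))
    stop("supply either `d` or `df`")
  if (is.null(d)) d <- df_to_d(c, df, m)
  p <- list(a = a, b = b, c = c, d = d, df = df, tau = tau, tau_i = tau_i,
            D = D, theta = theta, TD = TD, TR = TR, PR = PR,
            m = as.integer(m), slope = slope)
  num <- p[setdiff(names(p), "df")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1))))
    stop("malformed parameters: all fields must be finite scalars")
  neg <- c("a", "b", "c", "d", "D")
  if (any(unlist(p[neg]) < 0))
    stop("malformed parameters: a, b, c, d, D must be non-negative")
  if (p$tau <= 0 || p$tau_i <= 0 || p$TD <= 0 || p$TR <= 0 || p$slope <= 0)
    stop("malformed parameters: tau, tau_i, TD, TR, slope must be positive")
  if (p$theta <= 0 || p$theta >= 1)
    stop("malformed parameters: theta must lie in (0, 1)")
  if (p$m < 1) stop("malformed parameters: m must be a positive integer")
  structure(p, class = "two_tone_params")
}

#' @export
print.two_tone_params <- function(x, ...) {
  cat("Two-tone streaming model parameters\n")
  cat(sprintf("  coupling   a = %g, b = %g\n", x$a, x$b))
  cat(sprintf("  inputs     c = %g, d = %g%s\n", x$c, x$d,
              if (!is.null(x$df)) sprintf(" (df = %g, m = %d)", x$df, x$m)
              else ""))
  cat(sprintf("  times      tau = %g s, tau_i = %g s, D = %g s\n",
              x$tau, x$tau_i, x$D))
  cat(sprintf("  stimulus   TD = %g s, TR = %g s (PR = %g Hz)\n",
              x$TD, x$TR, x$PR))
  cat(sprintf("  gain       theta = %g, slope = %g\n", x$theta, x$slope))
  v <- validate_params(x)
  if (length(v)) cat("  VIOLATED:", paste(v, collapse = ", "), "\n")
  invisible(x)
}

#' Check the structural parameter conditions
#'
#' Evaluates the standing assumptions of the model: the uniqueness condition
#' `U1` (`a - b < theta`, the quiescent point is the only input-free
#' equilibrium), the responsiveness condition `U2` (`c >= theta`), the
#' tonotopy ordering `c >= d`, and the stimulus-timing restrictions
#' `TR >= TD` and `TR >= D`.
#'
#' @param p a [model_params()] object.
#' @return Character vector of violated condition identifiers (subset of
#'   `"U1"`, `"U2"`, `"tonotopy"`, `"TR>=TD"`, `"TR>=D"`); empty when all
#'   conditions hold.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "two_tone_params"))
  v <- character(0)
  if (!(p$a - p$b < p$theta)) v <- c(v, "U1")
  if (!(p$c >= p$theta))      v <- c(v, "U2")
  if (!(p$c >= p$d))          v <- c(v, "tonotopy")
  if (!(p$TR >= p$TD))        v <- c(v, "TR>=TD")
  if (!(p$TR >= p$D))         v <- c(v, "TR>=D")
  v
}

#' Timing regimes of a parameter set
#'
#' @param p a [model_params()] object.
#' @return Named logical vector with the derivable regime flags:
#'   `no_overlap` (`TD + D < TR`, tones and their delayed inhibition do not
#'   reach into the next tone), `long_delay` (`D > TD`), `bio` (`D <= TD`,
#'   the physiologically plausible short-delay case), and `strong_input`
#'   (`c - b >= theta`, tone input beats maximal inhibition).
#' @export
param_regime <- function(p) {
  stopifnot(inherits(p, "two_tone_params"))
  c(no_overlap = p$TD + p$D < p$TR,
    long_delay = p$D > p$TD,
    bio = p$D <= p$TD,
    strong_input = p$c - p$b >= p$theta)
}

#' Map a tone-frequency difference to the cross-frequency input strength
#'
#' Primary-cortex responses at a tone's best-frequency site decay nonlinearly
#' with the frequency separation of the other tone; this is captured by
#' `d = c * (1 - df^(1/m))`.
#'
#' @param c on-frequency input strength (>= 0).
#' @param df unitless frequency difference in \[0, 1\].
#' @param m positive integer exponent.
#' @return `c * (1 - df^(1/m))`, monotonically decreasing in `df`, in
#'   \[0, `c`\].
#' @examples
#' df_to_d(5.5, 0.5, 6)  # ~0.6
#' @export
df_to_d <- function(c, df, m = 6L) {
  if (any(df < 0 | df > 1)) stop("`df` must lie in [0, 1]")
  if (any(c < 0)) stop("`c` must be non-negative")
  if (m < 1) stop("`m` must be >= 1")
  c * (1 - df^(1 / m))
}

#' Convert a frequency difference to semitones
#'
#' Uses `12 * log2(1 + df)`, the musical-interval convention (one octave for
#' a doubling of frequency, `df = 1`).
#'
#' @param df unitless frequency difference (>= 0).
#' @return Semitone value.
#' @export
df_to_semitones <- function(df) {
  if (any(df < 0)) stop("`df` must be non-negative")
  12 * log2(1 + df)
}

#' Shipped parameter presets
#'
#' Named parameter sets used throughout the package examples and tests.
#' Fields a preset leaves open (for instance `PR` and `df` for `"fig3"`, or
#' the input strengths for `"fig9B"`/`"fig9C"`) must be supplied through
#' `...`, which also overrides any preset value.
#'
#' @param name one of `"fig3"`, `"fig9B"`, `"fig9C"`, `"fig10"`, `"fig11B"`.
#' @param ... overrides and completions passed on to [model_params()].
#' @return A [model_params()] object.
#' @examples
#' preset_params("fig10", PR = 10, df = 0.9)
#' @export
preset_params <- function(name = c("fig3", "fig9B", "fig9C", "fig10",
                                   "fig11B"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    fig3   = list(a = 2, b = 2.8, c = 5.5, D = 0.015, theta = 0.5,
                  TD = 0.022, tau_i = 0.25, tau = 0.025, m = 6L, slope = 30),
    fig9B  = list(tau_i = 0.4, theta = 0.5, TD = 0.03, D = 0.03, PR = 17,
                  a = 0.6, b = 2),
    fig9C  = list(tau_i = 0.4, theta = 0.5, TD = 0.005, D = 0.015, PR = 5,
                  a = 0.4, b = 3),
    fig10  = list(tau_i = 0.2, theta = 0.5, TD = 0.03, D = 0.01, c = 5,
                  a = 1, b = 2, m = 6L),
    fig11B = list(a = 2, b = 2.8, c = 5.5, D = 0.015, theta = 0.5,
                  TD = 0.022, tau_i = 0.25, tau = 0.01, m = 6L, slope = 30))
  dots <- list(...)
  base[names(dots)] <- dots
  do.call(model_params, base)
}

#' Alternating two-tone schedule
#'
#' Generates the labelled active tone intervals of an ABAB sequence up to a
#' requested horizon: A tones occupy `[2k*TR, 2k*TR + TD]` and B tones
#' `[(2k+1)*TR, (2k+1)*TR + TD]` (closed intervals).
#'
#' @param TR tone repetition time (s); or a [model_params()] object, in which
#'   case `TD` is taken from it.
#' @param TD tone duration (s).
#' @param horizon end time (s); intervals starting at or before the horizon
#'   are included.
#' @return A `data.frame` with columns `k` (pair index, 0-based), `label`
#'   (`"A"`/`"B"`), `onset`, `offset`, plus attributes `TR`, `TD`.
#' @export
tone_schedule <- function(TR, TD = NULL, horizon) {
  if (inherits(TR, "two_tone_params")) {
    TD <- TR$TD
    TR <- TR$TR
  }
  stopifnot(TR > 0, TD > 0, horizon >= 0)
  kmax <- max(0L, floor(horizon / (2 * TR)))
  k <- 0:kmax
  onset <- c(rbind(2 * k * TR, (2 * k + 1) * TR))
  sched <- data.frame(k = rep(k, each = 2L),
                      label = rep(c("A", "B"), length(k)),
                      onset = onset, offset = onset + TD)
  sched <- sched[sched$onset <= horizon, , drop = FALSE]
  attr(sched, "TR") <- TR
  attr(sched, "TD") <- TD
  sched
}
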