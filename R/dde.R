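#' Integrate the delayed two-population model
#'
#' Solves the four-dimensional DDE system (two firing-rate units, two
#' inhibitory synaptic variables, synaptic terms delayed by `D`) with a
#' classical fourth-order Runge-Kutta method of steps.  The step `h` divides
#' the forcing period `2TR` exactly, so consecutive periods are grid-aligned;
#' delayed synaptic values are read from the stored dense solution by cubic
#' Lagrange interpolation (fourth-order, matching the integrator).  The step
#' is capped at `min(tau/10, TD/20, D/4, TR/200)`.
#'
#' @param p a [model_params()] object (`D > 0` required).
#' @param gain `"sigmoid"` or `"heaviside"`, or a [gain_spec()] whose `kind`
#'   is used (threshold and slope always come from `p`).
#' @param input `"smooth"` or `"square"` forcing (see [smooth_input()],
#'   [square_input()]).
#' @param history constant history on `[-D, 0]`, a numeric 4-vector
#'   `(u_A, u_B, s_A, s_B)`; alternatively a `4 x k` matrix of grid values
#'   ending at `t = 0` (used internally for continuation).
#' @param horizon integration time in seconds (at least one period `2TR`),
#'   rounded up to a whole number of steps.
#' @param h optional step override; must satisfy `h <= D/4` (it is still
#'   snapped to an exact divisor of `2TR`).
#' @return An object of class `"two_tone_traj"`: list with `time` (uniform
#'   grid from 0), matrix `y` (4 rows: `u_A`, `u_B`, `s_A`, `s_B`), `h`,
#'   `steps_per_period`, and the call metadata (`params`, `gain`, `input`).
#' @examples
#' p <- preset_params("fig3", PR = 6, df = 0.02)
#' tr <- integrate_dde(p, horizon = 2 * 2 * p$TR)
#' range(tr$y["u_A", ])
#' @export
integrate_dde <- function(p, gain = c("sigmoid", "heaviside"),
                          input = c("smooth", "square"),
                          history = c(1, 0, 1, 0), horizon = NULL, h = NULL) {
  stopifnot(inherits(p, "two_tone_params"))
  if (inherits(gain, "gain_spec")) gain <- gain$kind
  gain <- match.arg(gain)
  input <- match.arg(input)
  if (p$D <= 0) stop("the method-of-steps integrator requires D > 0")
  if (is.null(horizon)) horizon <- 40 * 2 * p$TR
  if (horizon < 2 * p$TR) stop("horizon must cover at least one period 2TR")

  h <- dde_step(p, h)
  N <- round(2 * p$TR / h)          # steps per period (even)
  nsteps <- ceiling(horizon / h - 1e-9)

  nh <- ceiling(p$D / h) + 4L       # history columns needed for the stencil
  if (is.matrix(history)) {
    if (nrow(history) != 4L || ncol(history) < nh)
      stop("history matrix must be 4 x k with k >= ", nh)
    hist <- history[, (ncol(history) - nh + 1L):ncol(history), drop = FALSE]
  } else {
    stopifnot(length(history) == 4L)
    hist <- matrix(rep(as.numeric(history), nh), nrow = 4L)
  }

  y <- dde_rk4_cpp(unlist(p[c("a", "b", "c", "d", "tau", "tau_i", "D",
                              "theta", "TD", "TR", "slope")]),
                   gain = if (gain == "heaviside") 0L else 1L,
                   input = if (input == "square") 0L else 1L,
                   hist = hist, h = h, nsteps = as.integer(nsteps))
  rownames(y) <- c("u_A", "u_B", "s_A", "s_B")
  structure(list(time = seq(0, by = h, length.out = nsteps + 1L), y = y,
                 h = h, steps_per_period = N, params = p, gain = gain,
                 input = input, history = hist),
            class = "two_tone_traj")
}

# step that divides 2TR exactly, respects the stability/resolution caps,
# and has an even number of steps per period (so TR is also on the grid)
dde_step <- function(p, h = NULL) {
  hmax <- min(p$tau / 10, p$TD / 20, p$D / 4, p$TR / 200)
  if (!is.null(h)) {
    if (h > p$D / 4) stop("step too large: need h <= D/4")
    hmax <- min(hmax, h)
  }
  N <- ceiling(2 * p$TR / hmax)
  N <- N + (N %% 2L)
  2 * p$TR / N
}

#' @export
print.two_tone_traj <- function(x, ...) {
  cat(sprintf(
    "Two-tone trajectory: %d samples, t in [0, %.4g] s, h = %.3g s\n",
    length(x$time), max(x$time), x$h))
  cat(sprintf("  gain = %s, input = %s, PR = %g Hz\n", x$gain, x$input,
              x$params$PR))
  invisible(x)
}

#' @export
as.data.frame.two_tone_traj <- function(x, ...) {
  data.frame(t = x$time, u_A = x$y["u_A", ], u_B = x$y["u_B", ],
             s_A = x$y["s_A", ], s_B = x$y["s_B", ])
}

#' Count upward threshold crossings of the unit activities
#'
#' A unit "responds" when its activity rises through the threshold `theta`.
#' To reject grazing contacts, a crossing is counted only when the activity
#' climbs from below `theta - eps` to above `theta + eps`; the crossing
#' instant is located by interpolation on the dense grid.
#'
#' @param traj a [integrate_dde()] trajectory.
#' @param theta threshold (defaults to the trajectory's parameter value).
#' @param window numeric length-2 `[t0, t1)` analysis window; defaults to the
#'   final `2TR` window of the trajectory.
#' @param eps crossing hysteresis (default `1e-3`).
#' @return An object of class `"crossing_report"`: list with
#'   `crossings_A`, `crossings_B` (crossing times), counts `n_A`, `n_B`,
#'   `n = n_A + n_B`, the `window`, and the `residual` (sup-norm difference
#'   between the last two periods when the trajectory covers them, else
#'   `NA`).
#' @export
detect_crossings <- function(traj, theta = NULL, window = NULL, eps = 1e-3) {
  stopifnot(inherits(traj, "two_tone_traj"))
  p <- traj$params
  if (is.null(theta)) theta <- p$theta
  Tend <- max(traj$time)
  if (is.null(window)) window <- c(Tend - 2 * p$TR, Tend)
  if (window[1] < min(traj$time) - 1e-12 || window[2] > Tend + 1e-12)
    stop("window outside trajectory support")
  sel <- traj$time >= window[1] - 1e-12 & traj$time <= window[2] + 1e-12
  tt <- traj$time[sel]
  crossings <- function(u) {
    armed <- u[1] < theta - eps
    out <- numeric(0)
    last_below <- if (u[1] < theta) 1L else NA_integer_
    for (i in seq_along(u)[-1]) {
      if (u[i] < theta) last_below <- i
      if (!armed && u[i] < theta - eps) armed <- TRUE
      if (armed && u[i] > theta + eps) {
        j <- last_below
        tc <- if (!is.na(j) && j < length(u)) {
          tt[j] + (theta - u[j]) / (u[j + 1] - u[j]) * (tt[j + 1] - tt[j])
        } else tt[i]
        out <- c(out, tc)
        armed <- FALSE
      }
    }
    out[out >= window[1] & out < window[2]]
  }
  cA <- crossings(traj$y["u_A", sel])
  cB <- crossings(traj$y["u_B", sel])
  res <- periodicity_residual(traj)
  structure(list(window = window, crossings_A = cA, crossings_B = cB,
                 n_A = length(cA), n_B = length(cB),
                 n = length(cA) + length(cB), residual = res),
            class = "crossing_report")
}

#' @export
print.crossing_report <- function(x, ...) {
  cat(sprintf("Crossings over [%.4g, %.4g): n_A = %d, n_B = %d, n = %d\n",
              x$window[1], x$window[2], x$n_A, x$n_B, x$n))
  cat(sprintf("  periodicity residual = %s, percept = %s\n",
              format(x$residual), classify_percept(x)))
  invisible(x)
}

# sup-norm difference between the last two 2TR windows (grid-aligned)
periodicity_residual <- function(traj) {
  N <- traj$steps_per_period
  n <- ncol(traj$y)
  if (n < 2 * N + 1) return(NA_real_)
  a <- traj$y[, (n - N + 1):n, drop = FALSE]
  b <- traj$y[, (n - 2 * N + 1):(n - N), drop = FALSE]
  max(abs(a - b))
}

#' Converged periodic state of the smooth or steep model
#'
#' Integrates from the constant history `(1, 0, 1, 0)` for `periods` forcing
#' periods, then keeps extending in blocks until the sup-norm difference
#' between the last two `2TR` windows falls below `tol` (or `max_periods` is
#' reached, in which case the result is flagged non-periodic but still
#' returned).
#'
#' @inheritParams integrate_dde
#' @param periods initial number of `2TR` periods (default 40).
#' @param block extension block size in periods (default 20).
#' @param max_periods give up after this many periods (default 200).
#' @param tol periodicity tolerance (default `1e-5`).
#' @return List with `traj` (final-window trajectory, one period plus its
#'   history), `report` (the [detect_crossings()] of the final window),
#'   `converged` (logical), `periods_run`, and `residual`.
#' @examples
#' \donttest{
#' ps <- periodic_state(preset_params("fig3", PR = 6, df = 0.02))
#' ps$report$n  # 4: integration
#' }
#' @export
periodic_state <- function(p, gain = "sigmoid", input = "smooth",
                           history = c(1, 0, 1, 0), periods = 40L,
                           block = 20L, max_periods = 200L, tol = 1e-5,
                           h = NULL) {
  traj <- integrate_dde(p, gain = gain, input = input, history = history,
                        horizon = periods * 2 * p$TR, h = h)
  run <- periods
  res <- periodicity_residual(traj)
  while (is.na(res) || res >= tol) {
    if (run >= max_periods) break
    nxt <- integrate_dde(p, gain = gain, input = input, history = traj$y,
                         horizon = block * 2 * p$TR, h = traj$h)
    # stitch: drop the duplicated t = 0 column of the continuation
    y <- cbind(traj$y, nxt$y[, -1, drop = FALSE])
    traj$y <- y
    traj$time <- seq(0, by = traj$h, length.out = ncol(y))
    run <- run + block
    res <- periodicity_residual(traj)
  }
  report <- detect_crossings(traj)
  # trim the returned trajectory to the final period (plus delay history)
  N <- traj$steps_per_period
  keep <- max(1L, ncol(traj$y) - N - ceiling(p$D / traj$h) - 4L):ncol(traj$y)
  win <- traj
  win$y <- traj$y[, keep, drop = FALSE]
  win$time <- traj$time[keep]
  list(traj = win, report = report, converged = is.finite(res) && res < tol,
       periods_run = run, residual = res)
}

#' Percept label from a crossing count
#'
#' Maps the total number of upward threshold crossings per `2TR` period to
#' the perceptual interpretation of the streaming paradigm: 4 crossings
#' (both units respond to both tones) is integration `INT`; 3 (one unit
#' responds to both tones, the other to one) is bistability `BIS`; 2 (each
#' unit responds to one tone) is segregation `SEG`; 0 (activities pinned
#' above threshold) is the saturated state `SAT`; anything else is `OTHER`.
#'
#' @param report a [detect_crossings()] report, or a bare crossing count.
#' @return One of `"INT"`, `"BIS"`, `"SEG"`, `"SAT"`, `"OTHER"`.
#' @export
classify_percept <- function(report) {
  n <- if (inherits(report, "crossing_report")) report$n else report
  stopifnot(is.numeric(n), length(n) == 1L)
  switch(as.character(n), "4" = "INT", "3" = "BIS", "2" = "SEG",
         "0" = "SAT", "OTHER")
}

#' Z2-conjugate of a trajectory
#'
#' The model is equivariant under swapping the A and B labels combined with
#' a half-period time shift `TR` (the two tones play symmetric roles).  This
#' returns the conjugated trajectory `kappa(v(t + TR))`, dropping the final
#' `TR` of support; with the grid chosen by [integrate_dde()] the shift is an
#' exact whole number of steps.
#'
#' @param traj a [integrate_dde()] trajectory.
#' @return A `"two_tone_traj"` with swapped channels and shifted time.
#' @export
conjugate_traj <- function(traj) {
  stopifnot(inherits(traj, "two_tone_traj"))
  half <- traj$steps_per_period / 2
  stopifnot(half == round(half))
  n <- ncol(traj$y)
  if (n <= half + 1) stop("trajectory shorter than TR")
  y <- traj$y[c("u_B", "u_A", "s_B", "s_A"), (half + 1):n, drop = FALSE]
  rownames(y) <- c("u_A", "u_B", "s_A", "s_B")
  out <- traj
  out$y <- y
  out$time <- traj$time[1:(n - half)]
  out
}

#' Export a trajectory to CSV
#'
#' Writes columns `t, u_A, u_B, s_A, s_B`.
#'
#' @param traj a [integrate_dde()] trajectory.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_traj_csv <- function(traj, file) {
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' Export a crossing report to JSON
#'
#' @param report a [detect_crossings()] report.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_crossings_json <- function(report, file) {
  stopifnot(inherits(report, "crossing_report"))
  jsonlite::write_json(
    list(n_A = report$n_A, n_B = report$n_B, n = report$n,
         crossings_A = report$crossings_A, crossings_B = report$crossings_B,
         residual = report$residual, percept = classify_percept(report)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
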