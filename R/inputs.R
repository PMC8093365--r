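#' Gain specification
#'
#' The model's activation nonlinearity: a Heaviside step `H(x) = 1` iff
#' `x >= theta`, or its logistic approximation
#' `S(x - theta) = 1 / (1 + exp(-slope * (x - theta)))` centred on the same
#' threshold so the two share their half-activation point.
#'
#' @param kind `"heaviside"` or `"sigmoid"`.
#' @param theta activity threshold in (0, 1).
#' @param slope logistic steepness (sigmoid only).
#' @return An object of class `"gain_spec"` with a `$fun` element, the
#'   vectorized gain function.
#' @examples
#' g <- gain_spec("sigmoid", theta = 0.5, slope = 30)
#' g$fun(c(0.4, 0.5, 0.6))
#' @export
gain_spec <- function(kind = c("heaviside", "sigmoid"), theta = 0.5,
                      slope = 30) {
  kind <- match.arg(kind)
  stopifnot(theta > 0, theta < 1, slope > 0)
  fun <- if (kind == "heaviside") {
    function(x) as.numeric(x >= theta)
  } else {
    function(x) 1 / (1 + exp(-slope * (x - theta)))
  }
  structure(list(kind = kind, theta = theta, slope = slope, fun = fun),
            class = "gain_spec")
}

#' Square-wave tone inputs
#'
#' The idealized primary-cortex drive: during an A tone the A unit receives
#' `c` and the B unit `d`; during a B tone the roles swap; between tones both
#' inputs are zero.  Both channels are `2TR`-periodic.  Active intervals are
#' closed on both ends.
#'
#' @param p a [model_params()] object.
#' @param t time(s) in seconds (vectorized, `t >= 0`).
#' @return A list with numeric vectors `i_A` and `i_B`.
#' @export
square_input <- function(p, t) {
  stopifnot(inherits(p, "two_tone_params"))
  tm <- t %% (2 * p$TR)
  tm[2 * p$TR - tm < 1e-12] <- 0  # guard the floating-point wrap
  onA <- tm <= p$TD
  onB <- tm >= p$TR & tm <= p$TR + p$TD
  list(i_A = p$c * onA + p$d * onB, i_B = p$d * onA + p$c * onB)
}

#' Smooth tone inputs
#'
#' Continuous analogue of [square_input()] built from the logistic function
#' `S(x) = 1 / (1 + exp(-slope * x))`:
#' `I_A(t) = c * p(t) p(TD - t) + d * q(t) q(TD - t)` with
#' `p(t) = S(sin(pi * PR * t))`, `q(t) = S(-sin(pi * PR * t))`, and `I_B`
#' with `c` and `d` swapped.  The product structure yields `2TR`-periodic
#' pulses of width `TD` with smooth ramps; as `slope` grows the inputs
#' converge pointwise to the square wave away from the switch points.
#'
#' @inheritParams square_input
#' @return A list with numeric vectors `i_A` and `i_B`.
#' @export
smooth_input <- function(p, t) {
  stopifnot(inherits(p, "two_tone_params"))
  S <- function(x) 1 / (1 + exp(-p$slope * x))
  sn <- sin(pi * p$PR * t)
  snd <- sin(pi * p$PR * (p$TD - t))
  pA <- S(sn) * S(snd)
  pB <- S(-sn) * S(-snd)
  list(i_A = p$c * pA + p$d * pB, i_B = p$d * pA + p$c * pB)
}
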