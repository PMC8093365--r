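#' Synaptic decay landmarks
#'
#' For a `2TR`-periodic state with tones of duration `TD` and delay `D`, the
#' delayed synaptic variables sampled at the interval landmarks are powers of
#' the slow decay: `N^- = exp(-(TR-TD-D)/tau_i)`, `N^+ = exp(-(TR-D)/tau_i)`,
#' `M^- = exp(-(2TR-TD-D)/tau_i)`, `M^+ = exp(-(2TR-D)/tau_i)`, together with
#' the short-delay landmarks `R^- = exp(-(TR-2D)/tau_i)` and
#' `R^+ = exp(-(TR-D)/tau_i)`.  When `TD + D < TR` they satisfy
#' `N^- >= N^+ >= M^- >= M^+` and `R^- >= R^+`.
#'
#' @param p a [model_params()] object.
#' @return Named numeric vector `N_minus, N_plus, M_minus, M_plus, R_minus,
#'   R_plus`.  A warning is issued if an exponent argument is negative
#'   (outside the no-overlap regime the interpretation changes).
#' @export
landmarks <- function(p) {
  stopifnot(inherits(p, "two_tone_params"))
  ex <- c(N_minus = p$TR - p$TD - p$D, N_plus = p$TR - p$D,
          M_minus = 2 * p$TR - p$TD - p$D, M_plus = 2 * p$TR - p$D,
          R_minus = p$TR - 2 * p$D, R_plus = p$TR - p$D)
  if (any(ex[1:4] < 0))
    warning("negative decay-time argument: parameters outside the ",
            "no-overlap regime (TD + D < TR)")
  exp(-ex / p$tau_i)
}

#' Condition quantities for the 2TR-periodic state tables
#'
#' The inequalities deciding which periodic state exists compare the
#' threshold `theta` with affine combinations of the couplings and the decay
#' [landmarks()].  This evaluates all of them: `C1 = d`,
#' `C2^± = a - b M^± + d`, `C3^± = c - b N^±`, `C4^± = c - b M^±`,
#' `C5^± = a - b N^± + d`, `C6^± = a - b N^± + c`, `C7^± = d - b N^±`,
#' `C8^± = d - b M^±`, `C9 = a - b M^+`, `C10 = a - b N^+`, plus the
#' short-delay quantities `P = a - b + d`, `R6_minus = a - b R^- + d` and
#' `R7_minus = d - b R^-`.
#'
#' @param p a [model_params()] object.
#' @return Named numeric vector of all condition quantities.
#' @export
condition_values <- function(p) {
  L <- landmarks(p)
  Nm <- L[["N_minus"]]; Np <- L[["N_plus"]]
  Mm <- L[["M_minus"]]; Mp <- L[["M_plus"]]; Rm <- L[["R_minus"]]
  a <- p$a; b <- p$b; cc <- p$c; d <- p$d
  c(C1 = d,
    C2_minus = a - b * Mm + d,  C2_plus = a - b * Mp + d,
    C3_minus = cc - b * Nm,     C3_plus = cc - b * Np,
    C4_minus = cc - b * Mm,     C4_plus = cc - b * Mp,
    C5_minus = a - b * Nm + d,  C5_plus = a - b * Np + d,
    C6_minus = a - b * Nm + cc, C6_plus = a - b * Np + cc,
    C7_minus = d - b * Nm,      C7_plus = d - b * Np,
    C8_minus = d - b * Mm,      C8_plus = d - b * Mp,
    C9 = a - b * Mp,            C10 = a - b * Np,
    P = a - b + d,
    R6_minus = a - b * Rm + d,  R7_minus = d - b * Rm,
    # short-delay variant of C2+: when D <= TD the decaying inhibition seen
    # by the cross unit is cut off at the lead-window end, where the trace
    # value is exp(-(2TR - TD)/tau_i) rather than the long-delay landmark M+
    C2_plus_sd = a - b * exp(-(2 * p$TR - p$TD) / p$tau_i) + d)
}

#' Per-interval input evaluators
#'
#' During an A tone interval the on-frequency unit sees `f(s) = c - b s` and
#' the cross unit `g(s) = d - b s`; during a B tone the roles of `c` and `d`
#' swap.
#'
#' @param p a [model_params()] object.
#' @param tone `"A"` or `"B"`.
#' @return List of two functions `f(s)` and `g(s)`.
#' @export
interval_inputs <- function(p, tone = c("A", "B")) {
  tone <- match.arg(tone)
  own <- if (tone == "A") p$c else p$d
  cross <- if (tone == "A") p$d else p$c
  list(f = function(s) own - p$b * s, g = function(s) cross - p$b * s)
}

#' Admissible per-interval matrix forms
#'
#' A state's behaviour in one active tone interval is summarized by a binary
#' `2 x 2` matrix `[x_A y_A; x_B y_B]`: `x` says whether the unit turns ON at
#' the interval start, `y` whether it is ON by the interval end.  Of the 16
#' binary matrices only those with `x_A <= y_A`, `x_B <= y_B`, and
#' `x_A = x_B = 0 => y_A = y_B = 0` can be realized; this enumerates them by
#' brute force.
#'
#' @return List of exactly six binary `2 x 2` matrices (rows `A`, `B`).
#' @export
admissible_main_matrices <- function() {
  out <- list()
  for (bits in 0:15) {
    v <- as.integer(intToBits(bits))[1:4]  # xA, yA, xB, yB
    xA <- v[1]; yA <- v[2]; xB <- v[3]; yB <- v[4]
    ok <- xA <= yA && xB <= yB && !(xA == 0 && xB == 0 && (yA + yB) > 0)
    if (ok) {
      m <- matrix(c(xA, xB, yA, yB), 2, 2,
                  dimnames = list(c("A", "B"), c("x", "y")))
      out[[length(out) + 1L]] <- m
    }
  }
  out
}

#' Classify the interval dynamics from the synaptic samples
#'
#' Given the delayed synaptic values at the interval start
#' (`s_under_A`, `s_under_B`) and end (`s_bar_A`, `s_bar_B`), decides which
#' of the per-interval dynamics holds: the six turn-on-at-start/off patterns
#' `M1`-`M6` or the five interior-turn-on (connecting) patterns `C1`-`C5`.
#' The condition sets are mutually exclusive; satisfying more than one is an
#' internal contradiction and raises an error.
#'
#' @param p a [model_params()] object.
#' @param s_under_A,s_bar_A,s_under_B,s_bar_B delayed synaptic samples in
#'   \[0, 1\] with `s_under >= s_bar` (synapses decay across the interval).
#' @param tone `"A"` or `"B"` (selects the role of `c` and `d`).
#' @return A label among `"M1"`..`"M6"`, `"C1"`..`"C5"`, or `"none"`.
#' @export
interval_condition <- function(p, s_under_A, s_bar_A, s_under_B, s_bar_B,
                               tone = "A") {
  stopifnot(s_under_A >= s_bar_A - 1e-12, s_under_B >= s_bar_B - 1e-12)
  io <- interval_inputs(p, tone)
  f <- io$f; g <- io$g
  th <- p$theta; a <- p$a
  sat <- c(
    M1 = f(s_under_B) >= th && g(s_under_A) >= th,
    M2 = g(s_under_A) < th && f(s_under_B) >= th && a + g(s_under_A) >= th,
    M3 = f(s_under_B) < th && g(s_under_A) >= th && a + f(s_under_B) >= th,
    M4 = f(s_under_B) >= th && a + g(s_bar_A) < th,
    M5 = g(s_under_A) >= th && a + f(s_bar_B) < th,
    M6 = g(s_bar_A) < th && f(s_bar_B) < th,
    C1 = f(s_under_B) >= th && a + g(s_under_A) < th && a + g(s_bar_A) >= th,
    C2 = g(s_under_A) >= th && a + f(s_under_B) < th && a + f(s_bar_B) >= th,
    C3 = g(s_under_A) < th && g(s_bar_A) >= th && a + f(s_bar_B) < th,
    C4 = f(s_under_B) < th && f(s_bar_B) >= th && a + g(s_bar_A) < th,
    # C5 covers both interior-turn-on orders; the follower's condition uses
    # the other unit's synaptic sample (a + g(s_bar_A), a + f(s_bar_B)),
    # which makes C3/C4/C5 mutually exclusive
    C5 = (f(s_under_B) < th && f(s_bar_B) >= th && a + g(s_bar_A) >= th) ||
         (g(s_under_A) < th && g(s_bar_A) >= th && a + f(s_bar_B) >= th))
  hit <- names(sat)[sat]
  if (length(hit) > 1L)
    stop("interval conditions not mutually exclusive at this point: ",
         paste(hit, collapse = ", "))
  if (length(hit) == 0L) "none" else hit
}

# matrix forms of the nine long-delay (D > TD) periodic states, as 2x4
# binary matrices [V1 | V2] (rows A, B; columns x1 y1 x2 y2)
short_main_matrices <- function() {
  mk <- function(r1, r2) {
    m <- rbind(A = as.integer(strsplit(r1, "")[[1]]),
               B = as.integer(strsplit(r2, "")[[1]]))
    colnames(m) <- c("x1", "y1", "x2", "y2")
    m
  }
  list(S   = mk("1100", "0000"), SB  = mk("1100", "1100"),
       SD  = mk("1100", "0100"), AP  = mk("1100", "0011"),
       AS  = mk("1111", "0011"), ASD = mk("1101", "0011"),
       I   = mk("1111", "0000"), ID  = mk("1101", "0111"),
       IB  = mk("1111", "1111"))
}

#' Long-delay (D > TD) periodic state classification
#'
#' Evaluates the existence conditions of the nine `2TR`-periodic states that
#' turn on only at interval starts and are silent between tones, valid in
#' the regime `D > TD`, `TD + D < TR`.  The per-interval conditions (middle
#' set) are combined with the extra silence conditions involving `C9`/`C10`
#' that guarantee the units stay OFF in the gaps.  Coexistence is real in
#' this regime (the in-phase state `I` can coexist with `SB` or `SD`), so
#' all satisfied states are returned.
#'
#' @param p a [model_params()] object in the stated regime.
#' @param tol numeric tolerance on condition boundaries; a condition within
#'   `tol` of `theta` marks the point as degenerate (attribute
#'   `"degenerate"` on the result).
#' @return Character vector of satisfied state names (possibly length 0,
#'   named subset of `S, SB, SD, AP, AS, ASD, I, ID, IB`).
#' @export
short_main_state <- function(p, tol = 1e-12) {
  reg <- param_regime(p)
  if (!reg[["long_delay"]] || !reg[["no_overlap"]])
    stop("short_main_state requires D > TD and TD + D < TR")
  cv <- as.list(condition_values(p))
  th <- p$theta
  ge <- function(x) x >= th
  lt <- function(x) x < th
  sat <- c(
    S   = lt(cv$C1) && lt(cv$C2_plus) && lt(cv$C3_plus),
    SB  = lt(cv$C3_plus) && ge(cv$C8_minus) && lt(cv$C9),
    SD  = ge(cv$C4_minus) && ge(cv$C2_minus) && lt(cv$C3_plus) &&
          lt(cv$C8_minus) && lt(cv$C9),
    AP  = lt(cv$C2_plus) && ge(cv$C3_minus),
    AS  = ge(cv$C3_minus) && lt(cv$C5_plus) && ge(cv$C8_minus) &&
          lt(cv$C10),
    ASD = ge(cv$C2_minus) && ge(cv$C3_minus) && lt(cv$C5_plus) &&
          lt(cv$C8_minus) && lt(cv$C10),
    I   = ge(cv$C1) && lt(cv$C6_plus),
    ID  = ge(cv$C3_minus) && ge(cv$C5_minus) && lt(cv$C7_minus) &&
          lt(cv$C10),
    IB  = ge(cv$C7_minus) && lt(cv$C10))
  out <- names(sat)[sat]
  degen <- min(abs(unlist(cv) - th)) < tol
  attr(out, "degenerate") <- degen
  out
}

#' Short-delay (biological, D <= TD) periodic state classification
#'
#' In the physiologically plausible regime `D <= TD`, `TD + D < TR` with
#' strong tone input (`c - b >= theta`), each unit is ON throughout its own
#' tone, and the state is decided by what the cross unit does in the lead
#' window `[alpha, alpha + D]` of the other tone.  When the residual cross
#' drive `P = a - b + d >= theta` the state is `I` (both units on at every
#' tone onset, `C7^- >= theta`) or `ID` (cross unit delayed by the cascade).
#' Otherwise the seven states of the weak-cross-input case apply
#' (`IS`, `IDS`, `AS`, `ASD`, `AP`, `APcAS`, `AScI`), whose conditions are
#' mutually exclusive.
#'
#' @inheritParams short_main_state
#' @return A single state name (character), or `"none"`.
#' @export
bio_state <- function(p, tol = 1e-12) {
  reg <- param_regime(p)
  if (!reg[["bio"]] || !reg[["no_overlap"]])
    stop("bio_state requires D <= TD and TD + D < TR")
  if (!reg[["strong_input"]])
    stop("bio_state requires the strong-input condition c - b >= theta")
  cv <- as.list(condition_values(p))
  th <- p$theta
  if (cv$P >= th) {
    out <- if (cv$C7_minus >= th) "I" else "ID"
  } else {
    sat <- c(
      IS    = cv$R7_minus >= th,
      IDS   = cv$R7_minus < th && cv$R6_minus >= th,
      AS    = cv$C5_plus < th && cv$C8_minus >= th,
      ASD   = cv$C5_plus < th && cv$C8_minus < th && cv$C2_minus >= th,
      AP    = cv$C2_plus_sd < th,
      APcAS = cv$C2_minus < th && cv$C2_plus_sd >= th,
      AScI  = cv$R6_minus < th && cv$C5_plus >= th)
    hit <- names(sat)[sat]
    if (length(hit) > 1L)
      stop("state conditions not mutually exclusive at this point: ",
           paste(hit, collapse = ", "))
    out <- if (length(hit)) hit else "none"
  }
  attr(out, "degenerate") <- min(abs(unlist(cv) - th)) < tol
  out
}

#' Percept associated with an analytic state
#'
#' Integration: both units respond to every tone (`I`, `ID`, `IS`, `IDS`,
#' `AScI`, `IB`).  Segregation: no unit responds to both tones (`AP`, `S`,
#' `SB`, `SD`).  Bistability: one unit responds to both tones, the other to
#' every second tone (`AS`, `ASD`, `APcAS`).
#'
#' @param name a state name from [short_main_state()] or [bio_state()].
#' @return `"INT"`, `"SEG"`, or `"BIS"`.
#' @export
percept_of_state <- function(name) {
  map <- c(I = "INT", ID = "INT", IS = "INT", IDS = "INT", AScI = "INT",
           IB = "INT",
           AP = "SEG", S = "SEG", SB = "SEG", SD = "SEG",
           AS = "BIS", ASD = "BIS", APcAS = "BIS")
  if (length(name) != 1L || !name %in% names(map))
    stop("unknown state name: ", paste(name, collapse = ", "))
  unname(map[[name]])
}

#' Z2 conjugate of a state or matrix form
#'
#' The model's symmetry (swap A and B, shift time by `TR`) maps each periodic
#' state to a conjugate that exists under the same conditions.  On the
#' `2 x 4` matrix form the conjugation swaps the A-row of the first interval
#' block with the B-row of the second and vice versa.  The in-phase,
#' anti-phase and delayed in-phase states (`I`, `AP`, `ID`, and also `IB`,
#' `IS`, `IDS`) are symmetric (self-conjugate); the others come in conjugate
#' pairs.
#'
#' @param x a state name, or a binary `2 x 4` matrix form.
#' @return For a matrix: the conjugated matrix.  For a name: a list with
#'   `name` and logical `symmetric` (`TRUE` when the state equals its
#'   conjugate).
#' @export
conjugate_state <- function(x) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == 2L, ncol(x) == 4L)
    out <- x
    out[1, 1:2] <- x[2, 3:4]  # new A in I1 = old B in I2
    out[2, 1:2] <- x[1, 3:4]
    out[1, 3:4] <- x[2, 1:2]
    out[2, 3:4] <- x[1, 1:2]
    return(out)
  }
  mats <- short_main_matrices()
  if (x %in% names(mats)) {
    sym <- identical(unname(mats[[x]]), unname(conjugate_state(mats[[x]])))
    return(list(name = x, symmetric = sym))
  }
  sym_bio <- c("I", "ID", "AP", "IS", "IDS", "AScI")
  if (x %in% c(sym_bio, "AS", "ASD", "APcAS", "AScI"))
    return(list(name = x, symmetric = x %in% sym_bio))
  stop("unknown state or matrix form")
}

# admissibility of a 2x4 candidate [V1 | V2] for a periodic state that is
# silent between tones: both blocks per-interval admissible plus the
# cross-interval consistency conditions of the periodic closure
admissible_2x4 <- function(V) {
  ok22 <- function(m)
    m[1, 1] <= m[1, 2] && m[2, 1] <= m[2, 2] &&
      !(m[1, 1] == 0 && m[2, 1] == 0 && (m[1, 2] + m[2, 2]) > 0)
  xA1 <- V[1, 1]; yA1 <- V[1, 2]; xA2 <- V[1, 3]; yA2 <- V[1, 4]
  xB1 <- V[2, 1]; yB1 <- V[2, 2]; xB2 <- V[2, 3]; yB2 <- V[2, 4]
  if (!ok22(V[, 1:2]) || !ok22(V[, 3:4])) return(FALSE)
  # a periodic state silent in every interval is impossible under the
  # responsiveness condition c >= theta: the synapses would decay until the
  # tone input alone exceeds threshold
  if (all(V == 0)) return(FALSE)
  # 1
  if (yA1 == 1 && yB2 == 1 && xA1 != xB2) return(FALSE)
  if (yA2 == 1 && yB1 == 1 && xA2 != xB1) return(FALSE)
  # 2
  if (yB1 == yB2 && !(xA1 >= xA2)) return(FALSE)
  if (yA1 == yA2 && !(xB2 >= xB1)) return(FALSE)
  # 3: an entry below the minimum over all entries is impossible, so the
  # condition reads: every entry r of V satisfies x <= r
  if (yA2 == 1 && xB1 > min(V)) return(FALSE)
  if (yB1 == 1 && xA2 > min(V)) return(FALSE)
  # 4
  if (yA2 == yB2 && yA1 == yB1 && !(xA1 >= xB1 && xB2 >= xA2)) return(FALSE)
  TRUE
}

#' Enumerate the admissible 2x4 matrix forms
#'
#' Brute-forces all binary `2 x 4` matrices whose two `2 x 2` blocks are
#' individually admissible and which satisfy the cross-interval closure
#' conditions of a periodic state.  The result is exactly the nine named
#' states plus the conjugates of the asymmetric ones.
#'
#' @return List of binary `2 x 4` matrices.
#' @export
enumerate_2x4_forms <- function() {
  out <- list()
  for (bits in 0:255) {
    v <- as.integer(intToBits(bits))[1:8]
    V <- matrix(v, 2, 4, byrow = TRUE,
                dimnames = list(c("A", "B"), c("x1", "y1", "x2", "y2")))
    if (admissible_2x4(V)) out[[length(out) + 1L]] <- V
  }
  out
}

#' Fission and coherence boundary curves
#'
#' The van Noorden diagram's boundary curves as functions of the
#' presentation rate, for the short-delay regime.  Two variants are
#' provided.  `"printed"` evaluates the closed forms
#' `df_coh(PR) = [(a - b N^+ + c - theta)/c]^m` and
#' `df_fiss(PR) = [(a - b M^+ + c - theta)/c]^m` with
#' `N^+ = exp(-(TR-D)/tau_i)` and, in this formula only,
#' `M^+ = exp(-(2TR-TD)/tau_i)`.  `"derived"` solves the state-transition
#' conditions of the short-delay tables for the cross input `d` and inverts
#' the `df` mapping: the coherence line (`APcAS`/`AP` transition) from
#' `a - b exp(-(2TR-TD)/tau_i) + d = theta` (the short-delay form of
#' `C2^+`), and the fission line (`AScI`/`IDS` transition) from
#' `R6^-(d) = theta` with `R^- = exp(-(TR-2D)/tau_i)`.  The derived
#' coherence line coincides with the printed `df_fiss` formula; the printed
#' `df_coh` formula instead equals the `C5^+ = theta` (`AS`/`AScI`)
#' transition, so the two variants bracket the bistable band differently.
#' Values of `d` outside `[0, c]` make the boundary undefined at that rate
#' (`NA`).
#'
#' @param p a [model_params()] object (all fields except `TR`/`PR` are
#'   used).
#' @param PR presentation rates in Hz (vectorized).
#' @param variant `"printed"` or `"derived"`.
#' @return A `data.frame` with columns `PR`, `df_coh`, `df_fiss`, values
#'   clipped to \[0, 1\] (or `NA` where undefined).
#' @export
boundaries <- function(p, PR = seq(1, 40, length.out = 96),
                       variant = c("derived", "printed")) {
  stopifnot(inherits(p, "two_tone_params"))
  variant <- match.arg(variant)
  TR <- 1 / PR
  if (variant == "printed") {
    Np <- exp(-(TR - p$D) / p$tau_i)
    Mp <- exp(-(2 * TR - p$TD) / p$tau_i)
    coh <- ((p$a - p$b * Np + p$c - p$theta) / p$c)^p$m
    fis <- ((p$a - p$b * Mp + p$c - p$theta) / p$c)^p$m
    coh[p$a - p$b * Np + p$c - p$theta < 0] <- NA
    fis[p$a - p$b * Mp + p$c - p$theta < 0] <- NA
  } else {
    Mp_sd <- exp(-(2 * TR - p$TD) / p$tau_i)
    Rm <- exp(-(TR - 2 * p$D) / p$tau_i)
    d_coh <- p$theta - p$a + p$b * Mp_sd
    d_fis <- p$theta - p$a + p$b * Rm
    inv <- function(d) {
      df <- (1 - d / p$c)^p$m
      df[d < 0 | d > p$c] <- NA
      df
    }
    coh <- inv(d_coh)
    fis <- inv(d_fis)
  }
  data.frame(PR = PR, df_coh = pmin(pmax(coh, 0), 1),
             df_fiss = pmin(pmax(fis, 0), 1))
}

#' Scan for coexisting long-delay periodic states
#'
#' Draws random parameter sets in the long-delay regime (`D > TD`,
#' `TD + D < TR`, satisfying the structural conditions) and collects every
#' pair of states whose existence conditions hold simultaneously.  The
#' analysis predicts that only `(I, SB)` and `(I, SD)` can coexist.
#'
#' @param n_draws number of random draws.
#' @param sampler optional function `function(i)` returning a
#'   [model_params()] object; the default samples uniformly over a broad
#'   valid box.
#' @return A `data.frame` with columns `state1`, `state2`, `count` listing
#'   the observed coexisting pairs.
#' @export
coexistence_scan <- function(n_draws = 1e4, sampler = NULL) {
  if (is.null(sampler)) sampler <- random_long_delay_params
  pairs <- list()
  for (i in seq_len(n_draws)) {
    p <- sampler(i)
    st <- short_main_state(p)
    if (length(st) >= 2L) {
      key <- paste(sort(st), collapse = "+")
      pairs[[key]] <- (pairs[[key]] %||% 0L) + 1L
    }
  }
  if (!length(pairs))
    return(data.frame(state1 = character(0), state2 = character(0),
                      count = integer(0)))
  nm <- strsplit(names(pairs), "+", fixed = TRUE)
  data.frame(state1 = vapply(nm, `[`, "", 1L),
             state2 = vapply(nm, `[`, "", 2L),
             count = unlist(pairs, use.names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random valid parameter draw, long-delay regime
#'
#' Uniform draw over a broad box with `D > TD` and `TD + D < TR`, satisfying
#' the structural conditions (`U1`, `U2`, tonotopy).  Used by property tests
#' and [coexistence_scan()].
#'
#' @param i ignored (sampler-interface placeholder).
#' @return A [model_params()] object.
#' @export
random_long_delay_params <- function(i = NULL) {
  repeat {
    theta <- 0.5
    a <- stats::runif(1, 0, 1.5)
    b <- stats::runif(1, max(0, a - theta) + 0.05, 4)
    c <- stats::runif(1, theta, 6)
    d <- stats::runif(1, 0, c)
    TR <- stats::runif(1, 0.05, 1)
    TD <- stats::runif(1, 0.002, 0.4 * TR)
    D <- stats::runif(1, TD * 1.01, max(TD * 1.02, 0.95 * (TR - TD)))
    tau_i <- stats::runif(1, 0.05, 0.6)
    p <- model_params(a = a, b = b, c = c, d = d, tau_i = tau_i, D = D,
                      theta = theta, TD = TD, TR = TR)
    if (length(validate_params(p)) == 0L && p$TD + p$D < p$TR && p$D > p$TD)
      return(p)
  }
}

#' Random valid parameter draw, short-delay regime
#'
#' Uniform draw with `D <= TD`, `TD + D < TR` and the strong-input condition
#' `c - b >= theta`, satisfying the structural conditions.
#'
#' @param i ignored.
#' @return A [model_params()] object.
#' @export
random_bio_params <- function(i = NULL) {
  repeat {
    theta <- 0.5
    a <- stats::runif(1, 0, 1.5)
    b <- stats::runif(1, max(0, a - theta) + 0.05, 3)
    c <- stats::runif(1, b + theta, b + theta + 5)
    d <- stats::runif(1, 0, c)
    TR <- stats::runif(1, 0.05, 1)
    TD <- stats::runif(1, 0.002, 0.45 * TR)
    D <- stats::runif(1, 0.2 * TD, TD)
    tau_i <- stats::runif(1, 0.05, 0.6)
    p <- model_params(a = a, b = b, c = c, d = d, tau_i = tau_i, D = D,
                      theta = theta, TD = TD, TR = TR)
    if (length(validate_params(p)) == 0L && p$TD + p$D < p$TR &&
          p$D <= p$TD && p$c - p$b >= theta)
      return(p)
  }
}

#' Full analytic classification of one parameter point
#'
#' Convenience wrapper returning the regime flags, landmarks, condition
#' values, state name(s), conjugacy and percept for one parameter set,
#' dispatching on the delay regime.
#'
#' @param p a [model_params()] object.
#' @return A list with `regime`, `landmarks`, `conditions`, `state`,
#'   `symmetric`, `percept`.
#' @export
classify_point <- function(p) {
  reg <- param_regime(p)
  st <- if (reg[["bio"]]) bio_state(p) else short_main_state(p)
  percept <- tryCatch(
    paste(vapply(st, percept_of_state, ""), collapse = "/"),
    error = function(e) NA_character_)
  sym <- tryCatch(vapply(st, function(s) conjugate_state(s)$symmetric,
                         logical(1)),
                  error = function(e) NA)
  list(regime = reg, landmarks = landmarks(p),
       conditions = condition_values(p),
       state = as.character(st), symmetric = sym, percept = percept)
}
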