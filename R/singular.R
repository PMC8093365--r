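# Event-driven simulation of the slow-fast singular limit (tau -> 0,
# Heaviside gain): unit activities are binary and resolved through the fast
# subsystem's equilibria; synaptic variables are piecewise exponentials and
# every event time has a closed form.

#' Admissible fast-subsystem equilibria and hysteresis selection
#'
#' On the fast time scale the two units relax to a binary configuration
#' whose admissibility depends on the instantaneous inputs and the delayed
#' synaptic values: `(0,0)` needs `i_A < b s~_B + theta` and
#' `i_B < b s~_A + theta`; `(1,0)` needs `i_A >= b s~_B + theta` and
#' `a + i_B < b s~_A + theta`; `(0,1)` the mirror; `(1,1)` needs
#' `a + i_A >= b s~_B + theta` and `a + i_B >= b s~_A + theta`.  When both
#' `(0,0)` and `(1,1)` are admissible the realized configuration follows the
#' current one (hysteresis): a configuration persists until its own
#' admissibility fails.
#'
#' @param p a [model_params()] object (only `a`, `b`, `theta` used).
#' @param s_tilde_A,s_tilde_B delayed synaptic values in \[0, 1\].
#' @param current current binary configuration, length-2 0/1 vector.
#' @param input instantaneous inputs `c(i_A, i_B)`.
#' @return List with `admissible` (list of 0/1 pairs) and `selected` (the
#'   configuration realized from `current`).
#' @export
resolve_fast_state <- function(p, s_tilde_A, s_tilde_B,
                               current = c(0, 0), input) {
  stopifnot(s_tilde_A >= 0, s_tilde_A <= 1, s_tilde_B >= 0, s_tilde_B <= 1,
            length(input) == 2L)
  a <- p$a; b <- p$b; th <- p$theta
  iA <- input[1]; iB <- input[2]
  adm <- list()
  if (iA < b * s_tilde_B + th && iB < b * s_tilde_A + th)
    adm <- c(adm, list(c(0, 0)))
  if (iA >= b * s_tilde_B + th && a + iB < b * s_tilde_A + th)
    adm <- c(adm, list(c(1, 0)))
  if (a + iA < b * s_tilde_B + th && iB >= b * s_tilde_A + th)
    adm <- c(adm, list(c(0, 1)))
  if (a + iA >= b * s_tilde_B + th && a + iB >= b * s_tilde_A + th)
    adm <- c(adm, list(c(1, 1)))
  if (!length(adm))
    stop("no admissible fast equilibrium: inconsistent parameters ",
         "(implementation invariant violated)")
  sel <- current
  if (!any(vapply(adm, identical, logical(1), y = as.numeric(current)))) {
    # iterate the instantaneous switching rules from the current state
    for (k in 1:8) {
      drvA <- a * sel[2] - b * s_tilde_B + iA
      drvB <- a * sel[1] - b * s_tilde_A + iB
      nxt <- c(if (sel[1] == 1 && drvA < th) 0 else if
                 (sel[1] == 0 && drvA >= th) 1 else sel[1],
               if (sel[2] == 1 && drvB < th) 0 else if
                 (sel[2] == 0 && drvB >= th) 1 else sel[2])
      if (identical(nxt, sel)) break
      sel <- nxt
    }
  }
  list(admissible = adm, selected = as.numeric(sel))
}

#' Cascade order of a joint turn-on
#'
#' When `(1,1)` is the target from `(0,0)` during a tone, the two units may
#' turn on simultaneously or one may lead: if the cross unit's direct drive
#' is below threshold but excitation from the leading unit lifts it over,
#' the follower turns on after the leader's activity reaches
#' `u* = (theta - cross_drive) / a`, an infinitesimal lag of order `tau`
#' (see [delta_lag()]).
#'
#' @param p a [model_params()] object.
#' @param s_tilde_A,s_tilde_B delayed synaptic values.
#' @param tone `"A"` or `"B"` (whose tone interval this is).
#' @return List with `order` (`"simultaneous"`, `"A_then_B"`, `"B_then_A"`,
#'   or `"none"` when no joint turn-on happens) and `u_star` (`NA` when not
#'   applicable; a value > 1 means the cascade cannot complete).
#' @export
cascade_order <- function(p, s_tilde_A, s_tilde_B, tone = c("A", "B")) {
  tone <- match.arg(tone)
  a <- p$a; b <- p$b; th <- p$theta
  iA <- if (tone == "A") p$c else p$d
  iB <- if (tone == "A") p$d else p$c
  dA <- iA - b * s_tilde_B   # direct drive to A
  dB <- iB - b * s_tilde_A
  if (dA >= th && dB >= th)
    return(list(order = "simultaneous", u_star = 0))
  if (dA >= th && dB < th && a > 0) {
    u_star <- (th - dB) / a   # u* > 1 means the follower is never lifted
    return(list(order = if (u_star <= 1) "A_then_B" else "none",
                u_star = u_star))
  }
  if (dB >= th && dA < th && a > 0) {
    u_star <- (th - dA) / a
    return(list(order = if (u_star <= 1) "B_then_A" else "none",
                u_star = u_star))
  }
  list(order = "none", u_star = NA_real_)
}

#' Cascade lag of the delayed follower
#'
#' The follower turns on once the leader's activity, relaxing as
#' `1 - exp(-t/tau)`, reaches `u*`; the lag is
#' `delta = tau * log(1/(1 - u*))`.
#'
#' @param tau unit time constant (s).
#' @param u_star leader activity level in \[0, 1).
#' @return The lag `delta` in seconds (0 when `u_star = 0`).
#' @export
delta_lag <- function(tau, u_star) {
  if (any(u_star >= 1)) stop("u_star >= 1: no cascade (follower never lifts)")
  if (any(u_star < 0)) stop("u_star must be in [0, 1)")
  tau * log(1 / (1 - u_star))
}

# --- synaptic segment bookkeeping -----------------------------------------
# a segment is (t0, v0, mode): mode 1 = held at 1 (unit ON), 2 = exponential
# decay from v0, 3 = constant v0 (history)
seg_new <- function(t0, v0, mode) c(t0 = t0, v0 = v0, mode = mode)

seg_value <- function(segs, tq, tau_i) {
  # left-closed with tolerance: a query at a segment's start (in particular
  # a delayed landmark t_sw + D querying t_sw) reads the post-jump segment
  i <- findInterval(tq + 1e-9, segs[, "t0"])
  if (i < 1L) i <- 1L
  s <- segs[i, ]
  switch(s[["mode"]],
         1,
         s[["v0"]] * exp(-(tq - s[["t0"]]) / tau_i),
         s[["v0"]])
}

#' Simulate the singular limit of the two-tone network
#'
#' Advances the hybrid system by events: tone onsets/offsets, delayed
#' synaptic landmarks (`D` after every unit switch), and interior threshold
#' crossings of decaying delayed inhibition, whose times are closed-form
#' (`t = t0 + D + tau_i * log(b s0 / (drive - theta))`).  While a unit is ON
#' its synapse is held at 1; on turn-off it decays exponentially.  At every
#' event the instantaneous binary configuration is re-resolved to a fixed
#' point; turn-ons enabled by the other unit's excitation within the same
#' instant are recorded with `rank = 1` (the infinitesimally delayed cascade
#' of the singular limit), direct turn-ons with `rank = 0`.
#'
#' @param p a [model_params()] object (Heaviside regime; `TD + D < TR`
#'   recommended: outside that regime the returned log carries a
#'   `validity = FALSE` flag).
#' @param periods number of `2TR` forcing periods to simulate.
#' @param history initial constant state `(u_A, u_B, s_A, s_B)` on
#'   `[-D, 0]`.
#' @param max_events safety bound on the number of processed events.
#' @return An object of class `"singular_log"`: list with `events` (a
#'   `data.frame` `t, kind, unit, rank`), the synaptic segment tables, the
#'   parameters, `periods`, and `validity`.
#' @examples
#' p <- preset_params("fig10", PR = 10, df = 0.9)
#' log <- run_singular(p, periods = 8)
#' table(log$events$kind)
#' @export
run_singular <- function(p, periods = 12L, history = c(1, 0, 1, 0),
                         max_events = 1e6) {
  stopifnot(inherits(p, "two_tone_params"))
  horizon <- periods * 2 * p$TR
  tol <- 1e-9
  tau_i <- p$tau_i

  sched <- tone_schedule(p, horizon = horizon + p$TR)
  # half-open convention for event processing: input active on [onset, offset)
  input_at <- function(t) {
    tm <- t %% (2 * p$TR)
    if (2 * p$TR - tm < tol) tm <- 0   # guard the floating-point wrap
    onA <- tm >= -tol & tm < p$TD - tol
    onB <- tm >= p$TR - tol & tm < p$TR + p$TD - tol
    c(A = if (onA) p$c else if (onB) p$d else 0,
      B = if (onA) p$d else if (onB) p$c else 0)
  }

  u <- as.numeric(history[1:2])
  segs <- list(A = matrix(seg_new(-Inf, history[3], 3), 1, 3,
                          dimnames = list(NULL, c("t0", "v0", "mode"))),
               B = matrix(seg_new(-Inf, history[4], 3), 1, 3,
                          dimnames = list(NULL, c("t0", "v0", "mode"))))
  sval <- function(unit, tq) seg_value(segs[[unit]], tq, tau_i)

  ev_t <- numeric(0); ev_kind <- character(0)
  ev_unit <- character(0); ev_rank <- integer(0)
  log_event <- function(t, kind, unit, rank = 0L) {
    ev_t[length(ev_t) + 1L] <<- t
    ev_kind[length(ev_kind) + 1L] <<- kind
    ev_unit[length(ev_unit) + 1L] <<- unit
    ev_rank[length(ev_rank) + 1L] <<- rank
  }

  # structural times: tone boundaries plus dynamically added landmarks
  struct <- sort(unique(c(0, sched$onset, sched$offset)))
  struct <- struct[struct <= horizon + tol]
  landmarks_q <- numeric(0)

  switch_unit <- function(unit, t, on, rank) {
    other <- if (unit == "A") "B" else "A"
    if (on) {
      segs[[unit]] <<- rbind(segs[[unit]], seg_new(t, 1, 1))
      log_event(t, "unit_on", unit, rank)
    } else {
      v <- sval(unit, t)
      segs[[unit]] <<- rbind(segs[[unit]], seg_new(t, v, 2))
      log_event(t, "unit_off", unit, rank)
    }
    landmarks_q <<- c(landmarks_q, t + p$D)
  }

  drives <- function(t, uu) {
    i <- input_at(t)
    c(A = p$a * uu[2] - p$b * sval("B", t - p$D) + i[["A"]],
      B = p$a * uu[1] - p$b * sval("A", t - p$D) + i[["B"]])
  }

  resolve_at <- function(t) {
    # H(x) = 1 iff x >= theta; the tiny slack keeps closed-form crossing
    # times (where the drive equals theta up to rounding) on the ON side
    thr <- p$theta - 1e-9
    switched <- c(A = 0L, B = 0L)
    for (pass in 0:9) {
      drv <- drives(t, u)
      changed <- FALSE
      # turn-offs first
      for (k in 1:2) {
        un <- c("A", "B")[k]
        if (u[k] == 1 && drv[[un]] < thr) {
          if (switched[[un]] >= 2L) stop("chattering detected at t = ", t)
          u[k] <<- 0
          switched[[un]] <- switched[[un]] + 1L
          switch_unit(un, t, on = FALSE, rank = 0L)
          changed <- TRUE
        }
      }
      drv <- drives(t, u)
      for (k in 1:2) {
        un <- c("A", "B")[k]
        if (u[k] == 0 && drv[[un]] >= thr) {
          if (switched[[un]] >= 2L) stop("chattering detected at t = ", t)
          u[k] <<- 1
          switched[[un]] <- switched[[un]] + 1L
          # rank 1 when enabled by a unit that turned ON this same instant
          rank <- if (pass > 0L && any(switched > 0L & u == 1 &
                                         c("A", "B") != un)) 1L else 0L
          switch_unit(un, t, on = TRUE, rank = rank)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  # next interior turn-on (closed form) strictly inside (t, t_next]
  interior_crossing <- function(t, t_next) {
    best <- Inf
    tm <- (t + t_next) / 2
    i <- input_at(tm)
    for (k in 1:2) {
      if (u[k] == 1) next
      un <- c("A", "B")[k]
      other <- if (un == "A") "B" else "A"
      base <- p$a * u[c(2, 1)[k]] + i[[un]]
      if (base - p$theta <= 0) next
      oseg <- segs[[other]]
      j <- findInterval(tm - p$D, oseg[, "t0"]); if (j < 1L) j <- 1L
      sg <- oseg[j, ]
      if (sg[["mode"]] != 2) next
      val <- p$b * sg[["v0"]] / (base - p$theta)
      if (val <= 1) next
      tc <- sg[["t0"]] + p$D + tau_i * log(val)
      if (tc > t + tol && tc <= t_next + tol) best <- min(best, tc)
    }
    best
  }

  t <- 0
  resolve_at(0)
  n_ev <- 0L
  repeat {
    pend <- c(struct[struct > t + tol], landmarks_q[landmarks_q > t + tol])
    if (!length(pend)) break
    t_struct <- min(pend)
    if (t_struct > horizon + tol) break
    tc <- interior_crossing(t, t_struct)
    t_next <- min(tc, t_struct)
    # log tone/landmark kinds at structural instants
    if (t_next >= t_struct - tol) {
      if (any(abs(sched$onset - t_next) < tol))
        log_event(t_next, "tone_on",
                  sched$label[which.min(abs(sched$onset - t_next))], 0L)
      if (any(abs(sched$offset - t_next) < tol))
        log_event(t_next, "tone_off",
                  sched$label[which.min(abs(sched$offset - t_next))], 0L)
      if (any(abs(landmarks_q - t_next) < tol))
        log_event(t_next, "delayed_jump", "none", 0L)
    }
    t <- t_next
    resolve_at(t)
    n_ev <- n_ev + 1L
    if (n_ev > max_events)
      stop("event accumulation beyond the Zeno guard (", max_events,
           " events)")
  }

  validity <- p$TD + p$D < p$TR
  structure(list(events = data.frame(t = ev_t, kind = ev_kind,
                                     unit = ev_unit, rank = ev_rank),
                 segments = segs, params = p, periods = periods,
                 validity = validity),
            class = "singular_log")
}

#' @export
print.singular_log <- function(x, ...) {
  cat(sprintf("Singular-limit event log: %d events over %d periods\n",
              nrow(x$events), x$periods))
  print(table(x$events$kind))
  invisible(x)
}

#' Per-interval ON/OFF raster of a singular-limit log
#'
#' Summarizes each active tone interval of each period by a per-unit code:
#' `0` the unit stays OFF; `1` it turns ON at the interval onset (direct);
#' `2` it turns ON at the onset after the infinitesimal cascade lag
#' (`rank = 1`); `3` it turns ON strictly inside the interval (a connecting
#' state).  Also flags gaps in which both units are simultaneously ON
#' (`long`), and counts turn-ons per period.
#'
#' @param log a [run_singular()] log.
#' @return An object of class `"singular_raster"`: list with `codes` (array
#'   `periods x 2 intervals x 2 units`), `long` (logical per period),
#'   `n_A`, `n_B`, `n` (turn-on counts of the last period), `stable`
#'   (logical: last two periods identical), and `codes_last` (2 x 2 matrix,
#'   rows units A and B, columns intervals `I1`, `I2`, for the last period).
#' @export
extract_raster <- function(log) {
  stopifnot(inherits(log, "singular_log"))
  p <- log$params
  ev <- log$events[log$events$kind %in% c("unit_on", "unit_off"), ]
  per <- log$periods
  tol <- 1e-9
  codes <- array(0L, dim = c(per, 2L, 2L),
                 dimnames = list(NULL, c("I1", "I2"), c("A", "B")))
  for (k in seq_len(per) - 1L) {
    for (j in 1:2) {
      alpha <- (2 * k + (j - 1)) * p$TR
      beta <- alpha + p$TD
      for (un in c("A", "B")) {
        on <- ev[ev$kind == "unit_on" & ev$unit == un &
                   ev$t > alpha - tol & ev$t <= beta + tol, ]
        code <- 0L
        if (nrow(on)) {
          first <- on[which.min(on$t), ]
          code <- if (abs(first$t - alpha) < tol) {
            if (first$rank == 0L) 1L else 2L
          } else 3L
        } else if (k == 0L && j == 1L && un == "A" &&
                     infer_state_at(ev, "A", alpha + tol, init = 1) == 1) {
          code <- 1L  # still ON from the history at t = 0 (transient only)
        }
        codes[k + 1L, j, un] <- code
      }
    }
  }
  # LONG flag: both units ON somewhere strictly between tones
  long <- logical(per)
  init <- c(A = 1, B = 0)
  for (k in seq_len(per) - 1L) {
    gaps <- rbind(c(2 * k * p$TR + p$TD, (2 * k + 1) * p$TR),
                  c((2 * k + 1) * p$TR + p$TD, (2 * k + 2) * p$TR))
    for (g in 1:2) {
      tq <- seq(gaps[g, 1] + tol, gaps[g, 2] - tol, length.out = 7)
      both <- vapply(tq, function(s)
        infer_state_at(ev, "A", s, init[["A"]]) == 1 &&
          infer_state_at(ev, "B", s, init[["B"]]) == 1, logical(1))
      if (any(both)) long[k + 1L] <- TRUE
    }
  }
  last <- per
  win <- c((last - 1) * 2 * p$TR, last * 2 * p$TR)
  ons <- ev[ev$kind == "unit_on" & ev$t >= win[1] - tol & ev$t < win[2] - tol, ]
  n_A <- sum(ons$unit == "A"); n_B <- sum(ons$unit == "B")
  stable <- per >= 2 && identical(codes[per, , ], codes[per - 1, , ])
  codes_last <- t(codes[last, , ])  # rows units, cols intervals
  structure(list(codes = codes, long = long, n_A = n_A, n_B = n_B,
                 n = n_A + n_B, stable = stable, codes_last = codes_last),
            class = "singular_raster")
}

# unit state (0/1) at time tq from the switch events
infer_state_at <- function(ev, unit, tq, init) {
  e <- ev[ev$unit == unit & ev$t <= tq, ]
  if (!nrow(e)) return(init)
  if (e$kind[nrow(e)] == "unit_on") 1 else 0
}

#' Predicted per-interval codes of an analytic state
#'
#' Returns the raster code matrix (rows units `A`, `B`; columns intervals
#' `I1`, `I2`; codes as in [extract_raster()]) that the analytic
#' classification predicts for a named state, in either delay regime.
#'
#' @param name a state name from [short_main_state()] or [bio_state()].
#' @param regime `"long_delay"` (`D > TD`) or `"bio"` (`D <= TD`).
#' @return Integer `2 x 2` matrix of codes.
#' @export
state_codes <- function(name, regime = c("bio", "long_delay")) {
  regime <- match.arg(regime)
  code22 <- function(a1, b1, a2, b2)
    matrix(c(a1, b1, a2, b2), 2, 2,
           dimnames = list(c("A", "B"), c("I1", "I2")))
  tab <- if (regime == "bio") {
    list(I     = code22(1L, 1L, 1L, 1L),
         ID    = code22(1L, 2L, 2L, 1L),
         IS    = code22(1L, 1L, 1L, 1L),
         IDS   = code22(1L, 2L, 2L, 1L),
         AS    = code22(1L, 1L, 0L, 1L),
         ASD   = code22(1L, 2L, 0L, 1L),
         AP    = code22(1L, 0L, 0L, 1L),
         APcAS = code22(1L, 3L, 0L, 1L),
         AScI  = code22(1L, 3L, 3L, 1L))
  } else {
    mats <- short_main_matrices()
    lapply(mats, function(m) {
      cd <- function(x, y) if (x == 1L) 1L else if (y == 1L) 2L else 0L
      code22(cd(m[1, 1], m[1, 2]), cd(m[2, 1], m[2, 2]),
             cd(m[1, 3], m[1, 4]), cd(m[2, 3], m[2, 4]))
    })
  }
  if (!name %in% names(tab)) stop("unknown state name: ", name)
  tab[[name]]
}

#' Does a simulated raster match an analytic state?
#'
#' Compares the stabilized per-interval codes of a singular-limit run with
#' the codes predicted for a state name, accepting the Z2-conjugate raster
#' as a match (asymmetric states exist in conjugate pairs and the initial
#' history picks one member).
#'
#' @param raster an [extract_raster()] result.
#' @param name analytic state name.
#' @param regime `"bio"` or `"long_delay"`.
#' @return Logical.
#' @export
raster_matches_state <- function(raster, name, regime = c("bio",
                                                          "long_delay")) {
  regime <- match.arg(regime)
  pred <- state_codes(name, regime)
  obs <- raster$codes_last
  conj <- pred
  conj["A", "I1"] <- pred["B", "I2"]; conj["B", "I1"] <- pred["A", "I2"]
  conj["A", "I2"] <- pred["B", "I1"]; conj["B", "I2"] <- pred["A", "I1"]
  identical(unname(obs), unname(pred)) || identical(unname(obs),
                                                    unname(conj))
}

#' Export a singular event log as JSON lines
#'
#' One event per line: `{"t": ..., "kind": ..., "unit": ..., "rank": ...}`.
#'
#' @param log a [run_singular()] log.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_events_jsonl <- function(log, file) {
  stopifnot(inherits(log, "singular_log"))
  con <- file(file, "w")
  on.exit(close(con))
  ev <- log$events
  for (i in seq_len(nrow(ev)))
    writeLines(jsonlite::toJSON(list(t = ev$t[i], kind = ev$kind[i],
                                     unit = ev$unit[i], rank = ev$rank[i]),
                                auto_unbox = TRUE, digits = NA), con)
  invisible(file)
}
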