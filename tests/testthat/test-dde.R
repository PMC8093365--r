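test_that("uncoupled units follow the closed-form relaxation", {
  # a = b = 0 decouples the units; with Heaviside gain and square input the
  # A unit relaxes towards 1 during its tone, u(t) = 1 - exp(-t/tau), while
  # the B unit (d = 0, started at 1) decays as exp(-t/tau)
  p <- model_params(a = 0, b = 0, c = 5.5, d = 0, tau = 0.025, tau_i = 0.25,
                    D = 0.015, theta = 0.5, TD = 0.1, TR = 0.25)
  tr <- integrate_dde(p, gain = "heaviside", input = "square",
                      history = c(0, 1, 0, 1), horizon = 2 * 2 * p$TR)
  sel <- tr$time <= p$TD
  expect_equal(tr$y["u_A", sel], 1 - exp(-tr$time[sel] / p$tau),
               tolerance = 1e-6)
  expect_equal(tr$y["u_B", sel], exp(-tr$time[sel] / p$tau),
               tolerance = 1e-6)
})

test_that("synapse of a silent unit decays with the slow time constant", {
  p <- model_params(a = 0, b = 0, c = 5.5, d = 0, tau = 0.025, tau_i = 0.25,
                    D = 0.015, theta = 0.5, TD = 0.1, TR = 0.25)
  tr <- integrate_dde(p, gain = "heaviside", input = "square",
                      history = c(0, 1, 0, 1), horizon = 2 * 2 * p$TR)
  # u_B = exp(-t/tau) falls below theta at t* = tau log(1/theta); after that
  # s_B' = -s_B / tau_i
  tstar <- p$tau * log(1 / p$theta)
  sel <- tr$time > tstar + 5 * tr$h & tr$time <= p$TD
  i0 <- which(sel)[1]
  ref <- tr$y["s_B", i0] * exp(-(tr$time[sel] - tr$time[i0]) / p$tau_i)
  expect_equal(tr$y["s_B", sel], ref, tolerance = 1e-5)
})

test_that("all channels remain inside [0 - tol, 1 + tol]", {
  pts <- list(fig3(6, 0.02), fig3(20, 0.95),
              preset_params("fig11B", PR = 38, df = 0.02),
              preset_params("fig10", PR = 10, df = 0.5, tau = 0.005))
  for (p in pts) {
    tr <- integrate_dde(p, horizon = 10 * 2 * p$TR)
    expect_gt(min(tr$y), -1e-6)
    expect_lt(max(tr$y), 1 + 1e-6)
  }
})

test_that("fig3 integration point converges to a 2TR-periodic orbit", {
  ps <- periodic_state(fig3(6, 0.02))
  expect_true(ps$converged)
  expect_lt(ps$residual, 1e-5)
  expect_equal(ps$periods_run, 40)
  expect_identical(ps$report$n, 4L)
  expect_identical(ps$report$n_A, 2L)
  expect_identical(ps$report$n_B, 2L)
})

test_that("crossing detection counts upward threshold passages only", {
  p <- fig3(6, 0.5)
  n <- 600
  tt <- seq(0, 2 * p$TR, length.out = n + 1)
  # constant channel below threshold: no crossings
  r0 <- detect_crossings(synthetic_traj(tt, rep(0, n + 1), p = p),
                         window = c(0, 2 * p$TR))
  expect_identical(r0$n, 0L)
  # theta/2 + theta * sin(2 pi t / TR): one upward crossing per TR
  u <- p$theta / 2 + p$theta * sin(2 * pi * tt / p$TR)
  r2 <- detect_crossings(synthetic_traj(tt, u, p = p),
                         window = c(0, 2 * p$TR))
  expect_identical(r2$n_A, 2L)
  expect_identical(r2$n_B, 0L)
  # crossing instants at the analytic solution of sin = 1/2
  expect_equal(r2$crossings_A,
               c(asin(0.5) / (2 * pi) * p$TR, (2 * pi + asin(0.5)) /
                   (2 * pi) * p$TR), tolerance = 1e-3)
  # grazing contact within the hysteresis band is rejected
  ug <- (p$theta - 5e-4) + 8e-4 * sin(2 * pi * tt / p$TR)
  rg <- detect_crossings(synthetic_traj(tt, ug, p = p),
                         window = c(0, 2 * p$TR))
  expect_identical(rg$n, 0L)
})

test_that("percept labels are a pure lookup on the crossing count", {
  expect_identical(classify_percept(4), "INT")
  expect_identical(classify_percept(3), "BIS")
  expect_identical(classify_percept(2), "SEG")
  expect_identical(classify_percept(0), "SAT")
  expect_identical(classify_percept(1), "OTHER")
  expect_identical(classify_percept(5), "OTHER")
})

test_that("refining the step contracts at fourth order on the attractor", {
  p <- fig3(6, 0.02)
  ps1 <- periodic_state(p)
  h <- ps1$traj$h
  w1 <- final_window(ps1)
  ps2 <- periodic_state(p, h = h / 2)
  w2 <- final_window(ps2)
  ps4 <- periodic_state(p, h = h / 4)
  w4 <- final_window(ps4)
  ps8 <- periodic_state(p, h = h / 8)
  w8 <- final_window(ps8)
  ps16 <- periodic_state(p, h = h / 16)
  w16 <- final_window(ps16)
  d12 <- max(abs(w1 - w2[, seq(1, ncol(w2), 2)]))
  d24 <- max(abs(w2 - w4[, seq(1, ncol(w4), 2)]))
  d48 <- max(abs(w4 - w8[, seq(1, ncol(w8), 2)]))
  d816 <- max(abs(w8 - w16[, seq(1, ncol(w16), 2)]))
  expect_gt(d12 / d24, 8)        # ~2^4 contraction per halving
  expect_gt(d24 / d48, 8)
  expect_lt(d816, 1e-5)          # refined steps agree to the stated figure
  # crossing counts are step-independent
  expect_identical(ps1$report$n, ps16$report$n)
})

test_that("the integrator matches an adaptive reference DDE solver", {
  library(deSolve)
  p <- fig3(6, 0.3)
  S <- function(x) 1 / (1 + exp(-p$slope * (x - p$theta)))
  rhs <- function(t, y, parms) {
    sdel <- if (t < p$D) c(1, 0) else deSolve::lagvalue(t - p$D, c(3, 4))
    inp <- smooth_input(p, t)
    list(c((-y[1] + S(p$a * y[2] - p$b * sdel[2] + inp$i_A)) / p$tau,
           (-y[2] + S(p$a * y[1] - p$b * sdel[1] + inp$i_B)) / p$tau,
           S(y[1]) * (1 - y[3]) / p$tau - y[3] / p$tau_i,
           S(y[2]) * (1 - y[4]) / p$tau - y[4] / p$tau_i))
  }
  tr <- integrate_dde(p, horizon = 6 * 2 * p$TR)
  ref <- deSolve::dede(y = c(1, 0, 1, 0), times = tr$time, func = rhs,
                       parms = NULL, atol = 1e-8, rtol = 1e-8)
  expect_lt(max(abs(t(ref[, 2:5]) - tr$y)), 0.02)
  # both routes count the same responses over the final period
  reftraj <- synthetic_traj(tr$time, ref[, 2], ref[, 3], p = p)
  expect_identical(detect_crossings(reftraj)$n, detect_crossings(tr)$n)
})

test_that("conjugated trajectories solve the system (Z2 equivariance)", {
  for (dfv in c(0.02, 0.3, 0.95))
    expect_lt(z2_residual(fig3(6, dfv)), 1e-4)
})

test_that("steep-gain trajectories reproduce the singular-limit raster", {
  for (dfv in c(0.05, 0.5, 0.9)) {
    p <- preset_params("fig10", PR = 10, df = dfv, tau = 0.005, slope = 300)
    ps <- periodic_state(p)
    rs <- respond_sets(p, ps$traj)
    ras <- extract_raster(run_singular(p, periods = 12))
    expect_true(rasters_agree(rs, ras))
  }
})

test_that("trajectory and crossing exports round-trip", {
  p <- fig3(6, 0.02)
  tr <- integrate_dde(p, horizon = 2 * 2 * p$TR)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_traj_csv(tr, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$u_A, unname(tr$y["u_A", ]), tolerance = 1e-12)
  js <- withr::local_tempfile(fileext = ".json")
  rep <- detect_crossings(tr)
  write_crossings_json(rep, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(parsed$n, rep$n)
  expect_identical(parsed$percept, classify_percept(rep))
})

test_that("malformed integration requests raise errors", {
  p <- fig3(6, 0.5)
  expect_error(integrate_dde(p, horizon = p$TR), "horizon")
  expect_error(integrate_dde(p, horizon = 4 * p$TR, h = p$D), "step")
  pd0 <- model_params(a = 2, b = 2.8, c = 5.5, d = 1, D = 0, PR = 6)
  expect_error(integrate_dde(pd0, horizon = 4 * pd0$TR), "D > 0")
})
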