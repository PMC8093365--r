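# shared fixtures and small utilities for the suite

fig3 <- function(PR, df, ...) preset_params("fig3", PR = PR, df = df, ...)

# synthetic trajectory object around a given channel signal, for testing
# crossing detection in isolation
synthetic_traj <- function(time, u_A, u_B = rep(0, length(time)),
                           p = preset_params("fig3", PR = 6, df = 0.5)) {
  y <- rbind(u_A = u_A, u_B = u_B, s_A = 0 * u_A, s_B = 0 * u_A)
  structure(list(time = time, y = y, h = diff(time[1:2]),
                 steps_per_period = length(time) - 1L, params = p,
                 gain = "sigmoid", input = "smooth"),
            class = "two_tone_traj")
}

# final 2TR window of a converged periodic state, as a matrix
final_window <- function(ps) {
  y <- ps$traj$y
  N <- ps$traj$steps_per_period
  y[, (ncol(y) - N):ncol(y), drop = FALSE]
}

# sup-norm deviation of the conjugated trajectory from being a solution:
# re-integrate from the conjugate's own (phase-aligned) history segment and
# compare over one period
z2_residual <- function(p, periods = 41L) {
  tr <- integrate_dde(p, horizon = periods * 2 * p$TR)
  conj <- conjugate_traj(tr)
  N <- conj$steps_per_period
  nh <- ceiling(p$D / conj$h) + 4L
  k <- floor((ncol(conj$y) - N - 1) / N)
  j1 <- k * N + 1L
  stopifnot(j1 - nh >= 1L)
  re <- integrate_dde(p, history = conj$y[, (j1 - nh):j1, drop = FALSE],
                      horizon = 2 * p$TR, h = conj$h)
  max(abs(re$y[, 1:(N + 1)] - conj$y[, j1:(j1 + N)]))
}

# which tone intervals (1 = first, 2 = second) each unit responds to in the
# final period of a smooth trajectory
respond_sets <- function(p, tr) {
  t0 <- max(tr$time) - 2 * p$TR
  rep <- detect_crossings(tr, window = c(t0, max(tr$time)))
  f <- function(cr) sort(unique(ifelse(((cr - t0) %% (2 * p$TR)) < p$TR,
                                       1L, 2L)))
  list(A = f(rep$crossings_A), B = f(rep$crossings_B), n = rep$n)
}

# does a singular raster match the smooth model's responding-unit sets
# (directly or through the Z2 conjugate)?
rasters_agree <- function(rs, ras) {
  sA <- as.integer(which(ras$codes_last["A", ] > 0))
  sB <- as.integer(which(ras$codes_last["B", ] > 0))
  direct <- identical(rs$A, sA) && identical(rs$B, sB)
  swap <- identical(rs$A, sort(as.integer(3 - sB))) &&
    identical(rs$B, sort(as.integer(3 - sA)))
  direct || swap
}
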