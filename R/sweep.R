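#' Specify a (PR, df) parameter sweep
#'
#' @param params a [model_params()] object providing every parameter except
#'   `PR` and `df` (its own `PR`/`df` values are ignored).
#' @param engine `"analytic"` (state tables), `"singular"` (event-driven
#'   singular limit), or `"smooth"` (full DDE with sigmoid gain and smooth
#'   inputs).
#' @param PR_range,df_range axis limits; grids are uniform.
#' @param nx,ny number of grid points along `PR` and `df` (default 96).
#' @param warm_start smooth engine only: reuse the previous cell's final
#'   state as the history of the next cell instead of restarting from
#'   `(1, 0, 1, 0)` (default `FALSE`: every cell starts from the same
#'   initial conditions).
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(params, engine = c("analytic", "singular", "smooth"),
                       PR_range = c(1, 40), df_range = c(0, 1),
                       nx = 96L, ny = 96L, warm_start = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "two_tone_params"), nx >= 2L, ny >= 2L,
            PR_range[1] > 0, df_range[1] >= 0, df_range[2] <= 1)
  structure(list(params = params, engine = engine, PR_range = PR_range,
                 df_range = df_range, nx = as.integer(nx),
                 ny = as.integer(ny), warm_start = warm_start),
            class = "sweep_spec")
}

#' Run a (PR, df) sweep and assemble a van Noorden diagram
#'
#' Evaluates every grid cell with the requested engine.  The smooth engine
#' integrates the DDE to its periodic state ([periodic_state()]) and counts
#' threshold crossings; the singular engine runs the event-driven simulator
#' and counts turn-ons; the analytic engine evaluates the state tables
#' ([bio_state()] or [short_main_state()] depending on the delay regime).
#' Cells whose parameters fall outside an engine's validity (for instance
#' `TD + D >= TR` for the analytic tables) are flagged invalid rather than
#' aborting the sweep.  Deterministic: identical specs give identical
#' results.
#'
#' @param spec a [sweep_spec()].
#' @param progress print a dot per grid column (default `FALSE`).
#' @return A `data.frame` of class `"sweep_result"` with one row per cell:
#'   `PR`, `df`, `n_A`, `n_B`, `n`, `percept`, `state`, `residual`,
#'   `valid`.
#' @export
run_sweep <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  PRs <- seq(spec$PR_range[1], spec$PR_range[2], length.out = spec$nx)
  dfs <- seq(spec$df_range[1], spec$df_range[2], length.out = spec$ny)
  base <- spec$params
  rows <- vector("list", spec$nx * spec$ny)
  idx <- 0L
  for (pr in PRs) {
    hist_prev <- c(1, 0, 1, 0)
    for (df in dfs) {
      idx <- idx + 1L
      rec <- list(PR = pr, df = df, n_A = NA_integer_, n_B = NA_integer_,
                  n = NA_integer_, percept = NA_character_,
                  state = NA_character_, residual = NA_real_, valid = FALSE)
      res <- tryCatch({
        p <- model_params(a = base$a, b = base$b, c = base$c, df = df,
                          tau = base$tau, tau_i = base$tau_i, D = base$D,
                          theta = base$theta, TD = base$TD, PR = pr,
                          m = base$m, slope = base$slope)
        switch(spec$engine,
          analytic = {
            st <- if (param_regime(p)[["bio"]]) bio_state(p)
                  else short_main_state(p)
            st <- as.character(st)
            rec$state <- paste(st, collapse = "+")
            rec$percept <- if (length(st) == 1L && st != "none")
              percept_of_state(st) else NA_character_
            rec$valid <- TRUE
          },
          singular = {
            log <- run_singular(p, periods = 12L)
            ras <- extract_raster(log)
            rec$n_A <- ras$n_A; rec$n_B <- ras$n_B; rec$n <- ras$n
            rec$percept <- classify_percept(ras$n)
            rec$state <- singular_state_name(p, ras)
            rec$valid <- log$validity && ras$stable
          },
          smooth = {
            ps <- periodic_state(p, history = hist_prev)
            if (spec$warm_start) hist_prev <- ps$traj$y
            rec$n_A <- ps$report$n_A; rec$n_B <- ps$report$n_B
            rec$n <- ps$report$n
            rec$percept <- classify_percept(ps$report)
            rec$residual <- ps$residual
            rec$valid <- ps$converged
          })
        rec
      }, error = function(e) rec)
      rows[[idx]] <- res
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  attr(out, "spec") <- spec
  class(out) <- c("sweep_result", class(out))
  out
}

# name the analytic state whose predicted codes equal the observed raster;
# I/IS and ID/IDS share a raster (they differ in how long the cross unit
# stays on, not in its onset behaviour) and are split by the P branch
singular_state_name <- function(p, ras) {
  regime <- if (param_regime(p)[["bio"]]) "bio" else "long_delay"
  cands <- if (regime == "bio")
    c("I", "ID", "IS", "IDS", "AS", "ASD", "AP", "APcAS", "AScI")
  else names(short_main_matrices())
  for (nm in cands) {
    if (!raster_matches_state(ras, nm, regime)) next
    if (regime == "bio" && nm %in% c("I", "ID", "IS", "IDS")) {
      strong <- p$a - p$b + p$d >= p$theta
      nm <- switch(nm, I = , IS = if (strong) "I" else "IS",
                   ID = , IDS = if (strong) "ID" else "IDS")
    }
    return(nm)
  }
  "unclassified"
}

#' Extract percept-transition boundaries from a sweep
#'
#' For every `PR` column, reports the `df` midpoints between adjacent cells
#' whose crossing count `n` (or analytic state) differs: the empirical
#' boundary polylines of the van Noorden diagram.
#'
#' @param result a [run_sweep()] result.
#' @param by `"n"` (crossing counts) or `"state"` (analytic state names).
#' @return A `data.frame` with columns `PR`, `df` (transition midpoint),
#'   `from`, `to` (cell values on either side).
#' @export
extract_boundaries <- function(result, by = c("n", "state")) {
  stopifnot(inherits(result, "sweep_result"))
  by <- match.arg(by)
  out <- list()
  for (pr in unique(result$PR)) {
    col <- result[result$PR == pr, ]
    col <- col[order(col$df), ]
    v <- col[[by]]
    for (i in seq_len(nrow(col) - 1L)) {
      if (is.na(v[i]) || is.na(v[i + 1])) next
      if (v[i] != v[i + 1])
        out[[length(out) + 1L]] <- data.frame(
          PR = pr, df = (col$df[i] + col$df[i + 1]) / 2,
          from = as.character(v[i]), to = as.character(v[i + 1]))
    }
  }
  if (!length(out))
    return(data.frame(PR = numeric(0), df = numeric(0),
                      from = character(0), to = character(0)))
  do.call(rbind, out)
}

#' Crossing count of the intermediate band of a sweep
#'
#' Scans the `PR` columns of a smooth-model sweep for one in which the
#' `df`-ordered crossing counts pass from the integration value (4) through
#' a strictly intermediate value to the segregation value (2), and returns
#' that intermediate value.
#'
#' @param result a [run_sweep()] result with counts.
#' @return The intermediate crossing count (typically 3), or `NA` when no
#'   column shows the 4 -> intermediate -> 2 ordering.
#' @export
intermediate_count <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  for (pr in unique(result$PR)) {
    col <- result[result$PR == pr, ]
    col <- col[order(col$df), ]
    v <- col$n[!is.na(col$n)]
    # look for indices i < j < k with v = 4, intermediate, 2
    for (j in which(v > 2 & v < 4)) {
      if (any(v[seq_len(j - 1)] == 4) && any(v[-seq_len(j)] == 2))
        return(v[j])
    }
  }
  NA_integer_
}

#' Write a sweep result as tidy CSV
#'
#' Columns `PR, df, n_A, n_B, n, percept, state, residual, valid` with fixed
#' formatting, so identical sweeps yield byte-identical files.
#'
#' @param result a [run_sweep()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_sweep_csv <- function(result, file) {
  out <- as.data.frame(result)
  for (nm in c("PR", "df", "residual"))
    out[[nm]] <- ifelse(is.na(out[[nm]]), "NA",
                        sprintf("%.15g", out[[nm]]))
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read back a sweep CSV
#'
#' @param file path written by [write_sweep_csv()].
#' @return A `data.frame` of class `"sweep_result"`.
#' @export
read_sweep_csv <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE)
  out$percept <- as.character(out$percept)
  out$state <- as.character(out$state)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Greyscale heatmap of a sweep
#'
#' Plots the crossing count `n` over the (PR, df) grid in the conventional
#' greyscale (black for 0 and 2, lighter towards 4).
#'
#' @param x a [run_sweep()] result.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.sweep_result <- function(x, ...) {
  PRs <- sort(unique(x$PR)); dfs <- sort(unique(x$df))
  z <- matrix(NA_real_, length(PRs), length(dfs))
  for (i in seq_along(PRs))
    z[i, ] <- x$n[x$PR == PRs[i]][order(x$df[x$PR == PRs[i]])]
  shade <- function(n) ifelse(is.na(n), NA,
                              ifelse(n == 0, 0, pmax(0, (n - 2) / 2)))
  graphics::image(PRs, dfs, shade(z), col = grDevices::grey.colors(64, 0, 1),
                  xlab = "PR (Hz)", ylab = "df", ...)
  invisible(x)
}
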