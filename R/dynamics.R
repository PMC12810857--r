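#' Integrate the replicator system
#'
#' Solves the three-population replicator ODE with an adaptive Runge-Kutta
#' 4(5) scheme (Dormand-Prince via deSolve's `ode45`). The analytic flow
#' preserves the unit cube; states are clipped to \[0, 1\] after the solve to
#' remove floating-point overshoot (magnitude below the solver tolerance).
#' Output is sampled densely enough for time-to-threshold interpolation.
#'
#' @param init Initial strategy state (anything [strategy_state()] accepts;
#'   a single state).
#' @param params A `game_parameters` object.
#' @param horizon Integration end time, model time units (default 200).
#' @param rel_tol,abs_tol Solver relative/absolute tolerances.
#' @param n_out Number of equally spaced output samples (>= 200 recommended).
#' @return A `game_trajectory`: a tibble with columns `time`, `delta`, `eta`,
#'   `zeta` and attributes `params`, `solver` (method, tolerances, horizon).
#'   Has an [ggplot2::autoplot()] method.
#' @examples
#' traj <- simulate_game(c(0.5, 0.5, 0.5), baseline_parameters(), horizon = 50)
#' tail(traj)
#' @export
simulate_game <- function(init, params, horizon = 200,
                          rel_tol = 1e-8, abs_tol = 1e-10, n_out = 401) {
  stopifnot(horizon > 0, n_out >= 2)
  s0 <- strategy_state(init)
  if (nrow(s0) != 1L) abort("simulate_game expects a single initial state",
                            class = "trigame_error_state")
  p <- unclass(params)
  y0 <- c(delta = s0$delta, eta = s0$eta, zeta = s0$zeta)
  deriv <- function(t, y, parms) {
    y <- pmin(pmax(y, 0), 1)
    d <- y[[1]]; e <- y[[2]]; z <- y[[3]]
    gp <- p$ip1 - p$ip2 + (1 - e) * (1 - z) * p$mu * p$bp
    gm <- -p$cm1 - p$im2 + p$cm2 + (1 - z) * p$cc + d * p$mu * p$bm +
      z * p$theta * p$vm2
    gg <- p$w + (1 - e) * (p$theta * p$vm2 + d * p$mu * p$bg - p$ig2)
    list(c(d * (1 - d) * gp, e * (1 - e) * gm, z * (1 - z) * gg))
  }
  times <- seq(0, horizon, length.out = n_out)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "ode45", rtol = rel_tol, atol = abs_tol)
  diagn <- attr(sol, "istate")
  if (is.null(diagn) || nrow(sol) < n_out) {
    abort(sprintf("solver failed near t = %.6g",
                  if (nrow(sol) > 0) max(sol[, 1]) else 0),
          class = "trigame_error_solver")
  }
  out <- tibble(
    time = sol[, 1],
    delta = pmin(pmax(sol[, 2], 0), 1),
    eta   = pmin(pmax(sol[, 3], 0), 1),
    zeta  = pmin(pmax(sol[, 4], 0), 1)
  )
  # echo the exact initial condition (guards against clipping noise)
  out$delta[1] <- s0$delta; out$eta[1] <- s0$eta; out$zeta[1] <- s0$zeta
  structure(
    out,
    params = params,
    solver = list(method = "ode45", rel_tol = rel_tol, abs_tol = abs_tol,
                  horizon = horizon, n_out = n_out),
    class = c("game_trajectory", class(out))
  )
}

#' Detect convergence of a trajectory to a corner
#'
#' Returns the corner label whose state is within `corner_tol` (max norm) of
#' the trajectory's final state and at which the vector field norm is below
#' `corner_tol`; `NA` when no corner qualifies.
#'
#' @param traj A `game_trajectory`.
#' @param corner_tol Max-norm tolerance (default 1e-3).
#' @return A corner label (`"E1"`..`"E8"`) or `NA_character_`.
#' @export
detect_convergence <- function(traj, corner_tol = 1e-3) {
  stopifnot(nrow(traj) >= 1)
  params <- attr(traj, "params")
  final <- traj[nrow(traj), c("delta", "eta", "zeta")]
  corners <- corner_equilibria()
  dist <- pmax(
    abs(corners$delta - final$delta),
    abs(corners$eta - final$eta),
    abs(corners$zeta - final$zeta)
  )
  i <- which.min(dist)
  if (dist[i] > corner_tol) return(NA_character_)
  if (!is.null(params)) {
    f <- replicator_field(final, params)
    if (max(abs(c(f$d_delta, f$d_eta, f$d_zeta))) >= corner_tol) {
      return(NA_character_)
    }
  }
  corners$label[i]
}

#' Sample basins of attraction
#'
#' Draws `n` initial states uniformly from the open box (0.01, 0.99)^3 (a
#' margin excludes the absorbing faces of the cube), integrates each, and
#' tallies the detected attractor corners. Reproducible for a fixed seed.
#'
#' @param params A `game_parameters` object.
#' @param n Number of initial states.
#' @param seed Integer RNG seed.
#' @param horizon Integration horizon per trajectory.
#' @param corner_tol Convergence tolerance passed to [detect_convergence()].
#' @param ... Passed on to [simulate_game()].
#' @return A `basin_summary`: tibble with columns `attractor` (corner label
#'   or `"none"`) and `count`, plus attributes `n_samples` and `seed`.
#' @examples
#' basin_sample(baseline_parameters(), n = 5, seed = 1, horizon = 100)
#' @export
basin_sample <- function(params, n, seed = 0, horizon = 200,
                         corner_tol = 1e-3, ...) {
  stopifnot(n >= 0)
  labels <- character(0)
  if (n > 0) {
    set.seed(seed)
    inits <- matrix(runif(3 * n, 0.01, 0.99), ncol = 3)
    labels <- vapply(seq_len(n), function(i) {
      traj <- simulate_game(inits[i, ], params, horizon = horizon, ...)
      lab <- detect_convergence(traj, corner_tol = corner_tol)
      if (is.na(lab)) "none" else lab
    }, character(1))
  }
  tally <- tibble(attractor = labels) |>
    dplyr::count(attractor, name = "count")
  structure(tally, n_samples = n, seed = seed,
            class = c("basin_summary", class(tally)))
}

#' First crossing time of a strategy share, normalized by the horizon
#'
#' Finds the first time a trajectory component reaches `level` (linear
#' interpolation between stored samples) and reports it divided by the
#' integration horizon, so results are comparable across horizons; `NA` when
#' the level is never reached.
#'
#' @param traj A `game_trajectory`.
#' @param variable One of `"delta"`, `"eta"`, `"zeta"`.
#' @param level Threshold in (0, 1).
#' @return Normalized crossing time in \[0, 1\], or `NA_real_`.
#' @examples
#' traj <- simulate_game(c(0.5, 0.5, 0.5), baseline_parameters())
#' time_to_threshold(traj, "eta", 0.96)
#' @export
time_to_threshold <- function(traj, variable = c("delta", "eta", "zeta"),
                              level) {
  variable <- arg_match(variable)
  stopifnot(level > 0, level < 1, nrow(traj) >= 1)
  horizon <- attr(traj, "solver")$horizon %||% max(traj$time)
  x <- traj[[variable]]
  if (x[1] >= level) return(0)
  idx <- which(x >= level)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1]
  t0 <- traj$time[i - 1]; t1 <- traj$time[i]
  x0 <- x[i - 1]; x1 <- x[i]
  tc <- if (x1 == x0) t1 else t0 + (level - x0) / (x1 - x0) * (t1 - t0)
  tc / horizon
}

#' @export
print.game_trajectory <- function(x, ...) {
  meta <- attr(x, "solver")
  cat(sprintf("<game_trajectory> %d samples over t in [0, %g] (%s, rtol %g)\n",
              nrow(x), meta$horizon, meta$method, meta$rel_tol))
  NextMethod()
}
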