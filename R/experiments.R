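.sweep_metrics <- c("final_delta", "final_eta", "final_zeta",
                    "attractor_label", "time_to_eta_0.9")

# evaluate one metric from a finished trajectory
.trajectory_metric <- function(traj, metric) {
  final <- traj[nrow(traj), ]
  switch(metric,
    final_delta = final$delta,
    final_eta = final$eta,
    final_zeta = final$zeta,
    attractor_label = {
      lab <- detect_convergence(traj)
      if (is.na(lab)) "none" else lab
    },
    `time_to_eta_0.9` = time_to_threshold(traj, "eta", 0.9),
    abort(sprintf("unknown metric '%s'", metric),
          class = "trigame_error_metric")
  )
}

.check_param_value <- function(name, value) {
  if (!name %in% .param_names) {
    abort(sprintf("unknown parameter '%s'", name),
          class = "trigame_error_missing_field")
  }
  lo <- 0
  hi <- if (name %in% c("mu", "theta")) 1 else Inf
  if (any(value < lo | value > hi)) {
    abort(sprintf("grid value out of range for '%s'", name),
          class = "trigame_error_range")
  }
  invisible(TRUE)
}

#' Sweep one or two parameters over a grid
#'
#' Re-integrates the system once per grid point and extracts a summary
#' metric from each trajectory: a final strategy share, the detected
#' attractor corner, or the normalized time for compliance to reach 0.9.
#'
#' @param base A `game_parameters` object used for all non-swept fields.
#' @param names Character vector of 1 or 2 parameter names to sweep.
#' @param grids A list of numeric grids, one per swept name (a single
#'   numeric vector is accepted for a 1-parameter sweep).
#' @param metric One of `"final_delta"`, `"final_eta"`, `"final_zeta"`,
#'   `"attractor_label"`, `"time_to_eta_0.9"`.
#' @param init Initial state for every run (default (0.5, 0.5, 0.5)).
#' @param horizon Integration horizon per run.
#' @param ... Passed on to [simulate_game()].
#' @return A `game_sweep`: a long-format tibble with one column per swept
#'   parameter plus `metric` and `value`; attribute `metric_name`.
#' @examples
#' sweep_game(baseline_parameters(), "mu", list(c(0.2, 0.8)),
#'            metric = "attractor_label", horizon = 100)
#' @export
sweep_game <- function(base, names, grids, metric = "final_eta",
                       init = c(0.5, 0.5, 0.5), horizon = 200, ...) {
  metric <- arg_match(metric, .sweep_metrics)
  if (is.numeric(grids)) grids <- list(grids)
  stopifnot(length(names) %in% 1:2, length(grids) == length(names))
  for (i in seq_along(names)) .check_param_value(names[i], grids[[i]])
  grid_df <- tidyr::expand_grid(!!!setNames(grids, names))
  values <- map(seq_len(nrow(grid_df)), function(i) {
    p <- modify_parameters(base, as.list(grid_df[i, ]))
    traj <- simulate_game(init, p, horizon = horizon, ...)
    .trajectory_metric(traj, metric)
  })
  out <- grid_df
  out$metric <- metric
  out$value <- if (metric == "attractor_label") {
    vapply(values, as.character, character(1))
  } else {
    vapply(values, as.numeric, numeric(1))
  }
  structure(out, metric_name = metric,
            class = c("game_sweep", class(out)))
}

#' Locate a critical parameter value by bisection
#'
#' Scans a single parameter for the boundary where a binary criterion flips:
#' * `"attractor_flip"` -- the corner the default-initialized trajectory
#'   converges to changes;
#' * `"e8_stability"` -- the sign of the full-compliance stability margin
#'   `cm1 - cm2 + im2 - cc - mu*bm` (the proposition condition for the
#'   all-ones corner) changes. For a scan over `mu` at otherwise fixed
#'   parameters the boundary has the closed form
#'   `(cm1 - cm2 + im2 - cc) / bm`.
#'
#' @param base A `game_parameters` object.
#' @param name Parameter to scan.
#' @param lo,hi Scan interval endpoints (criterion must differ at the two).
#' @param criterion `"attractor_flip"` or `"e8_stability"`.
#' @param tol Interval width at which bisection stops.
#' @param init,horizon Used by the `attractor_flip` criterion.
#' @return The critical parameter value (interval midpoint), a scalar.
#' @examples
#' threshold_scan(baseline_parameters(), "mu", 0.05, 0.95,
#'                criterion = "e8_stability")
#' @export
threshold_scan <- function(base, name, lo, hi,
                           criterion = c("attractor_flip", "e8_stability"),
                           tol = 1e-3, init = c(0.5, 0.5, 0.5),
                           horizon = 200) {
  criterion <- arg_match(criterion)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    abort("need lo < hi", class = "trigame_error_range")
  }
  .check_param_value(name, c(lo, hi))
  probe <- switch(criterion,
    e8_stability = function(v) {
      p <- unclass(modify_parameters(base, setNames(list(v), name)))
      (p$cm1 - p$cm2 + p$im2 - p$cc - p$mu * p$bm) < 0
    },
    attractor_flip = function(v) {
      p <- modify_parameters(base, setNames(list(v), name))
      traj <- simulate_game(init, p, horizon = horizon)
      lab <- detect_convergence(traj)
      if (is.na(lab)) "none" else lab
    }
  )
  f_lo <- probe(lo); f_hi <- probe(hi)
  if (identical(f_lo, f_hi)) {
    abort("criterion takes the same value at both interval ends",
          class = "trigame_error_no_flip")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (identical(probe(mid), f_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Variance-based sensitivity indices and local elasticities
#'
#' Monte-Carlo first-order sensitivity of the long-run compliance rate to a
#' subset of parameters. Parameters are drawn jointly uniform on their
#' ranges, final eta is computed for each draw, and each first-order index
#' is estimated by the correlation ratio: the variance of per-bin means of
#' the output across equal-probability bins of the input, over the total
#' output variance. One-at-a-time elasticities
#' \eqn{(\partial\eta/\partial p)(p/\eta)} around `base` (central
#' differences, step 1% of the range) are reported alongside; they are local
#' and vanish where the output saturates.
#'
#' @param base A `game_parameters` object (the elasticity anchor; non-swept
#'   fields in the Monte-Carlo draws).
#' @param names Parameters to analyze (default the three policy levers:
#'   medical risk `vm2`, penalty intensity `theta`, exposure rate `mu`).
#' @param ranges Named list of length-2 ranges; defaults `vm2` \[10, 30\],
#'   `theta` \[0.2, 0.8\], `mu` \[0.1, 0.9\].
#' @param n Number of Monte-Carlo draws (>= 16).
#' @param seed Integer RNG seed; fixed seed gives a bit-identical report.
#' @param init,horizon Trajectory settings for every model run.
#' @return A `game_sensitivity` object: list with `indices` (tibble:
#'   `parameter`, `first_order`, `elasticity`), `n_samples`, `seed`. Has
#'   [tidy()] and [ggplot2::autoplot()] methods.
#' @export
sensitivity_indices <- function(base,
                                names = c("vm2", "theta", "mu"),
                                ranges = NULL, n = 512, seed = 0,
                                init = c(0.5, 0.5, 0.5), horizon = 200) {
  if (n < 16) abort("n must be at least 16", class = "trigame_error_range")
  defaults <- list(vm2 = c(10, 30), theta = c(0.2, 0.8), mu = c(0.1, 0.9))
  if (is.null(ranges)) ranges <- defaults[intersect(names, names(defaults))]
  for (nm in names) {
    if (is.null(ranges[[nm]])) {
      abort(sprintf("no range supplied for '%s'", nm),
            class = "trigame_error_range")
    }
    rg <- ranges[[nm]]
    if (length(rg) != 2 || rg[1] >= rg[2]) {
      abort(sprintf("invalid range for '%s'", nm),
            class = "trigame_error_range")
    }
    .check_param_value(nm, rg)
  }
  k <- length(names)
  set.seed(seed)
  u <- matrix(runif(n * k), nrow = n, ncol = k, dimnames = list(NULL, names))
  x <- u
  for (j in seq_len(k)) {
    x[, j] <- ranges[[names[j]]][1] + u[, j] * diff(ranges[[names[j]]])
  }
  y <- vapply(seq_len(n), function(i) {
    p <- modify_parameters(base, as.list(x[i, ]))
    traj <- simulate_game(init, p, horizon = horizon)
    traj$eta[nrow(traj)]
  }, numeric(1))
  vy <- var(y)
  nb <- max(4L, min(32L, n %/% 32L))
  first_order <- vapply(seq_len(k), function(j) {
    if (vy == 0) return(0)
    bins <- cut(rank(x[, j], ties.method = "first"),
                breaks = nb, labels = FALSE)
    bin_means <- tapply(y, bins, mean)
    bin_n <- tabulate(bins, nbins = nb)
    mu_y <- mean(y)
    sum(bin_n * (bin_means - mu_y)^2) / ((n - 1) * vy)
  }, numeric(1))
  elasticity <- vapply(seq_len(k), function(j) {
    nm <- names[j]
    p0 <- unclass(base)[[nm]]
    h <- 0.01 * diff(ranges[[nm]])
    lo <- max(ranges[[nm]][1], p0 - h)
    hi <- min(ranges[[nm]][2], p0 + h)
    run <- function(v) {
      traj <- simulate_game(init, modify_parameters(base, setNames(list(v), nm)),
                            horizon = horizon)
      traj$eta[nrow(traj)]
    }
    y0 <- run(p0)
    if (hi <= lo || y0 == 0) return(NA_real_)
    (run(hi) - run(lo)) / (hi - lo) * p0 / y0
  }, numeric(1))
  structure(
    list(
      indices = tibble(parameter = names, first_order = pmax(first_order, 0),
                       elasticity = elasticity),
      n_samples = n, seed = seed, ranges = ranges
    ),
    class = "game_sensitivity"
  )
}

#' @export
print.game_sensitivity <- function(x, ...) {
  cat(sprintf("<game_sensitivity> n = %d, seed = %d\n", x$n_samples, x$seed))
  print(as.data.frame(x$indices), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @method tidy game_sensitivity
#' @export
tidy.game_sensitivity <- function(x, ...) x$indices

#' @method glance game_sensitivity
#' @export
glance.game_sensitivity <- function(x, ...) {
  tibble(
    n_samples = x$n_samples, seed = x$seed,
    top_parameter = x$indices$parameter[which.max(x$indices$first_order)],
    total_first_order = sum(x$indices$first_order)
  )
}

#' Random parameter sets for property testing
#'
#' Rejection-samples valid parameter sets: payoffs, costs and losses uniform
#' on \[1, 100\], `mu` and `theta` uniform on \[0.05, 0.95\], with
#' `cm2 < cm1` enforced by swapping the pair when drawn in the wrong order.
#' Optionally keeps only sets satisfying one of the two proposition
#' conditions (see [proposition_check()]).
#'
#' @param constraint `"any"`, `"cond1"` or `"cond2"`.
#' @param n Number of sets to return.
#' @param seed Integer RNG seed.
#' @param max_tries Rejection budget (total draws attempted).
#' @return A list of `game_parameters` objects of length `n`.
#' @examples
#' sample_parameters("cond2", n = 2, seed = 1)
#' @export
sample_parameters <- function(constraint = c("any", "cond1", "cond2"),
                              n, seed = 0, max_tries = 1000 * max(n, 1)) {
  constraint <- arg_match(constraint)
  stopifnot(n >= 0)
  out <- vector("list", n)
  if (n == 0) return(out)
  set.seed(seed)
  payoff_fields <- setdiff(.param_names, c("mu", "theta"))
  got <- 0L; tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort("rejection budget exceeded: constraint too tight for the sampling ranges",
            class = "trigame_error_budget")
    }
    draw <- as.list(setNames(runif(length(payoff_fields), 1, 100),
                             payoff_fields))
    draw$mu <- runif(1, 0.05, 0.95)
    draw$theta <- runif(1, 0.05, 0.95)
    if (draw$cm2 >= draw$cm1) {
      tmp <- draw$cm1; draw$cm1 <- draw$cm2; draw$cm2 <- tmp
    }
    if (draw$cm2 == draw$cm1) next
    p <- validate_parameters(draw)
    keep <- switch(constraint,
      any = TRUE,
      cond1 = proposition_check(p)$cond1_holds,
      cond2 = proposition_check(p)$cond2_holds
    )
    if (keep) {
      got <- got + 1L
      out[[got]] <- p
    }
  }
  out
}
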