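#' Available case-study names
#'
#' @return Character vector of bundled case identifiers.
#' @export
list_cases <- function() {
  names(.load_case_file())
}

.load_case_file <- function() {
  path <- system.file("extdata", "cases.toml", package = "trigame",
                      mustWork = TRUE)
  .read_flat_toml(path)
}

#' Load a bundled case-study fixture
#'
#' Each case bundles the observed strategy means (used as the initial
#' condition when simulating the case) and the scenario-specific parameter
#' overrides (`mu`, `vm2`, `theta`); all other payoff parameters are not
#' reported for the cases and fall back to the baseline set when the case is
#' simulated -- case conclusions therefore inherit that fill-in.
#'
#' @param name One of [list_cases()]: `"saudi_tb"`, `"guangdong_covid"`,
#'   `"vietnam_antibiotics"`.
#' @return A `case_study` list: `name`, `description`, `observed` (one-row
#'   strategy-state tibble), `overrides` (named list).
#' @examples
#' load_case("saudi_tb")$observed
#' @export
load_case <- function(name) {
  cases <- .load_case_file()
  if (!name %in% names(cases)) {
    abort(sprintf("unknown case '%s'; available: %s", name,
                  paste(names(cases), collapse = ", ")),
          class = "trigame_error_case")
  }
  raw <- cases[[name]]
  observed <- strategy_state(raw$observed_delta, raw$observed_eta,
                             raw$observed_zeta)
  overrides <- raw[intersect(.param_names, names(raw))]
  structure(
    list(name = name, description = raw$description %||% name,
         observed = observed, overrides = overrides),
    class = "case_study"
  )
}

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf("<case_study> %s\n  %s\n", x$name, x$description))
  cat(sprintf("  observed: delta=%.3f eta=%.3f zeta=%.3f\n",
              x$observed$delta, x$observed$eta, x$observed$zeta))
  cat("  overrides:", paste(sprintf("%s=%g", names(x$overrides),
                                    unlist(x$overrides)), collapse = " "), "\n")
  invisible(x)
}

#' Simulate a case study
#'
#' Integrates the replicator system with the base parameters merged with the
#' case's overrides, starting from the case's observed strategy means.
#'
#' @param case A `case_study` (from [load_case()]) or a case name.
#' @param base A `game_parameters` object supplying the fields the case does
#'   not report (default [baseline_parameters()]).
#' @param horizon Integration horizon.
#' @param ... Passed on to [simulate_game()].
#' @return A `game_trajectory`.
#' @examples
#' traj <- simulate_case("saudi_tb", horizon = 50)
#' detect_convergence(traj)
#' @export
simulate_case <- function(case, base = baseline_parameters(), horizon = 200,
                          ...) {
  if (is.character(case)) case <- load_case(case)
  stopifnot(inherits(case, "case_study"))
  params <- modify_parameters(base, case$overrides)
  simulate_game(case$observed, params, horizon = horizon, ...)
}

#' Compare observed case means against model equilibria
#'
#' For each case: integrates the model from the observed means with the
#' case's overrides and reports the gap between observed values and
#' simulated final states. Across cases, reports the Pearson correlation of
#' observed participation vs observed compliance; with fewer than 10 cases
#' the correlation is flagged descriptive, and it is `NA` when either
#' variable has zero variance.
#'
#' @param cases List of `case_study` objects or character vector of case
#'   names (at least 2; default: all bundled cases).
#' @param base,horizon,... As in [simulate_case()].
#' @return A `case_comparison` list: `per_case` (tibble with observed,
#'   simulated-final and gap columns plus the detected attractor),
#'   `delta_eta_correlation`, `descriptive` (logical), `n_cases`.
#' @export
compare_cases <- function(cases = list_cases(), base = baseline_parameters(),
                          horizon = 200, ...) {
  if (is.character(cases)) cases <- map(cases, load_case)
  if (length(cases) < 2) {
    abort("need at least two cases to compare", class = "trigame_error_case")
  }
  rows <- map(cases, function(cs) {
    traj <- simulate_case(cs, base = base, horizon = horizon, ...)
    final <- traj[nrow(traj), ]
    lab <- detect_convergence(traj)
    tibble(
      case = cs$name,
      observed_delta = cs$observed$delta,
      observed_eta = cs$observed$eta,
      observed_zeta = cs$observed$zeta,
      final_delta = final$delta,
      final_eta = final$eta,
      final_zeta = final$zeta,
      gap_delta = final$delta - cs$observed$delta,
      gap_eta = final$eta - cs$observed$eta,
      gap_zeta = final$zeta - cs$observed$zeta,
      attractor = if (is.na(lab)) "none" else lab
    )
  }) |> list_rbind()
  r <- if (var(rows$observed_delta) == 0 || var(rows$observed_eta) == 0) {
    NA_real_
  } else {
    cor(rows$observed_delta, rows$observed_eta)
  }
  structure(
    list(per_case = rows, delta_eta_correlation = r,
         descriptive = nrow(rows) < 10, n_cases = nrow(rows)),
    class = "case_comparison"
  )
}

#' @export
print.case_comparison <- function(x, ...) {
  cat(sprintf("<case_comparison> %d cases\n", x$n_cases))
  print(as.data.frame(x$per_case), row.names = FALSE, digits = 3)
  cat(sprintf("Pearson r(observed delta, observed eta) = %s%s\n",
              format(x$delta_eta_correlation, digits = 3),
              if (x$descriptive) " (descriptive: n < 10)" else ""))
  invisible(x)
}

#' @method tidy case_comparison
#' @export
tidy.case_comparison <- function(x, ...) x$per_case

#' @method glance case_comparison
#' @export
glance.case_comparison <- function(x, ...) {
  tibble(n_cases = x$n_cases,
         delta_eta_correlation = x$delta_eta_correlation,
         descriptive = x$descriptive)
}
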