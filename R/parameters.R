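#' Construct and validate a payoff parameter set
#'
#' The supervision game is parameterized by 17 nonnegative constants in
#' normalized payoff units (each parameter's unit is scaled to 1). The public
#' chooses between participating in safety-risk oversight (payoff `ip1`) and
#' staying out (`ip2`), and bears a loss `bp` when non-compliant care goes
#' unpunished; `mu` is the probability that participation exposes a violation.
#' Institutions earn `im1` at cost `cm1` under compliant care; non-compliance
#' adds revenue `im2` at the smaller cost `cm2` but risks the fine
#' `theta * vm2` under strict supervision, the capture cost `cc` under lax
#' supervision, and reputational damage `bm` when exposed. Regulators earn a
#' base benefit `ig1`, a strict-supervision reward `w` at cost `cg1`, side
#' income `ig2` from captured lax supervision, and a superior-authority
#' penalty `bg` when lax supervision is exposed.
#'
#' Validation enforces the model's structural assumptions: all values
#' nonnegative, `mu` and `theta` in \[0, 1\] (they are a probability and a
#' penalty intensity), and `cm2 < cm1` (cutting corners must be cheaper than
#' compliance, otherwise non-compliance has no cost advantage to model).
#'
#' @param ... Named parameter values (see field list above), or a single
#'   named list/data frame supplying them. All 17 must be present.
#' @return A `game_parameters` object: a named list of the 17 validated
#'   values with a compact print method.
#' @examples
#' p <- baseline_parameters()
#' p$mu
#' tidy(p)
#' @export
game_parameters <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) &&
      (is.list(dots[[1]]) || is.data.frame(dots[[1]]))) {
    dots <- as.list(dots[[1]])
  }
  names(dots) <- tolower(names(dots))
  validate_parameters(dots)
}

#' Validate a raw mapping of the 17 game parameters
#'
#' Lower-level companion to [game_parameters()]: takes a named list and
#' returns a validated `game_parameters` object, raising a distinct classed
#' error for each failure mode.
#'
#' @param raw Named list (or single-row data frame) with the 17 fields,
#'   lowercase names (`ip1`, `ip2`, `mu`, `bp`, `im1`, `cm1`, `im2`, `cm2`,
#'   `theta`, `vm2`, `bm`, `cc`, `ig1`, `w`, `cg1`, `ig2`, `bg`).
#' @return A `game_parameters` object.
#' @section Errors:
#' * `trigame_error_missing_field` -- a field is absent.
#' * `trigame_error_range` -- `mu` or `theta` outside \[0, 1\].
#' * `trigame_error_ordering` -- `cm2 >= cm1`.
#' * `trigame_error_negative` -- any negative value.
#' @export
validate_parameters <- function(raw) {
  raw <- as.list(raw)
  names(raw) <- tolower(names(raw))
  missing <- setdiff(.param_names, names(raw))
  if (length(missing) > 0L) {
    abort(
      paste0("missing parameter field(s): ", paste(missing, collapse = ", ")),
      class = "trigame_error_missing_field"
    )
  }
  vals <- lapply(raw[.param_names], function(x) as.numeric(x)[1])
  bad <- names(vals)[!vapply(vals, function(x) is.finite(x), logical(1))]
  if (length(bad) > 0L) {
    abort(
      paste0("non-finite parameter value(s): ", paste(bad, collapse = ", ")),
      class = "trigame_error_range"
    )
  }
  neg <- names(vals)[vapply(vals, function(x) x < 0, logical(1))]
  if (length(neg) > 0L) {
    abort(
      paste0("negative parameter value(s): ", paste(neg, collapse = ", ")),
      class = "trigame_error_negative"
    )
  }
  for (pr in c("mu", "theta")) {
    if (vals[[pr]] > 1) {
      abort(
        sprintf("%s = %g is outside [0, 1]", pr, vals[[pr]]),
        class = "trigame_error_range"
      )
    }
  }
  if (vals$cm2 >= vals$cm1) {
    abort(
      sprintf(
        "cm2 (%g) must be strictly smaller than cm1 (%g): non-compliant care must be the cheaper option",
        vals$cm2, vals$cm1
      ),
      class = "trigame_error_ordering"
    )
  }
  structure(vals, class = "game_parameters")
}

#' Baseline parameter set (Saudi TB supervision scenario)
#'
#' The reference parameterization used throughout the package's examples,
#' drawn from the tuberculosis treatment-adherence supervision scenario that
#' anchors the model's numerical analysis: `ip1 = 30`, `ip2 = 20`,
#' `mu = 0.8`, `bp = 15`, `im1 = 40`, `cm1 = 30`, `im2 = 20`, `cm2 = 15`,
#' `theta = 0.6`, `vm2 = 20`, `bm = 70`, `cc = 15`, `ig1 = 30`, `w = 25`,
#' `cg1 = 15`, `ig2 = 20`, `bg = 25`. Under this set the all-ones corner
#' (participate, comply, supervise strictly) is the unique evolutionarily
#' stable strategy.
#'
#' @param ... Named overrides of individual fields, e.g.
#'   `baseline_parameters(theta = 0.8)`.
#' @return A `game_parameters` object.
#' @export
baseline_parameters <- function(...) {
  base <- list(
    ip1 = 30, ip2 = 20, mu = 0.8, bp = 15,
    im1 = 40, cm1 = 30, im2 = 20, cm2 = 15,
    theta = 0.6, vm2 = 20, bm = 70, cc = 15,
    ig1 = 30, w = 25, cg1 = 15, ig2 = 20, bg = 25
  )
  overrides <- list(...)
  if (length(overrides) > 0L) {
    names(overrides) <- tolower(names(overrides))
    unknown <- setdiff(names(overrides), .param_names)
    if (length(unknown) > 0L) {
      abort(
        paste0("unknown parameter field(s): ", paste(unknown, collapse = ", ")),
        class = "trigame_error_missing_field"
      )
    }
    base <- modifyList(base, overrides)
  }
  validate_parameters(base)
}

#' Modify fields of a validated parameter set
#'
#' @param params A `game_parameters` object.
#' @param ... Named replacement values; the result is re-validated.
#' @return A `game_parameters` object.
#' @export
modify_parameters <- function(params, ...) {
  stopifnot(inherits(params, "game_parameters"))
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  if (length(overrides) == 0L) return(params)
  names(overrides) <- tolower(names(overrides))
  unknown <- setdiff(names(overrides), .param_names)
  if (length(unknown) > 0L) {
    abort(
      paste0("unknown parameter field(s): ", paste(unknown, collapse = ", ")),
      class = "trigame_error_missing_field"
    )
  }
  validate_parameters(modifyList(unclass(params), overrides))
}

#' @export
print.game_parameters <- function(x, ...) {
  cat("<game_parameters>\n")
  v <- unlist(x)
  cat("  public:     ", sprintf("ip1=%g ip2=%g mu=%g bp=%g", v["ip1"], v["ip2"], v["mu"], v["bp"]), "\n")
  cat("  institution:", sprintf(
    "im1=%g cm1=%g im2=%g cm2=%g theta=%g vm2=%g bm=%g cc=%g",
    v["im1"], v["cm1"], v["im2"], v["cm2"], v["theta"], v["vm2"], v["bm"], v["cc"]
  ), "\n")
  cat("  regulator:  ", sprintf(
    "ig1=%g w=%g cg1=%g ig2=%g bg=%g",
    v["ig1"], v["w"], v["cg1"], v["ig2"], v["bg"]
  ), "\n")
  invisible(x)
}

#' @export
as.list.game_parameters <- function(x, ...) unclass(x)

#' Tidy a parameter set into a two-column tibble
#'
#' @param x A `game_parameters` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter` and `value`.
#' @method tidy game_parameters
#' @export
tidy.game_parameters <- function(x, ...) {
  tibble(parameter = .param_names, value = unlist(x, use.names = FALSE))
}
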