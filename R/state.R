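#' Strategy states of the three populations
#'
#' A strategy state is a point (delta, eta, zeta) in the unit cube: the
#' population shares of publics participating in oversight, institutions
#' providing compliant care, and regulators supervising strictly.
#' `strategy_state()` normalizes flexible input -- a length-3 numeric vector,
#' three scalars, or a data frame with columns `delta`, `eta`, `zeta` -- into
#' a tibble with those three columns, validating that every component lies in
#' \[0, 1\].
#'
#' @param delta Either the participation share, a length-3 vector
#'   `c(delta, eta, zeta)`, or a data frame with the three columns.
#' @param eta,zeta Compliance and strict-supervision shares (ignored when
#'   `delta` already carries all three components).
#' @return A tibble with numeric columns `delta`, `eta`, `zeta` (one row per
#'   state).
#' @examples
#' strategy_state(0.5, 0.5, 0.5)
#' strategy_state(c(1, 0, 1))
#' @export
strategy_state <- function(delta, eta = NULL, zeta = NULL) {
  if (is.data.frame(delta)) {
    need <- c("delta", "eta", "zeta")
    if (!all(need %in% names(delta))) {
      abort("state data frame must have columns delta, eta, zeta",
            class = "trigame_error_state")
    }
    out <- as_tibble(delta[need])
  } else if (is.numeric(delta) && length(delta) == 3L && is.null(eta)) {
    v <- as.numeric(delta)
    out <- tibble(delta = v[1], eta = v[2], zeta = v[3])
  } else {
    if (is.null(eta) || is.null(zeta)) {
      abort("supply delta, eta and zeta", class = "trigame_error_state")
    }
    out <- tibble(delta = as.numeric(delta), eta = as.numeric(eta),
                  zeta = as.numeric(zeta))
  }
  m <- as.matrix(out)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    abort("strategy state components must lie in [0, 1]",
          class = "trigame_error_state")
  }
  out
}

#' Enumerate the eight corner equilibria
#'
#' Every vertex of the strategy cube is a fixed point of the replicator
#' system (each component carries a factor x(1-x)). The corners are labelled
#' E1..E8 in the conventional order: E1(0,0,0), E2(1,0,0), E3(0,1,0),
#' E4(0,0,1), E5(1,1,0), E6(1,0,1), E7(0,1,1), E8(1,1,1).
#'
#' @return A tibble with columns `label`, `delta`, `eta`, `zeta` (8 rows).
#' @examples
#' corner_equilibria()
#' @export
corner_equilibria <- function() {
  tibble(
    label = paste0("E", 1:8),
    delta = c(0, 1, 0, 0, 1, 1, 0, 1),
    eta   = c(0, 0, 1, 0, 1, 0, 1, 1),
    zeta  = c(0, 0, 0, 1, 0, 1, 1, 1)
  )
}

# corner lookup by label, internal
.corner_state <- function(label) {
  corners <- corner_equilibria()
  row <- corners[corners$label == label, ]
  if (nrow(row) != 1L) {
    abort(sprintf("unknown equilibrium label '%s'", label),
          class = "trigame_error_label")
  }
  row
}
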