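#' Jacobian of the replicator system
#'
#' Analytic partial derivatives of the replicator vector field at a state.
#' With \eqn{F_\delta = \delta(1-\delta)G_p} etc., the diagonal entries are
#' \eqn{(1-2\delta)G_p}, \eqn{(1-2\eta)G_m}, \eqn{(1-2\zeta)G_g}; each
#' off-diagonal entry carries a factor \eqn{x(1-x)} and therefore vanishes at
#' every corner, so corner Jacobians are diagonal and the bracket expressions
#' evaluated at a corner are its eigenvalues.
#'
#' @param state A single strategy state.
#' @param params A `game_parameters` object.
#' @return A 3x3 numeric matrix with dimnames `delta`, `eta`, `zeta` (rows:
#'   equations; columns: differentiation variables).
#' @examples
#' game_jacobian(c(0, 0, 0), baseline_parameters())
#' @export
game_jacobian <- function(state, params) {
  s <- strategy_state(state)
  if (nrow(s) != 1L) abort("game_jacobian expects a single state",
                           class = "trigame_error_state")
  p <- unclass(params)
  d <- s$delta; e <- s$eta; z <- s$zeta
  g <- bracket_terms(s, params)
  J <- matrix(0, 3, 3, dimnames = list(c("delta", "eta", "zeta"),
                                       c("delta", "eta", "zeta")))
  J[1, 1] <- (1 - 2 * d) * g$gp
  J[1, 2] <- d * (1 - d) * (-(1 - z) * p$mu * p$bp)
  J[1, 3] <- d * (1 - d) * (-(1 - e) * p$mu * p$bp)
  J[2, 1] <- e * (1 - e) * p$mu * p$bm
  J[2, 2] <- (1 - 2 * e) * g$gm
  J[2, 3] <- e * (1 - e) * (p$theta * p$vm2 - p$cc)
  J[3, 1] <- z * (1 - z) * (1 - e) * p$mu * p$bg
  J[3, 2] <- z * (1 - z) * (-(p$theta * p$vm2 + d * p$mu * p$bg - p$ig2))
  J[3, 3] <- (1 - 2 * z) * g$gg
  J
}

#' Classify one corner equilibrium by Lyapunov's first method
#'
#' Evaluates the Jacobian eigenvalues at a labelled corner and classifies:
#' an evolutionarily stable strategy (ESS) when all eigenvalues are strictly
#' negative, unstable when any is strictly positive, and indeterminate when
#' an eigenvalue lies within `tol` of zero (the linearization is then
#' inconclusive on the center manifold).
#'
#' @param label Corner label, one of `"E1"` .. `"E8"`.
#' @param params A `game_parameters` object.
#' @param tol Eigenvalue magnitude below which the sign is treated as zero.
#' @return A one-row tibble with columns `label`, `delta`, `eta`, `zeta`,
#'   `lambda1`, `lambda2`, `lambda3`, `sign_pattern`, `classification`.
#' @examples
#' classify_equilibrium("E8", baseline_parameters())
#' @export
classify_equilibrium <- function(label, params, tol = 1e-9) {
  corner <- .corner_state(label)
  J <- game_jacobian(corner, params)
  ev <- diag(J)  # corner Jacobians are diagonal
  signs <- ifelse(abs(ev) <= tol, "0", ifelse(ev > 0, "+", "-"))
  classification <- if (all(ev < -tol)) {
    "ESS"
  } else if (any(ev > tol)) {
    "unstable"
  } else {
    "indeterminate"
  }
  bind_cols(
    corner,
    tibble(
      lambda1 = ev[[1]], lambda2 = ev[[2]], lambda3 = ev[[3]],
      sign_pattern = paste0("(", paste(signs, collapse = ","), ")"),
      classification = classification
    )
  )
}

#' Labels of all evolutionarily stable corners
#'
#' @inheritParams classify_equilibrium
#' @return Character vector of corner labels classified ESS (possibly empty).
#' @examples
#' ess_set(baseline_parameters())
#' @export
ess_set <- function(params, tol = 1e-9) {
  reports <- stability_analysis(params, tol = tol)$equilibria
  reports$label[reports$classification == "ESS"]
}

#' Check the two stability propositions
#'
#' The model's two headline results give parameter conditions under which a
#' single corner is evolutionarily stable:
#' * condition 1 (stable non-compliance corner E6(1,0,1)):
#'   `cm2 - cm1 - im2 + theta*vm2 + mu*bm < 0` and `ip2 - ip1 < 0`;
#' * condition 2 (stable full-compliance corner E8(1,1,1)):
#'   `cm1 - cm2 + im2 - cc - mu*bm < 0` and `ip2 - ip1 < 0`.
#'
#' The propositions leave the third eigenvalue's sign implicit; the
#' auxiliary margins `ig2 - w - theta*vm2 - mu*bg` (E6) and `-w` (E8) are
#' therefore reported alongside. Note the printed condition-2 margin keeps
#' the capture cost `cc`, whereas the exact eta-eigenvalue at E8 derived
#' from the replicator equations carries the fine `theta*vm2` instead; when
#' `cc > theta*vm2` condition 2 can hold while E8 is dynamically unstable
#' (see the package vignette). Classification in [stability_analysis()]
#' always uses the exact eigenvalues.
#'
#' @param params A `game_parameters` object.
#' @return A one-row tibble with columns `cond1_holds`, `cond2_holds`, the
#'   two condition margins `cond1_margin`, `cond2_margin`, and the auxiliary
#'   eigenvalues `aux_e6`, `aux_e8`.
#' @examples
#' proposition_check(baseline_parameters())
#' @export
proposition_check <- function(params) {
  p <- unclass(params)
  m1 <- p$cm2 - p$cm1 - p$im2 + p$theta * p$vm2 + p$mu * p$bm
  m2 <- p$cm1 - p$cm2 + p$im2 - p$cc - p$mu * p$bm
  dp <- p$ip2 - p$ip1
  tibble(
    cond1_holds = m1 < 0 && dp < 0,
    cond2_holds = m2 < 0 && dp < 0,
    cond1_margin = m1,
    cond2_margin = m2,
    participation_margin = dp,
    aux_e6 = p$ig2 - p$w - p$theta * p$vm2 - p$mu * p$bg,
    aux_e8 = -p$w
  )
}

#' Full corner-equilibrium stability analysis
#'
#' Classifies all eight corner equilibria and evaluates the two proposition
#' conditions in one pass.
#'
#' @inheritParams classify_equilibrium
#' @return A `game_stability` object: a list with elements `equilibria`
#'   (tibble of eight classified corners), `propositions` (one-row tibble
#'   from [proposition_check()]), `params` and `tol`. Has [tidy()],
#'   [glance()] and [ggplot2::autoplot()] methods.
#' @examples
#' stability_analysis(baseline_parameters())
#' @export
stability_analysis <- function(params, tol = 1e-9) {
  eq <- list_rbind(map(corner_equilibria()$label,
                       classify_equilibrium, params = params, tol = tol))
  structure(
    list(equilibria = eq, propositions = proposition_check(params),
         params = params, tol = tol),
    class = "game_stability"
  )
}

#' @export
print.game_stability <- function(x, ...) {
  cat("<game_stability> corner equilibria:\n")
  print(as.data.frame(x$equilibria), row.names = FALSE, digits = 4)
  pc <- x$propositions
  cat(sprintf(
    "condition 1 (E6): %s (margin %.3g); condition 2 (E8): %s (margin %.3g)\n",
    pc$cond1_holds, pc$cond1_margin, pc$cond2_holds, pc$cond2_margin
  ))
  invisible(x)
}

#' @method tidy game_stability
#' @export
tidy.game_stability <- function(x, ...) x$equilibria

#' @method glance game_stability
#' @export
glance.game_stability <- function(x, ...) {
  ess <- x$equilibria$label[x$equilibria$classification == "ESS"]
  bind_cols(
    tibble(
      n_ess = length(ess),
      ess_labels = paste(ess, collapse = ",")
    ),
    x$propositions[, c("cond1_holds", "cond2_holds")]
  )
}
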