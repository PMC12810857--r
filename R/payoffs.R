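#' Expected utilities of the three populations
#'
#' For each strategy state, computes the expected payoff of each pure
#' strategy and the population mean:
#' \deqn{H_{p1} = I_{p1} - (1-\eta)(1-\zeta)(1-\mu)B_p, \qquad
#'       H_{p2} = I_{p2} - (1-\eta)(1-\zeta)B_p}
#' \deqn{H_{m1} = I_{m1} - C_{m1}, \qquad
#'       H_{m2} = I_{m1} + I_{m2} - C_{m2} - (1-\zeta)C_c - \zeta\theta V_{m2} - \delta\mu B_m}
#' \deqn{H_{g1} = W + I_{g1} - C_{g1} + (1-\eta)\theta V_{m2}, \qquad
#'       H_{g2} = I_{g1} + (1-\eta)I_{g2} - C_{g1} - (1-\eta)\delta\mu B_g}
#' with means \eqn{\bar H_p = \delta H_{p1} + (1-\delta)H_{p2}} and
#' analogously for institutions (weight \eqn{\eta}) and regulators (weight
#' \eqn{\zeta}).
#'
#' @param state A strategy state (anything [strategy_state()] accepts);
#'   vectorized over rows.
#' @param params A `game_parameters` object.
#' @return A tibble, one row per state, with columns `hp1`, `hp2`, `hp_mean`,
#'   `hm1`, `hm2`, `hm_mean`, `hg1`, `hg2`, `hg_mean`.
#' @examples
#' expected_utilities(strategy_state(0.5, 0, 0), baseline_parameters())
#' @export
expected_utilities <- function(state, params) {
  s <- strategy_state(state)
  p <- unclass(params)
  d <- s$delta; e <- s$eta; z <- s$zeta
  hp1 <- p$ip1 - (1 - e) * (1 - z) * (1 - p$mu) * p$bp
  hp2 <- p$ip2 - (1 - e) * (1 - z) * p$bp
  hm1 <- rep(p$im1 - p$cm1, length(d))
  hm2 <- p$im1 + p$im2 - p$cm2 - (1 - z) * p$cc - z * p$theta * p$vm2 -
    d * p$mu * p$bm
  hg1 <- rep(p$w + p$ig1 - p$cg1, length(d)) + (1 - e) * p$theta * p$vm2
  hg2 <- p$ig1 + (1 - e) * p$ig2 - p$cg1 - (1 - e) * d * p$mu * p$bg
  tibble(
    hp1 = hp1, hp2 = hp2, hp_mean = d * hp1 + (1 - d) * hp2,
    hm1 = hm1, hm2 = hm2, hm_mean = e * hm1 + (1 - e) * hm2,
    hg1 = hg1, hg2 = hg2, hg_mean = z * hg1 + (1 - z) * hg2
  )
}

#' Bracket (payoff-advantage) terms of the replicator system
#'
#' The replicator equation for each population is x(1-x) times a "bracket"
#' equal to the payoff difference between its two pure strategies:
#' \deqn{G_p = I_{p1} - I_{p2} + (1-\eta)(1-\zeta)\mu B_p}
#' \deqn{G_m = -C_{m1} - I_{m2} + C_{m2} + (1-\zeta)C_c + \delta\mu B_m + \zeta\theta V_{m2}}
#' \deqn{G_g = W + (1-\eta)\theta V_{m2} + (1-\eta)\delta\mu B_g - (1-\eta)I_{g2}}
#' Each equals the corresponding \eqn{H_{x1} - H_{x2}} from
#' [expected_utilities()].
#'
#' @inheritParams expected_utilities
#' @return A tibble with columns `gp`, `gm`, `gg`, one row per state.
#' @examples
#' bracket_terms(strategy_state(0.5, 0.5, 0.5), baseline_parameters())
#' @export
bracket_terms <- function(state, params) {
  s <- strategy_state(state)
  p <- unclass(params)
  d <- s$delta; e <- s$eta; z <- s$zeta
  tibble(
    gp = p$ip1 - p$ip2 + (1 - e) * (1 - z) * p$mu * p$bp,
    gm = -p$cm1 - p$im2 + p$cm2 + (1 - z) * p$cc + d * p$mu * p$bm +
      z * p$theta * p$vm2,
    gg = p$w + (1 - e) * (p$theta * p$vm2 + d * p$mu * p$bg - p$ig2)
  )
}

#' Replicator vector field
#'
#' Time derivatives of the three strategy shares:
#' \deqn{\dot\delta = \delta(1-\delta)G_p,\quad
#'       \dot\eta = \eta(1-\eta)G_m,\quad
#'       \dot\zeta = \zeta(1-\zeta)G_g.}
#' A share grows when its strategy out-earns the population average; every
#' corner of the cube is a fixed point.
#'
#' @inheritParams expected_utilities
#' @return A tibble with columns `d_delta`, `d_eta`, `d_zeta` and the bracket
#'   values `gp`, `gm`, `gg`, one row per state.
#' @examples
#' replicator_field(strategy_state(0.5, 0.5, 0.5), baseline_parameters())
#' @export
replicator_field <- function(state, params) {
  s <- strategy_state(state)
  g <- bracket_terms(s, params)
  tibble(
    d_delta = s$delta * (1 - s$delta) * g$gp,
    d_eta   = s$eta * (1 - s$eta) * g$gm,
    d_zeta  = s$zeta * (1 - s$zeta) * g$gg,
    gp = g$gp, gm = g$gm, gg = g$gg
  )
}

#' Single cell of the stage-game payoff matrix
#'
#' Returns the (regulator, institution, public) payoffs of one pure-strategy
#' profile. The published payoff table deducts the fine `theta*vm2` from
#' non-compliant institutions even under lax regulation, which is
#' inconsistent with the expected-utility equations used for the dynamics
#' (there the fine applies only under strict supervision, and lax supervision
#' instead costs the capture payment `cc`). With `reconciled = FALSE` the
#' table's printed cells are returned verbatim so the discrepancy is
#' inspectable; with `reconciled = TRUE` (the default elsewhere in the
#' package is to use the expected-utility equations directly) the lax-row
#' non-compliant institution cells substitute `cc` for `theta*vm2`.
#'
#' @param regulator_strict,compliant,participates Logical flags selecting the
#'   pure-strategy profile.
#' @param params A `game_parameters` object.
#' @param reconciled Logical; see Details.
#' @return A one-row tibble with columns `regulator_payoff`,
#'   `institution_payoff`, `public_payoff`.
#' @examples
#' payoff_cell(TRUE, TRUE, TRUE, baseline_parameters())
#' @export
payoff_cell <- function(regulator_strict, compliant, participates, params,
                        reconciled = FALSE) {
  p <- unclass(params)
  fine <- p$theta * p$vm2
  # public
  pub <- if (participates) p$ip1 else p$ip2
  if (!compliant && !regulator_strict) {
    pub <- pub - (if (participates) (1 - p$mu) * p$bp else p$bp)
  }
  # institution
  if (compliant) {
    inst <- p$im1 - p$cm1
  } else {
    inst <- p$im1 + p$im2 - p$cm2
    if (regulator_strict) {
      inst <- inst - fine
    } else {
      inst <- inst - (if (reconciled) p$cc else fine)
    }
    if (participates) inst <- inst - p$mu * p$bm
  }
  # regulator
  if (regulator_strict) {
    reg <- p$w + p$ig1 - p$cg1 + (if (compliant) 0 else fine)
  } else {
    reg <- p$ig1 - p$cg1
    if (!compliant) {
      reg <- reg + p$ig2 - (if (participates) p$mu * p$bg else 0)
    }
  }
  tibble(
    regulator_payoff = reg,
    institution_payoff = inst,
    public_payoff = pub
  )
}

#' Full stage-game payoff matrix
#'
#' All eight pure-strategy profiles as a long tibble; see [payoff_cell()].
#'
#' @inheritParams payoff_cell
#' @return A tibble with flag columns `regulator_strict`, `compliant`,
#'   `participates` and the three payoff columns (8 rows).
#' @export
payoff_matrix <- function(params, reconciled = FALSE) {
  grid <- tidyr::expand_grid(
    regulator_strict = c(TRUE, FALSE),
    compliant = c(TRUE, FALSE),
    participates = c(TRUE, FALSE)
  )
  cells <- pmap(grid, function(regulator_strict, compliant, participates) {
    payoff_cell(regulator_strict, compliant, participates, params,
                reconciled = reconciled)
  })
  bind_cols(grid, list_rbind(cells))
}
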