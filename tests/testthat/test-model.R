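test_that("expected utilities match direct substitution at reference states", {
  p <- baseline_parameters()
  # no compliance, lax supervision: public faces the full inaction loss
  u <- expected_utilities(strategy_state(0.3, 0, 0), p)
  expect_equal(u$hp1, 27)
  expect_equal(u$hp2, 5)
  # full compliance removes the loss terms entirely
  u1 <- expected_utilities(strategy_state(0.7, 1, 0.2), p)
  expect_equal(u1$hp1, 30)
  expect_equal(u1$hp2, 20)
  # institutions under full participation and strict supervision
  u2 <- expected_utilities(strategy_state(1, 0.5, 1), p)
  expect_equal(u2$hm1, 10)
  expect_equal(u2$hm2, -23)
})

test_that("population means are the strategy-share-weighted utilities", {
  params <- random_params(20, seed = 11)
  states <- random_states(20, seed = 12, lo = 0, hi = 1)
  for (i in seq_along(params)) {
    s <- states[i, ]
    u <- expected_utilities(s, params[[i]])
    expect_equal(u$hp_mean, s$delta * u$hp1 + (1 - s$delta) * u$hp2)
    expect_equal(u$hm_mean, s$eta * u$hm1 + (1 - s$eta) * u$hm2)
    expect_equal(u$hg_mean, s$zeta * u$hg1 + (1 - s$zeta) * u$hg2)
  }
})

test_that("brackets equal pairwise payoff differences on random draws", {
  params <- random_params(50, seed = 21)
  states <- random_states(20, seed = 22, lo = 0, hi = 1)
  for (p in params) {
    u <- expected_utilities(states, p)
    g <- bracket_terms(states, p)
    expect_equal(g$gp, u$hp1 - u$hp2, tolerance = 1e-12)
    expect_equal(g$gm, u$hm1 - u$hm2, tolerance = 1e-12)
    expect_equal(g$gg, u$hg1 - u$hg2, tolerance = 1e-12)
  }
})

test_that("bracket values match hand substitution at the baseline", {
  p <- baseline_parameters()
  g <- bracket_terms(strategy_state(0.5, 0.5, 0.5), p)
  expect_equal(unlist(g), c(gp = 13, gm = 6.5, gg = 26))
  g0 <- bracket_terms(strategy_state(0.2, 0, 0), p)
  expect_equal(g0$gp, 22)  # 10 + 0.8 * 15
  # the eta/zeta loss terms vanish at full compliance + strict supervision
  g1 <- bracket_terms(strategy_state(0.5, 1, 1), p)
  expect_equal(g1$gp, p$ip1 - p$ip2)
})

test_that("replicator field is x(1-x) times the bracket and two forms of the
           growth equation agree", {
  p <- baseline_parameters()
  f <- replicator_field(strategy_state(0.5, 0.5, 0.5), p)
  expect_equal(unlist(f[, 1:3]),
               c(d_delta = 3.25, d_eta = 1.625, d_zeta = 6.5))
  # corners are exact fixed points for arbitrary valid parameters
  corners <- corner_equilibria()
  for (q in random_params(25, seed = 31)) {
    fc <- replicator_field(corners, q)
    expect_true(all(fc$d_delta == 0 & fc$d_eta == 0 & fc$d_zeta == 0))
  }
  # x * (H_x1 - mean) form equals x(1-x) * (H_x1 - H_x2) form
  params <- random_params(25, seed = 32)
  states <- random_states(25, seed = 33, lo = 0, hi = 1)
  for (i in seq_along(params)) {
    s <- states[i, ]
    u <- expected_utilities(s, params[[i]])
    f <- replicator_field(s, params[[i]])
    expect_equal(f$d_delta, s$delta * (u$hp1 - u$hp_mean), tolerance = 1e-12)
    expect_equal(f$d_eta, s$eta * (u$hm1 - u$hm_mean), tolerance = 1e-12)
    expect_equal(f$d_zeta, s$zeta * (u$hg1 - u$hg_mean), tolerance = 1e-12)
  }
})

test_that("participation pressure is nonnegative whenever ip1 > ip2", {
  states <- random_states(200, seed = 41, lo = 0, hi = 1)
  for (q in random_params(20, seed = 42)) {
    if (q$ip1 <= q$ip2) next
    g <- bracket_terms(states, q)
    expect_true(all(g$gp > 0))
    f <- replicator_field(states, q)
    expect_true(all(f$d_delta >= 0))
  }
})

test_that("payoff table cells match the printed matrix and its reconciled form", {
  p <- baseline_parameters()
  expect_equal(unlist(payoff_cell(TRUE, TRUE, TRUE, p)),
               c(regulator_payoff = 40, institution_payoff = 10,
                 public_payoff = 30))
  expect_equal(unlist(payoff_cell(FALSE, TRUE, FALSE, p)),
               c(regulator_payoff = 15, institution_payoff = 10,
                 public_payoff = 20))
  # lax + non-compliant: printed table deducts the fine, the reconciled
  # form deducts the capture cost instead
  verbatim <- payoff_cell(FALSE, FALSE, FALSE, p, reconciled = FALSE)
  fixed <- payoff_cell(FALSE, FALSE, FALSE, p, reconciled = TRUE)
  expect_equal(verbatim$institution_payoff, 33)
  expect_equal(fixed$institution_payoff, 30)
  # regulator and public cells are unaffected by reconciliation
  expect_equal(verbatim$regulator_payoff, fixed$regulator_payoff)
  expect_equal(verbatim$public_payoff, fixed$public_payoff)
})

test_that("reconciled payoff cells reproduce the expected-utility equations", {
  # expectation of the cell payoffs over opponents' mixed strategies must
  # equal the closed-form expected utilities, for every population
  params <- random_params(10, seed = 51)
  states <- random_states(10, seed = 52, lo = 0, hi = 1)
  for (i in seq_along(params)) {
    p <- params[[i]]
    s <- states[i, ]
    cells <- payoff_matrix(p, reconciled = TRUE)
    w <- with(cells, ifelse(regulator_strict, s$zeta, 1 - s$zeta) *
                ifelse(compliant, s$eta, 1 - s$eta) *
                ifelse(participates, s$delta, 1 - s$delta))
    u <- expected_utilities(s, p)
    # public: condition on participate vs not
    wp <- with(cells, ifelse(regulator_strict, s$zeta, 1 - s$zeta) *
                 ifelse(compliant, s$eta, 1 - s$eta))
    expect_equal(sum((wp * cells$public_payoff)[cells$participates]),
                 u$hp1, tolerance = 1e-10)
    expect_equal(sum((wp * cells$public_payoff)[!cells$participates]),
                 u$hp2, tolerance = 1e-10)
    # institution: condition on compliant vs not
    wm <- with(cells, ifelse(regulator_strict, s$zeta, 1 - s$zeta) *
                 ifelse(participates, s$delta, 1 - s$delta))
    expect_equal(sum((wm * cells$institution_payoff)[cells$compliant]),
                 u$hm1, tolerance = 1e-10)
    expect_equal(sum((wm * cells$institution_payoff)[!cells$compliant]),
                 u$hm2, tolerance = 1e-10)
    # regulator: condition on strict vs lax
    wg <- with(cells, ifelse(compliant, s$eta, 1 - s$eta) *
                 ifelse(participates, s$delta, 1 - s$delta))
    expect_equal(sum((wg * cells$regulator_payoff)[cells$regulator_strict]),
                 u$hg1, tolerance = 1e-10)
    expect_equal(sum((wg * cells$regulator_payoff)[!cells$regulator_strict]),
                 u$hg2, tolerance = 1e-10)
  }
})
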