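test_that("the eight corners are enumerated in the conventional order", {
  corners <- corner_equilibria()
  expect_equal(nrow(corners), 8)
  expect_equal(corners$label, paste0("E", 1:8))
  expect_equal(unlist(corners[6, c("delta", "eta", "zeta")]),
               c(delta = 1, eta = 0, zeta = 1))
  expect_equal(unlist(corners[8, c("delta", "eta", "zeta")]),
               c(delta = 1, eta = 1, zeta = 1))
  # all eight vertices of the cube, no duplicates
  expect_equal(nrow(unique(corners[, c("delta", "eta", "zeta")])), 8)
})

test_that("corner Jacobians are diagonal with the symbolic eigenvalues", {
  params <- random_params(500, seed = 61)
  corners <- corner_equilibria()
  for (p in params) {
    for (i in seq_len(8)) {
      J <- game_jacobian(corners[i, ], p)
      off <- J - diag(diag(J))
      expect_true(all(off == 0))
      expect_equal(diag(J), corner_eigen_oracle(corners$label[i], p),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("analytic Jacobian agrees with central differences at interior states", {
  params <- random_params(10, seed = 71)
  states <- random_states(20, seed = 72, lo = 0.05, hi = 0.95)
  for (p in params) {
    for (i in seq_len(nrow(states))) {
      J <- game_jacobian(states[i, ], p)
      expect_equal(J, fd_jacobian(states[i, ], p),
                   tolerance = 1e-5, ignore_attr = TRUE)
    }
  }
})

test_that("baseline classification: E8 is the unique ESS, E1/E6 unstable", {
  p <- baseline_parameters()
  st <- stability_analysis(p)
  e1 <- st$equilibria[st$equilibria$label == "E1", ]
  expect_equal(c(e1$lambda1, e1$lambda2, e1$lambda3), c(22, -20, 17))
  expect_equal(e1$sign_pattern, "(+,-,+)")
  expect_equal(e1$classification, "unstable")
  e6 <- st$equilibria[st$equilibria$label == "E6", ]
  expect_equal(c(e6$lambda1, e6$lambda2, e6$lambda3), c(-10, 33, -37))
  expect_equal(e6$classification, "unstable")
  e8 <- st$equilibria[st$equilibria$label == "E8", ]
  expect_true(all(c(e8$lambda1, e8$lambda2, e8$lambda3) < 0))
  expect_equal(e8$classification, "ESS")
  expect_equal(ess_set(p), "E8")
  g <- glance(st)
  expect_equal(g$n_ess, 1)
  expect_equal(g$ess_labels, "E8")
})

test_that("parameter variants move the ESS as the eigenvalues dictate", {
  # weak reputational damage and penalty: non-compliance corner is stable
  p6 <- baseline_parameters(bm = 10, theta = 0.3)
  e6 <- classify_equilibrium("E6", p6)
  expect_equal(c(e6$lambda1, e6$lambda2, e6$lambda3), c(-10, -21, -31))
  expect_equal(ess_set(p6), "E6")
  # participation not worthwhile and no exposure: all-zeros-but-zeta corner
  p4 <- baseline_parameters(ip1 = 10, ip2 = 20, mu = 0)
  e4 <- classify_equilibrium("E4", p4)
  expect_equal(c(e4$lambda1, e4$lambda2, e4$lambda3), c(-10, -23, -17))
  expect_equal(ess_set(p4), "E4")
})

test_that("zero eigenvalues are reported indeterminate, not stable", {
  # ip1 == ip2 makes the participation eigenvalue exactly zero at E8
  p <- baseline_parameters(ip1 = 20, ip2 = 20)
  e8 <- classify_equilibrium("E8", p)
  expect_equal(e8$lambda1, 0)
  expect_equal(e8$classification, "indeterminate")
  expect_false("E8" %in% ess_set(p))
})

test_that("proposition conditions evaluate the printed inequalities", {
  pc <- proposition_check(baseline_parameters())
  expect_false(pc$cond1_holds)   # margin 15-30-20+12+56 = +33
  expect_equal(pc$cond1_margin, 33)
  expect_true(pc$cond2_holds)    # margin 30-15+20-15-56 = -36
  expect_equal(pc$cond2_margin, -36)
  expect_equal(pc$aux_e8, -25)
  pc6 <- proposition_check(baseline_parameters(bm = 10, theta = 0.3))
  expect_true(pc6$cond1_holds)   # 15-30-20+6+8 = -21
  expect_equal(pc6$cond1_margin, -21)
  # equal participation payoffs satisfy neither strict inequality
  pc_eq <- proposition_check(baseline_parameters(ip1 = 20, ip2 = 20))
  expect_false(pc_eq$cond1_holds)
  expect_false(pc_eq$cond2_holds)
})

test_that("proposition conditions predict the ESS where they are exact", {
  # condition 1 with a negative auxiliary margin guarantees E6 stability;
  # condition 2 needs the extra requirement fine >= capture cost to bound
  # the true compliance eigenvalue at E8 (it equals the printed margin
  # plus cc - theta*vm2)
  sets1 <- sample_parameters("cond1", n = 100, seed = 81)
  checked1 <- 0
  for (p in sets1) {
    pc <- proposition_check(p)
    if (pc$aux_e6 < 0) {
      checked1 <- checked1 + 1
      expect_true("E6" %in% ess_set(p))
    }
  }
  expect_gt(checked1, 10)
  sets2 <- sample_parameters("cond2", n = 300, seed = 82)
  checked2 <- 0
  for (p in sets2) {
    if (p$theta * p$vm2 >= p$cc && p$w > 0) {
      checked2 <- checked2 + 1
      expect_true("E8" %in% ess_set(p))
    }
  }
  expect_gt(checked2, 5)
})

test_that("printed condition 2 is not sufficient when the fine exceeds the
           capture cost: dynamics settle on E6 instead of E8", {
  # between the condition-2 boundary (2/7) and the true compliance
  # eigenvalue root (23/70) the printed inequality holds while the
  # all-ones corner is dynamically unstable
  p <- baseline_parameters(mu = 0.31)
  pc <- proposition_check(p)
  expect_true(pc$cond2_holds)
  expect_false("E8" %in% ess_set(p))
  expect_equal(ess_set(p), "E6")
  traj <- simulate_game(c(0.5, 0.5, 0.5), p)
  expect_equal(detect_convergence(traj), "E6")
})

test_that("every ESS corner attracts nearby trajectories and unstable
           corners repel along a positive eigendirection", {
  for (p in list(baseline_parameters(),
                 baseline_parameters(bm = 10, theta = 0.3))) {
    st <- stability_analysis(p)$equilibria
    ess <- st[st$classification == "ESS", ]
    for (i in seq_len(nrow(ess))) {
      start <- abs(unlist(ess[i, c("delta", "eta", "zeta")]) - 0.01)
      traj <- simulate_game(start, p, horizon = 100)
      expect_equal(detect_convergence(traj), ess$label[i])
    }
    # at E1 the participation eigenvalue is positive for both sets:
    # a small delta perturbation grows
    expect_gt(st$lambda1[st$label == "E1"], 0)
    traj <- simulate_game(c(0.01, 0, 0), p, horizon = 50)
    expect_gt(traj$delta[nrow(traj)], 0.5)
  }
})
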