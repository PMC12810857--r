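# shared fixtures for the suite

baseline_list <- function() {
  list(
    ip1 = 30, ip2 = 20, mu = 0.8, bp = 15,
    im1 = 40, cm1 = 30, im2 = 20, cm2 = 15,
    theta = 0.6, vm2 = 20, bm = 70, cc = 15,
    ig1 = 30, w = 25, cg1 = 15, ig2 = 20, bg = 25
  )
}

# random valid parameter draws without the proposition machinery,
# used where sample_parameters itself is under test
random_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pay <- setNames(as.list(runif(15, 1, 100)),
                    c("ip1", "ip2", "bp", "im1", "cm1", "im2", "cm2",
                      "vm2", "bm", "cc", "ig1", "w", "cg1", "ig2", "bg"))
    if (pay$cm2 >= pay$cm1) {
      tmp <- pay$cm1; pay$cm1 <- pay$cm2; pay$cm2 <- tmp
    }
    pay$mu <- runif(1, 0.05, 0.95)
    pay$theta <- runif(1, 0.05, 0.95)
    validate_parameters(pay)
  })
}

random_states <- function(n, seed, lo = 0.01, hi = 0.99) {
  set.seed(seed)
  tibble::tibble(
    delta = runif(n, lo, hi), eta = runif(n, lo, hi), zeta = runif(n, lo, hi)
  )
}

# independent central-difference Jacobian of the replicator field
fd_jacobian <- function(state, params, h = 1e-6) {
  s0 <- as.numeric(strategy_state(state)[1, ])
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    up <- s0; dn <- s0
    up[j] <- up[j] + h; dn[j] <- dn[j] - h
    fu <- replicator_field(trigame::strategy_state(pmin(pmax(up, 0), 1)), params)
    fd <- replicator_field(trigame::strategy_state(pmin(pmax(dn, 0), 1)), params)
    J[, j] <- (unlist(fu[1, c("d_delta", "d_eta", "d_zeta")]) -
                 unlist(fd[1, c("d_delta", "d_eta", "d_zeta")])) / (2 * h)
  }
  J
}

# per-corner symbolic eigenvalues, written out corner by corner from the
# pairwise payoff differences (the oracle for game_jacobian at corners);
# the published eigenvalue table agrees except at E7/E8 where its second
# entry is garbled -- these are the expressions the dynamics imply
corner_eigen_oracle <- function(label, params) {
  p <- as.list(params)
  fine <- p$theta * p$vm2
  with(p, switch(label,
    E1 = c(ip1 - ip2 + mu * bp,
           cm2 - cm1 - im2 + cc,
           w + fine - ig2),
    E2 = c(ip2 - ip1 - mu * bp,
           cm2 - cm1 - im2 + cc + mu * bm,
           w + fine + mu * bg - ig2),
    E3 = c(ip1 - ip2,
           cm1 + im2 - cm2 - cc,
           w),
    E4 = c(ip1 - ip2,
           cm2 - cm1 - im2 + fine,
           ig2 - w - fine),
    E5 = c(ip2 - ip1,
           cm1 + im2 - cm2 - cc - mu * bm,
           w),
    E6 = c(ip2 - ip1,
           cm2 - cm1 - im2 + fine + mu * bm,
           ig2 - w - fine - mu * bg),
    E7 = c(ip1 - ip2,
           cm1 + im2 - cm2 - fine,
           -w),
    E8 = c(ip2 - ip1,
           cm1 + im2 - cm2 - fine - mu * bm,
           -w),
    stop("unknown label")
  ))
}
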