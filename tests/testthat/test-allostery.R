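# Allosteric efficacies, channel closed forms, chains, interacting channels.

test_that("two-component efficacy matches the exponential closed form", {
  ind <- ising_system(c("L", "R"), conf_energy = c(0.3, -0.7))
  e0 <- allosteric_efficacy(ind, "L", "R")
  expect_equal(e0$alpha, 1, tolerance = 1e-12)
  expect_equal(e0$u_eff, 0, tolerance = 1e-12)

  s <- ising_system(c("L", "R"), conf_energy = 0, couplings = c("L:R" = -1))
  expect_rel(allosteric_efficacy(s, "L", "R")$alpha, exp(4))

  expect_equal(alpha_two_component(0), 1)
  expect_rel(alpha_two_component(-1), exp(4))
  expect_rel(alpha_two_component(0.5), exp(-2))  # inverse agonism

  set.seed(61)
  for (rep in 1:200) {
    u <- stats::rnorm(1); h <- stats::rnorm(2); b <- stats::runif(1, 0.5, 2)
    sys <- ising_system(c("L", "R"), conf_energy = h,
                        couplings = c("L:R" = u), beta = b)
    expect_rel(allosteric_efficacy(sys, "L", "R")$alpha,
               alpha_two_component(u, b))
  }
})

test_that("efficacy at one site is independent of other uncoupled sites", {
  set.seed(62)
  for (rep in 1:50) {
    u1 <- stats::rnorm(1); u2 <- stats::rnorm(1)
    sys <- ising_system(c("L", "A1", "A2"),
                        conf_energy = stats::rnorm(3),
                        couplings = c("L:A1" = u1, "L:A2" = u2))
    expect_rel(allosteric_efficacy(sys, "L", "A1")$alpha,
               alpha_two_component(u1))
  }
})

test_that("conditional efficacies equal the direct pair term in Ising systems", {
  set.seed(63)
  for (rep in 1:50) {
    sys <- random_triangle()
    d <- enumerate_distribution(sys)
    expected <- alpha_two_component(sys$J["L", "A"])
    expect_rel(conditional_efficacy(d, "L", "A", "C", 1), expected)
    expect_rel(conditional_efficacy(d, "L", "A", "C", -1), expected)
    expect_rel(direct_efficacy(d, "L", "A", "C"), expected)
  }
  s0 <- ising_system(c("L", "C", "A"), conf_energy = 0,
                     couplings = c("L:C" = -1, "C:A" = -1))
  d0 <- enumerate_distribution(s0)
  expect_equal(conditional_efficacy(d0, "L", "A", "C", 1), 1,
               tolerance = 1e-12)
  expect_error(conditional_efficacy(d0, "L", "A", "L", 1), "distinct")
})

test_that("direct efficacy is the probability-weighted conditional odds ratio", {
  set.seed(64)
  for (rep in 1:30) {
    g <- random_general(3)
    d <- enumerate_distribution(g)
    nm <- component_names(g)
    # hand-computed weighted sum over the mediator's states
    pm <- marginal(d, nm[2L])
    manual <- pm$p[pm[[nm[2L]]] == 1] *
        conditional_efficacy(d, nm[1L], nm[3L], nm[2L], 1) +
      pm$p[pm[[nm[2L]]] == -1] *
        conditional_efficacy(d, nm[1L], nm[3L], nm[2L], -1)
    expect_rel(direct_efficacy(d, nm[1L], nm[3L], nm[2L]), manual, 1e-12)
    expect_rel(direct_efficacy(d, nm[1L], nm[3L]),
               allosteric_efficacy(d, nm[1L], nm[3L])$alpha, 1e-12)
  }
  d <- enumerate_distribution(random_general(3))
  expect_error(direct_efficacy(d, "X1", "X3", "X1"), "disjoint")
})

test_that("three-component closed form and indirect factor are exact", {
  expect_rel(alpha_three_component(-0.3, channel_spec(1.2, 0, 0.8)),
             alpha_two_component(-0.3))
  expect_rel(alpha_three_component(0, channel_spec(0, -1, -1)),
             (cosh(4) + 1) / 2)
  expect_rel(alpha_three_component(0, channel_spec(1, -1, -1)),
             (cosh(4) + cosh(2)) / (1 + cosh(2)))

  expect_rel(alpha_indirect(channel_spec(0, -1, -1)), (cosh(4) + 1) / 2)
  # sign reversal inverts the indirect factor exactly
  expect_rel(alpha_indirect(channel_spec(0, -1, 1)),
             1 / alpha_indirect(channel_spec(0, -1, -1)), 1e-12)
  # a frozen channel transmits nothing
  expect_rel(alpha_indirect(channel_spec(300, -1, -1)), 1)
  expect_rel(alpha_indirect(channel_spec(-300, -1, -1)), 1)

  set.seed(65)
  for (rep in 1:200) {
    sys <- random_triangle()
    expect_rel(
      allosteric_efficacy(sys, "L", "A")$alpha,
      alpha_three_component(sys$J["L", "A"],
                            channel_spec(unname(sys$conf["C"]),
                                         sys$J["L", "C"], sys$J["C", "A"])))
  }
})

test_that("the efficacy decomposes into direct and indirect factors", {
  set.seed(66)
  for (rep in 1:50) {
    sys <- random_triangle()
    rp <- allosteric_efficacy(sys, "L", "A", decompose = "C")
    expect_rel(rp$alpha, rp$alpha_direct * rp$alpha_indirect)
    expect_rel(rp$alpha_direct, alpha_two_component(sys$J["L", "A"]))
    expect_rel(rp$alpha_indirect,
               alpha_indirect(channel_spec(unname(sys$conf["C"]),
                                           sys$J["L", "C"],
                                           sys$J["C", "A"])))
    expect_rel(rp$conditional[["up"]], rp$alpha_direct)
    expect_rel(rp$conditional[["down"]], rp$alpha_direct)
  }
})

test_that("estimate_from_direct reconstructs the exact Ising efficacy", {
  expect_equal(estimate_from_direct(1, 1, 1, 0.7), 1, tolerance = 1e-12)
  expect_error(estimate_from_direct(-1, 1, 1, 0), "positive")

  set.seed(67)
  for (rep in 1:100) {
    sys <- random_triangle()
    d <- enumerate_distribution(sys)
    est <- estimate_from_direct(direct_efficacy(d, "L", "A", "C"),
                                direct_efficacy(d, "L", "C", "A"),
                                direct_efficacy(d, "C", "A", "L"),
                                unname(sys$conf["C"]))
    expect_rel(est, allosteric_efficacy(d, "L", "A")$alpha)
  }
})

test_that("channel and site roles are interchangeable (duality)", {
  set.seed(68)
  for (rep in 1:50) {
    sys <- random_triangle()
    d <- enumerate_distribution(sys)
    # treat A (rather than C) as the mediating channel for the L-C pair
    est <- estimate_from_direct(direct_efficacy(d, "L", "C", "A"),
                                direct_efficacy(d, "L", "A", "C"),
                                direct_efficacy(d, "A", "C", "L"),
                                unname(sys$conf["A"]))
    expect_rel(est, allosteric_efficacy(d, "L", "C")$alpha)
  }
})

test_that("multi-channel energies are additive and efficacies multiplicative", {
  ch <- channel_spec(0, -1, -1)
  one <- multichannel_estimate(0.2, list(ch))
  expect_rel(one$alpha, alpha_three_component(0.2, ch))

  two <- multichannel_estimate(0, list(ch, ch))
  sys4 <- ising_system(c("L", "C1", "C2", "A"), conf_energy = 0,
                       couplings = c("L:C1" = -1, "L:C2" = -1,
                                     "C1:A" = -1, "C2:A" = -1))
  expect_rel(two$alpha, allosteric_efficacy(sys4, "L", "A")$alpha)
  expect_rel(two$alpha, ((cosh(4) + 1) / 2)^2)

  # equal-magnitude, opposite-sign channels cancel exactly
  canc <- multichannel_estimate(0.4, list(channel_spec(0.3, -1, -0.5),
                                          channel_spec(0.3, -1, 0.5)))
  expect_equal(canc$u_eff, 0.4, tolerance = 1e-12)

  set.seed(69)
  for (rep in 1:100) {
    k <- sample(1:3, 1L)
    u_la <- stats::rnorm(1)
    chans <- replicate(k, channel_spec(stats::rnorm(1), stats::rnorm(1),
                                       stats::rnorm(1)), simplify = FALSE)
    nm <- c("L", paste0("C", seq_len(k)), "A")
    cp <- c(stats::setNames(vapply(chans, `[[`, 0, "u_lc"),
                            paste0("L:C", seq_len(k))),
            stats::setNames(vapply(chans, `[[`, 0, "u_ca"),
                            paste0("C", seq_len(k), ":A")),
            c("L:A" = u_la))
    sys <- ising_system(nm,
                        conf_energy = c(0, vapply(chans, `[[`, 0, "u_conf_c"),
                                        0),
                        couplings = cp)
    expect_rel(multichannel_estimate(u_la, chans)$alpha,
               allosteric_efficacy(sys, "L", "A")$alpha)
  }
})

test_that("serial chains obey the tanh-product law and decay exponentially", {
  expect_equal(chain_effective_energy(-0.8), -0.8, tolerance = 1e-12)
  expect_rel(chain_effective_energy(c(-1, -1)), -atanh(tanh(1)^2))

  set.seed(70)
  for (rep in 1:30) {
    n <- sample(3:12, 1L)
    u <- stats::rnorm(n - 1L)
    u_eff <- chain_effective_energy(u)
    expect_rel(tanh(-u_eff), prod(tanh(-u)))
  }

  prof <- chain_decay_profile(10, lengths = 2:10)
  expect_true(all(diff(abs(prof$u_eff)) < 0))
})

test_that("interacting channel pairs reshape or cancel the allosteric signal", {
  sweep_ <- seq(-2, 2, by = 0.5)

  # zero inter-channel coupling reduces to the independent multichannel value
  bp <- two_channel_scan("both_positive", "both", 0)
  expect_rel(bp$alpha,
             multichannel_estimate(0, list(channel_spec(0, -1, -1),
                                           channel_spec(0, -1, -1)))$alpha)

  # opposite channels engaged equally cancel at every swept coupling
  opp <- two_channel_scan("opposite", "both", sweep_)
  expect_true(all(abs(opp$u_eff) < 1e-10))

  # negative inter-channel coupling amplifies positive-pair signaling
  amp1 <- two_channel_scan("both_positive", "one", c(-1, 0))
  ampb <- two_channel_scan("both_positive", "both", c(-1, 0))
  expect_gt(abs(amp1$u_eff[1L]), abs(amp1$u_eff[2L]))
  expect_gt(abs(ampb$u_eff[1L]), abs(ampb$u_eff[2L]))
})

test_that("degenerate odds cells raise errors rather than infinities", {
  frozen <- ising_system(c("L", "R"), conf_energy = c(0, 800))
  expect_error(allosteric_efficacy(frozen, "L", "R"), "degenerate")
  expect_error(allosteric_efficacy(frozen, "L", "L"), "differ")
})
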