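# Model types, energies, enumeration, marginals, conditionals.

test_that("Ising configuration energies follow the spin Hamiltonian", {
  s1 <- ising_system(c("A", "B"), conf_energy = 0, couplings = c("A:B" = -1))
  expect_equal(state_energy(s1, c(1, 1)), -1)

  s2 <- ising_system(c("A", "B"), conf_energy = c(1, 1),
                     couplings = c("A:B" = -1))
  expect_equal(state_energy(s2, c(-1, -1)), -3)  # -2 field, s_i s_j = +1

  expect_error(state_energy(s1, c(1, 1, 1)), "2 components")
  expect_error(state_energy(s1, c(1, 2)), "-1 or \\+1")
})

test_that("general two-state energies sum conformational and table terms", {
  g <- general_system(c("L", "R"),
                      conf_energy_table = rbind(c(0, 0.3), c(0, -0.2)),
                      interaction_tables = list(
                        "L:R" = matrix(c(0, 0, 0, -1), 2, 2, byrow = TRUE)))
  expect_equal(state_energy(g, c(1, 1)), -0.9)
  expect_equal(state_energy(g, c(-1, -1)), 0)
})

test_that("ising_to_general imposes the Ising symmetries and preserves the distribution", {
  s <- ising_system(c("A", "B"), conf_energy = c(0.4, -0.2),
                    couplings = c("A:B" = -1))
  g <- ising_to_general(s)
  tb <- g$int_tables[["A:B"]]
  expect_equal(unname(tb), matrix(c(-1, 1, 1, -1), 2, 2))
  expect_equal(unname(g$conf_table[, "up"]), c(0.4, -0.2))
  expect_equal(unname(g$conf_table[, "down"]), -c(0.4, -0.2))

  z <- ising_to_general(ising_system(c("A", "B"), conf_energy = 0))
  expect_true(all(z$conf_table == 0))
  expect_length(z$int_tables, 0L)

  set.seed(11)
  for (rep in 1:50) {
    n <- sample(2:4, 1L)
    sys <- random_ising(n)
    p1 <- enumerate_distribution(sys)$p
    p2 <- enumerate_distribution(ising_to_general(sys))$p
    expect_lt(max(abs(p1 - p2)), 1e-12)
  }
})

test_that("ligandize reproduces the zero-when-unbound physical system", {
  s <- ising_system(c("L", "R"), conf_energy = c(L = 0, R = 0.5),
                    couplings = c("L:R" = -1))
  lz <- ligandize(s, "L")
  expect_equal(unname(lz$conf["R"]), 0)       # 0.5 + (-1)/2
  expect_equal(lz$J["L", "R"], -0.5)

  s0 <- ising_system(c("L", "R"), conf_energy = c(0, 0.5))
  expect_equal(ligandize(s0, "L"), s0)

  # oracle: general system with the Eq.-24 form (interaction only when bound)
  set.seed(21)
  for (rep in 1:30) {
    sys <- random_triangle()
    g <- ising_to_general(sys)
    for (key in names(g$int_tables)) {
      pr <- strsplit(key, ":", fixed = TRUE)[[1L]]
      if (!"L" %in% pr) next
      u <- sys$J[pr[1L], pr[2L]]
      phys <- matrix(c(0, 0, -u, u), 2, 2, byrow = TRUE)  # rows = L state
      if (pr[2L] == "L") phys <- t(phys)
      g$int_tables[[key]] <- phys
    }
    p_phys <- enumerate_distribution(g)$p
    p_lig <- enumerate_distribution(ligandize(sys, "L"))$p
    expect_lt(max(abs(p_phys - p_lig)), 1e-12)
  }

  expect_error(ligandize(s, "Q"), "unknown component")
})

test_that("zero_unbound_ligand blanks exactly the unbound-ligand cells", {
  set.seed(31)
  g <- random_general(3)
  gz <- zero_unbound_ligand(g, "X1")
  for (key in names(g$int_tables)) {
    pr <- strsplit(key, ":", fixed = TRUE)[[1L]]
    a <- g$int_tables[[key]]; b <- gz$int_tables[[key]]
    if (pr[1L] == "X1") {
      expect_equal(unname(b["down", ]), c(0, 0))
      expect_equal(b["up", ], a["up", ])
    } else if (pr[2L] == "X1") {
      expect_equal(unname(b[, "down"]), c(0, 0))
      expect_equal(b[, "up"], a[, "up"])
    } else {
      expect_equal(b, a)
    }
  }
})

test_that("enumeration gives exact Boltzmann probabilities, stably", {
  d1 <- enumerate_distribution(ising_system("X", conf_energy = 0))
  expect_equal(d1$p, c(0.5, 0.5))

  d2 <- enumerate_distribution(
    ising_system(c("A", "B"), conf_energy = 0, couplings = c("A:B" = -1)))
  # hand-evaluated Boltzmann weights: Z = 2e + 2/e
  p_same <- exp(1) / (2 * exp(1) + 2 * exp(-1))
  expect_equal(d2$p, c(p_same, (1 - 2 * p_same) / 2, (1 - 2 * p_same) / 2,
                       p_same), tolerance = 1e-12)

  d3 <- enumerate_distribution(
    ising_system(c("A", "B"), conf_energy = c(100, 0)))
  expect_true(all(is.finite(d3$p)))
  mA <- marginal(d3, "A")
  expect_equal(mA$p[mA$A == -1], 1, tolerance = 1e-12)

  d4 <- enumerate_distribution(
    ising_system(c("A", "B"), conf_energy = c(500, -500),
                 couplings = c("A:B" = 480)))
  expect_true(all(is.finite(d4$p)))
  expect_equal(sum(d4$p), 1, tolerance = 1e-12)
})

test_that("the enumeration cap is enforced by name", {
  sys <- ising_system(paste0("X", 1:5), conf_energy = 0)
  expect_error(enumerate_distribution(sys, cap = 4), "capped at 4")
})

test_that("marginals sum out exactly the right components", {
  set.seed(41)
  sys <- random_ising(3)
  d <- enumerate_distribution(sys)

  expect_equal(marginal(d, component_names(sys))$p, d$p)

  ind <- enumerate_distribution(ising_system(c("A", "B"), conf_energy = 0))
  expect_equal(marginal(ind, "A")$p, c(0.5, 0.5))
  expect_equal(marginal(ind, "B")$p, c(0.5, 0.5))

  # direct-summation oracle over the third component
  m12 <- marginal(d, c("X1", "X2"))
  for (r in seq_len(nrow(m12))) {
    keep <- d$spins[, 1L] == m12$X1[r] & d$spins[, 2L] == m12$X2[r]
    expect_equal(m12$p[r], sum(d$p[keep]), tolerance = 1e-14)
  }
  expect_equal(sum(m12$p), 1, tolerance = 1e-12)

  expect_error(marginal(d, "nope"), "unknown component")
  expect_error(marginal(d, character()), "at least one")
})

test_that("conditionals renormalise and obey total probability", {
  set.seed(42)
  sys <- random_ising(3)
  d <- enumerate_distribution(sys)

  expect_equal(conditional(d, c("X1", "X2"))$p, marginal(d, c("X1", "X2"))$p)

  pC <- marginal(d, "X3")
  up <- conditional(d, c("X1", "X2"), c(X3 = 1))
  dn <- conditional(d, c("X1", "X2"), c(X3 = -1))
  expect_equal(sum(up$p), 1, tolerance = 1e-12)
  recomb <- pC$p[pC$X3 == 1] * up$p + pC$p[pC$X3 == -1] * dn$p
  expect_equal(recomb, marginal(d, c("X1", "X2"))$p, tolerance = 1e-12)

  expect_error(conditional(d, "X1", c(X1 = 1)), "disjoint")
  frozen <- enumerate_distribution(
    ising_system(c("A", "B"), conf_energy = c(800, 0)))
  expect_error(conditional(frozen, "B", c(A = 1)), "zero probability")
})

test_that("distributions are normalised and spin-flip symmetric", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(2:5, 1L)
    sys <- random_ising(n)
    d <- enumerate_distribution(sys)
    expect_lt(abs(sum(d$p) - 1), 1e-12)

    flipped <- sys
    flipped$conf <- -flipped$conf
    df <- enumerate_distribution(flipped)
    expect_lt(max(abs(d$p - rev(df$p))), 1e-12)

    g <- random_general(n)
    expect_lt(abs(sum(enumerate_distribution(g)$p) - 1), 1e-12)
  }
})

test_that("construction validates names, pairs, and energies", {
  expect_error(ising_system(c("A", "A")), "unique")
  expect_error(ising_system(c("A", "B"), couplings = c("A:C" = 1)),
               "unknown component 'C'")
  expect_error(ising_system(c("A", "B"), couplings = c("A:A" = 1)),
               "self-coupling")
  expect_error(ising_system(c("A", "B"), conf_energy = c(Inf, 0)), "finite")
  expect_error(ising_system(c("A", "B"), beta = -1), "positive")
  expect_error(general_system(c("A", "B"), rbind(c(0, 1), c(0, 1)),
                              list("A:C" = diag(2))),
               "unknown component 'C'")
})
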