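# Random-system generators used across the suite.  Callers control the RNG
# state with set.seed(); every energy is an independent Normal(0, sigma) draw.

random_ising <- function(n, sigma = 1, beta = 1) {
  nm <- paste0("X", seq_len(n))
  pr <- t(utils::combn(n, 2L))
  cp <- data.frame(i = nm[pr[, 1L]], j = nm[pr[, 2L]],
                   value = stats::rnorm(nrow(pr), 0, sigma))
  ising_system(nm, conf_energy = stats::rnorm(n, 0, sigma), couplings = cp,
               beta = beta)
}

random_general <- function(n, sigma = 1, beta = 1) {
  nm <- paste0("X", seq_len(n))
  ct <- matrix(stats::rnorm(2L * n, 0, sigma), n, 2L)
  pr <- t(utils::combn(n, 2L))
  tabs <- list()
  for (k in seq_len(nrow(pr)))
    tabs[[paste(nm[pr[k, 1L]], nm[pr[k, 2L]], sep = ":")]] <-
      matrix(stats::rnorm(4L, 0, sigma), 2L, 2L)
  general_system(nm, ct, tabs, beta = beta)
}

# a random Ising ligand/channel/site triangle with named components
random_triangle <- function(sigma = 1, beta = 1, direct = TRUE) {
  ising_system(c("L", "C", "A"),
               conf_energy = stats::rnorm(3, 0, sigma),
               couplings = c("L:C" = stats::rnorm(1, 0, sigma),
                             "C:A" = stats::rnorm(1, 0, sigma),
                             "L:A" = if (direct) stats::rnorm(1, 0, sigma)
                                     else 0),
               beta = beta)
}

expect_rel <- function(actual, expected, tol = 1e-9) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
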