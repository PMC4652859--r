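# Random-system ensembles: generate Ising and general (non-Ising) two-state
# systems with Normal(0, sigma) energies and run the validation experiments
# that compare exact enumerated effective interaction energies with the
# Ising-derived estimators, or relate symmetric uncertainty to |u_eff|.
#
# All per-system quantities are computed column-parallel: one Boltzmann
# matrix of dimension 2^n x n_systems carries every sampled system at once.

#' Configure a random-system ensemble
#'
#' @param topology `"two_component"` (L, A), `"three_component_triangle"`
#'   (L, C, A with all three couplings), or `"k_channel"` (L, C1..Ck, A with
#'   ligand-channel and channel-site couplings and no channel-channel
#'   interactions).
#' @param model_kind `"ising"` (one Normal draw per conformational energy and
#'   per coupling) or `"general"` (one draw per conformational state entry and
#'   per interaction-table cell).
#' @param sigma standard deviation of the energy distribution (1/beta units).
#' @param n_systems number of systems to sample.
#' @param seed RNG seed recorded in the config (used by the run functions).
#' @param k number of channels for the `"k_channel"` topology.
#' @param zero_unbound_ligand for general systems, zero every interaction
#'   entry involving the ligand's unbound (down) state after sampling;
#'   defaults to `TRUE` for general systems (the physical convention).
#' @param include_direct include the direct L-A coupling in channel
#'   topologies (default `TRUE`).
#' @param beta inverse temperature.
#' @return an `ensemble_config` list.
#' @export
ensemble_config <- function(topology = c("two_component",
                                         "three_component_triangle",
                                         "k_channel"),
                            model_kind = c("ising", "general"),
                            sigma = 1, n_systems = 10000L, seed = NULL,
                            k = 2L, zero_unbound_ligand = NULL,
                            include_direct = TRUE, beta = 1) {
  topology <- match.arg(topology)
  model_kind <- match.arg(model_kind)
  if (!is.numeric(sigma) || sigma <= 0) .stopf("sigma must be positive")
  if (n_systems < 1L) .stopf("n_systems must be at least 1")
  if (topology == "k_channel" && k < 1L) .stopf("k must be at least 1")
  if (is.null(zero_unbound_ligand))
    zero_unbound_ligand <- model_kind == "general"
  if (zero_unbound_ligand && model_kind == "ising")
    .stopf("zero_unbound_ligand applies only to general systems")
  structure(list(topology = topology, model_kind = model_kind, sigma = sigma,
                 n_systems = as.integer(n_systems), seed = seed,
                 k = as.integer(k),
                 zero_unbound_ligand = zero_unbound_ligand,
                 include_direct = include_direct, beta = beta),
            class = "ensemble_config")
}

# component names, edge list (index pairs), and special component indices
.ensemble_layout <- function(config) {
  if (config$topology == "two_component") {
    comps <- c("L", "A")
    edges <- list(c(1L, 2L))
    channels <- integer()
  } else if (config$topology == "three_component_triangle") {
    comps <- c("L", "C1", "A")
    channels <- 2L
    edges <- list(c(1L, 2L), c(2L, 3L))
    if (config$include_direct) edges <- c(edges, list(c(1L, 3L)))
  } else {
    comps <- c("L", paste0("C", seq_len(config$k)), "A")
    channels <- 1L + seq_len(config$k)
    site <- length(comps)
    edges <- c(lapply(channels, function(ci) c(1L, ci)),
               lapply(channels, function(ci) c(ci, site)))
    if (config$include_direct) edges <- c(edges, list(c(1L, site)))
  }
  list(comps = comps, edges = edges, ligand = 1L, site = length(comps),
       channels = channels)
}

# parameter layout: row labels in the exact order draws are consumed, plus
# index helpers.  Ising: conf energies then edge couplings.  General: (down,
# up) conformational entries per component, then four table cells per edge in
# the order (dd, du, ud, uu) with the first letter the first component.
.param_layout <- function(config, lay) {
  n <- length(lay$comps)
  enames <- vapply(lay$edges, function(e)
    paste(lay$comps[e[1L]], lay$comps[e[2L]], sep = "."), character(1))
  if (config$model_kind == "ising") {
    labels <- c(paste0("conf_", lay$comps), paste0("int_", enames))
    conf_rows <- seq_len(n)
    edge_rows <- lapply(seq_along(lay$edges), function(e) n + e)
  } else {
    labels <- c(paste0("conf_", rep(lay$comps, each = 2L), c("_down", "_up")),
                paste0("int_", rep(enames, each = 4L),
                       c("_dd", "_du", "_ud", "_uu")))
    conf_rows <- lapply(seq_len(n), function(i) c(2L * i - 1L, 2L * i))
    edge_rows <- lapply(seq_along(lay$edges), function(e)
      2L * n + 4L * (e - 1L) + 1:4)
  }
  list(labels = labels, K = length(labels), conf_rows = conf_rows,
       edge_rows = edge_rows)
}

# rows of the parameter vector zeroed under the physical ligand convention
.zero_rows <- function(config, lay, par) {
  if (!(config$model_kind == "general" && config$zero_unbound_ligand))
    return(integer())
  out <- integer()
  for (e in seq_along(lay$edges)) {
    pr <- lay$edges[[e]]
    rows <- par$edge_rows[[e]]
    if (pr[1L] == lay$ligand) out <- c(out, rows[c(1L, 2L)])  # dd, du
    if (pr[2L] == lay$ligand) out <- c(out, rows[c(1L, 3L)])  # dd, ud
  }
  out
}

# design matrix mapping parameter vectors to per-configuration energies
.design_matrix <- function(config, lay, S) {
  n <- ncol(S)
  if (config$model_kind == "ising") {
    D <- cbind(S, vapply(lay$edges, function(e) S[, e[1L]] * S[, e[2L]],
                         numeric(nrow(S))))
  } else {
    cols <- vector("list", n + length(lay$edges))
    for (i in seq_len(n))
      cols[[i]] <- cbind(S[, i] == -1, S[, i] == 1)
    for (e in seq_along(lay$edges)) {
      i <- lay$edges[[e]][1L]; j <- lay$edges[[e]][2L]
      cols[[n + e]] <- cbind(S[, i] == -1 & S[, j] == -1,
                             S[, i] == -1 & S[, j] == 1,
                             S[, i] == 1 & S[, j] == -1,
                             S[, i] == 1 & S[, j] == 1)
    }
    D <- do.call(cbind, cols)
    storage.mode(D) <- "double"
  }
  D
}

#' Sample one random system from an ensemble configuration
#'
#' Draws every energy parameter independently from Normal(0, sigma) in the
#' same deterministic order as the ensemble runs, so the system returned for a
#' given seed is the first system of the corresponding ensemble.
#'
#' @param config an [ensemble_config()].
#' @param seed optional seed (default: the config's seed).
#' @return an `aim_ising` or `aim_general` system.
#' @export
sample_system <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ensemble_config"))
  if (!is.null(seed)) set.seed(seed)
  lay <- .ensemble_layout(config)
  par <- .param_layout(config, lay)
  theta <- stats::rnorm(par$K, 0, config$sigma)
  theta[.zero_rows(config, lay, par)] <- 0
  .system_from_params(config, lay, par, theta)
}

.system_from_params <- function(config, lay, par, theta) {
  roles <- rep("channel", length(lay$comps))
  roles[lay$ligand] <- "ligand"; roles[lay$site] <- "site"
  names(roles) <- lay$comps
  if (config$model_kind == "ising") {
    cp <- data.frame(i = vapply(lay$edges, function(e) lay$comps[e[1L]], ""),
                     j = vapply(lay$edges, function(e) lay$comps[e[2L]], ""),
                     value = vapply(par$edge_rows, function(r) theta[r],
                                    numeric(1)))
    ising_system(lay$comps, conf_energy = theta[seq_along(lay$comps)],
                 couplings = cp, beta = config$beta, roles = roles)
  } else {
    ct <- t(vapply(par$conf_rows, function(r) theta[r], numeric(2)))
    tabs <- list()
    for (e in seq_along(lay$edges)) {
      v <- theta[par$edge_rows[[e]]]  # dd, du, ud, uu
      tabs[[paste(lay$comps[lay$edges[[e]][1L]],
                  lay$comps[lay$edges[[e]][2L]], sep = ":")]] <-
        matrix(v, 2L, 2L, byrow = TRUE)
    }
    general_system(lay$comps, ct, tabs, beta = config$beta, roles = roles)
  }
}

# column-parallel Boltzmann probabilities for all sampled systems
.ensemble_probs <- function(config, lay, par, theta, S) {
  D <- .design_matrix(config, lay, S)
  LW <- -config$beta * (D %*% theta)
  m <- apply(LW, 2L, max)
  W <- exp(sweep(LW, 2L, m, "-"))
  sweep(W, 2L, colSums(W), "/")
}

# weighted-average conditional odds ratio between components ia and ib given
# the joint states of `meds`; meds = integer() gives the marginal odds ratio.
# Returns per-system values plus a validity flag.
.or_columns <- function(P, S, ia, ib, meds, tiny = 1e-300) {
  M <- ncol(P)
  total <- numeric(M)
  ok <- rep(TRUE, M)
  Gm <- if (length(meds)) .spin_grid(length(meds)) else matrix(0, 1L, 0L)
  for (r in seq_len(nrow(Gm))) {
    mmask <- rep(TRUE, nrow(S))
    for (kk in seq_along(meds))
      mmask <- mmask & S[, meds[kk]] == Gm[r, kk]
    cs <- function(extra) colSums(P[mmask & extra, , drop = FALSE])
    cuu <- cs(S[, ia] == 1 & S[, ib] == 1)
    cud <- cs(S[, ia] == 1 & S[, ib] == -1)
    cdu <- cs(S[, ia] == -1 & S[, ib] == 1)
    cdd <- cs(S[, ia] == -1 & S[, ib] == -1)
    or_r <- (cuu * cdd) / (cud * cdu)
    ok <- ok & is.finite(or_r) & or_r > tiny & cuu > tiny & cud > tiny &
      cdu > tiny & cdd > tiny
    total <- total + if (length(meds)) (cuu + cud + cdu + cdd) * or_r else or_r
  }
  list(value = total, ok = ok)
}

.ensemble_summary <- function(tab, threshold) {
  big <- abs(tab$u_exact) > threshold & abs(tab$u_est) > threshold
  agree <- sign(tab$u_exact[big]) == sign(tab$u_est[big])
  list(threshold = threshold,
       n = nrow(tab),
       correlation = if (nrow(tab) > 1L) stats::cor(tab$u_exact, tab$u_est)
                     else NA_real_,
       n_compared = sum(big),
       sign_agreement = if (any(big)) mean(agree) else NA_real_,
       false_positive = sum(abs(tab$u_exact) <= threshold &
                              abs(tab$u_est) > threshold),
       true_negative = sum(abs(tab$u_exact) > threshold &
                             abs(tab$u_est) <= threshold))
}

#' Exact-versus-estimated effective interaction energies over an ensemble
#'
#' Samples systems from a channel topology, computes the exact ligand-site
#' effective interaction energy by enumeration, and estimates the same
#' quantity from measured direct (fully conditioned) efficacies through the
#' single- or multi-channel Ising closed form.  For general systems the
#' channel conformational energy entering the estimator is
#' `(U_conf(up) - U_conf(down)) / 2`.  Systems with degenerate probability
#' cells are dropped and counted.
#'
#' @param config an [ensemble_config()] with a channel topology.
#' @param seed optional seed overriding the config's.
#' @param threshold |u| cut used for the summary's sign-agreement and
#'   discrepancy counts (default `0.1 / beta`).
#' @return an `ensemble_result`: list with `table` (one row per retained
#'   system: sampled energies, `u_exact`, `u_est`), `dropped`, `summary`, and
#'   `config`.
#' @export
run_estimator_experiment <- function(config, seed = config$seed,
                                     threshold = 0.1 / config$beta) {
  stopifnot(inherits(config, "ensemble_config"))
  if (!config$topology %in% c("three_component_triangle", "k_channel"))
    .stopf("the estimator experiment needs a channel topology")
  if (!is.null(seed)) set.seed(seed)
  lay <- .ensemble_layout(config)
  par <- .param_layout(config, lay)
  M <- config$n_systems
  beta <- config$beta
  theta <- matrix(stats::rnorm(par$K * M, 0, config$sigma), par$K, M)
  theta[.zero_rows(config, lay, par), ] <- 0
  S <- .spin_grid(length(lay$comps))
  P <- .ensemble_probs(config, lay, par, theta, S)

  exact <- .or_columns(P, S, lay$ligand, lay$site, integer())
  direct_la <- .or_columns(P, S, lay$ligand, lay$site, lay$channels)
  ok <- exact$ok & direct_la$ok & direct_la$value > 0
  u_est <- u_eff_from_alpha(pmax(direct_la$value, 1e-300), beta)
  for (ci in lay$channels) {
    rest_l <- setdiff(c(lay$site, lay$channels), ci)
    rest_a <- setdiff(c(lay$ligand, lay$channels), ci)
    a_lc <- .or_columns(P, S, lay$ligand, ci, rest_l)
    a_ca <- .or_columns(P, S, ci, lay$site, rest_a)
    ok <- ok & a_lc$ok & a_ca$ok & a_lc$value > 0 & a_ca$value > 0
    u_lc <- u_eff_from_alpha(pmax(a_lc$value, 1e-300), beta)
    u_ca <- u_eff_from_alpha(pmax(a_ca$value, 1e-300), beta)
    u_conf <- if (config$model_kind == "ising") theta[par$conf_rows[[ci]], ]
              else (theta[par$conf_rows[[ci]][2L], ] -
                      theta[par$conf_rows[[ci]][1L], ]) / 2
    u_est <- u_est - .log_channel_factor(u_lc, u_ca, u_conf, beta) / (4 * beta)
  }
  u_exact <- u_eff_from_alpha(pmax(exact$value, 1e-300), beta)
  ok <- ok & is.finite(u_exact) & is.finite(u_est)

  tab <- as.data.frame(t(theta))
  names(tab) <- par$labels
  tab$u_exact <- u_exact
  tab$u_est <- u_est
  tab <- tab[ok, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, dropped = sum(!ok),
                 summary = .ensemble_summary(tab, threshold),
                 config = config),
            class = "ensemble_result")
}

#' Symmetric uncertainty versus |u_eff| over two-component ensembles
#'
#' Samples two-component systems, computes each system's symmetric
#' uncertainty and absolute effective interaction energy exactly, and
#' summarises the minimum |u_eff| within each decile of symmetric
#' uncertainty.  A nondecreasing decile-minimum profile expresses the lower
#' bound that dependence places on allosteric efficacy.
#'
#' @param config an [ensemble_config()] with `topology = "two_component"`.
#' @param seed optional seed overriding the config's.
#' @return an `ensemble_result` whose `table` has columns for the sampled
#'   energies plus `su` and `u_abs`; `summary$decile_min_u` holds the ten
#'   decile minima.
#' @export
run_su_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ensemble_config"))
  if (config$topology != "two_component")
    .stopf("the symmetric-uncertainty experiment needs the two-component topology")
  if (!is.null(seed)) set.seed(seed)
  lay <- .ensemble_layout(config)
  par <- .param_layout(config, lay)
  M <- config$n_systems
  theta <- matrix(stats::rnorm(par$K * M, 0, config$sigma), par$K, M)
  theta[.zero_rows(config, lay, par), ] <- 0
  S <- .spin_grid(2L)
  P <- .ensemble_probs(config, lay, par, theta, S)

  plogp <- function(x) ifelse(x > 0, x * log(x), 0)
  p1 <- colSums(P[S[, 1L] == 1, , drop = FALSE])
  p2 <- colSums(P[S[, 2L] == 1, , drop = FALSE])
  h1 <- -(plogp(p1) + plogp(1 - p1))
  h2 <- -(plogp(p2) + plogp(1 - p2))
  h12 <- -colSums(plogp(P))
  mi <- pmax(h1 + h2 - h12, 0)
  or_ <- .or_columns(P, S, 1L, 2L, integer())
  ok <- or_$ok & (h1 + h2) > 0
  su <- 2 * mi / (h1 + h2)
  u_abs <- abs(u_eff_from_alpha(pmax(or_$value, 1e-300), config$beta))
  ok <- ok & is.finite(su) & is.finite(u_abs)

  tab <- as.data.frame(t(theta))
  names(tab) <- par$labels
  tab$su <- su
  tab$u_abs <- u_abs
  tab <- tab[ok, , drop = FALSE]
  rownames(tab) <- NULL
  dec <- cut(tab$su,
             breaks = unique(stats::quantile(tab$su, probs = 0:10 / 10)),
             include.lowest = TRUE)
  structure(list(table = tab, dropped = sum(!ok),
                 summary = list(decile_min_u = as.numeric(
                   tapply(tab$u_abs, dec, min))),
                 config = config),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("Ensemble result: %s / %s, sigma = %g, %d systems retained (%d dropped)\n",
              x$config$topology, x$config$model_kind, x$config$sigma,
              nrow(x$table), x$dropped))
  s <- x$summary
  if (!is.null(s$correlation))
    cat(sprintf("  cor(exact, estimate) = %.4f; sign agreement %.4f over %d systems with |u| > %g\n",
                s$correlation, s$sign_agreement, s$n_compared, s$threshold))
  if (!is.null(s$decile_min_u))
    cat("  SU-decile minimum |u_eff|:",
        paste(sprintf("%.3g", s$decile_min_u), collapse = " "), "\n")
  invisible(x)
}

#' Classify estimator discrepancies in an ensemble result
#'
#' Labels each retained system by comparing |exact| and |estimated| effective
#' interaction energies with a threshold: false positives (exact ~ 0 but
#' estimate non-zero), true negatives (exact non-zero but estimate ~ 0), and
#' sign agreement among systems where both exceed the threshold.
#'
#' @param result an `ensemble_result` from [run_estimator_experiment()].
#' @param threshold positive |u| cut (1/beta units).
#' @return list of counts: `false_positive`, `true_negative`, `sign_agree`,
#'   `sign_disagree`, `both_zero`.
#' @export
classify_discrepancies <- function(result, threshold = 0.1) {
  stopifnot(inherits(result, "ensemble_result"))
  if (!is.numeric(threshold) || threshold <= 0)
    .stopf("threshold must be positive")
  tab <- result$table
  if (is.null(tab$u_exact)) .stopf("result does not contain estimator columns")
  ex <- abs(tab$u_exact) > threshold
  es <- abs(tab$u_est) > threshold
  both <- ex & es
  agree <- sign(tab$u_exact[both]) == sign(tab$u_est[both])
  list(false_positive = sum(!ex & es),
       true_negative = sum(ex & !es),
       sign_agree = sum(agree),
       sign_disagree = sum(!agree),
       both_zero = sum(!ex & !es))
}
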