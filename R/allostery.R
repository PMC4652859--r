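# Allosteric efficacies, effective interaction energies, and the closed-form
# channel expressions.
#
# The central quantity is the allosteric efficacy alpha between a ligand L and
# an allosteric site A: the odds ratio of the site's on/off equilibrium with
# the ligand bound versus unbound,
#   alpha = p(L+,A+) p(L-,A-) / [p(L+,A-) p(L-,A+)],
# with p the marginal over every other component.  The effective interaction
# energy is the single Ising coupling that would reproduce that alpha in a
# two-component system: u* = -log(alpha) / (4 beta).

.odds_ratio <- function(cells, context = "marginal") {
  if (any(cells <= 0) || any(!is.finite(cells)))
    .stopf("degenerate %s cell: all four ligand/site probabilities must be positive",
           context)
  unname((cells["uu"] * cells["dd"]) / (cells["ud"] * cells["du"]))
}

#' Effective interaction energy from an allosteric efficacy
#'
#' Inverts the two-component relation `alpha = exp(-4 beta u)`.
#'
#' @param alpha positive allosteric efficacy.
#' @param beta inverse temperature.
#' @return energy in 1/beta units.
#' @export
u_eff_from_alpha <- function(alpha, beta = 1) {
  if (any(alpha <= 0)) .stopf("alpha must be positive")
  -log(alpha) / (4 * beta)
}

#' Allosteric efficacy between a ligand and a site
#'
#' Computes the marginal efficacy `alpha`, its effective interaction energy
#' `u_eff = -log(alpha)/(4 beta)`, and optionally a decomposition into direct
#' and indirect factors with respect to a set of mediating components.
#'
#' @param x an `aim_system` (enumerated internally) or an `aim_dist`.
#' @param ligand,site names of two distinct components.
#' @param decompose optional character vector of mediator components (or
#'   `TRUE` for all remaining components).  When given, the report includes
#'   `alpha_direct` (the mediator-conditioned efficacy), `alpha_indirect =
#'   alpha / alpha_direct`, and, for a single mediator, the per-state
#'   conditional efficacies.
#' @return an object of class `efficacy_report`: a list with `ligand`, `site`,
#'   `alpha`, `u_eff`, `beta`, and optional decomposition fields.
#' @examples
#' sys <- ising_system(c("L", "C", "A"), conf_energy = 0,
#'                     couplings = c("L:C" = -1, "C:A" = -1))
#' allosteric_efficacy(sys, "L", "A", decompose = "C")
#' @export
allosteric_efficacy <- function(x, ligand, site, decompose = NULL) {
  dist <- if (inherits(x, "aim_system")) enumerate_distribution(x) else x
  stopifnot(inherits(dist, "aim_dist"))
  if (identical(ligand, site)) .stopf("ligand and site must differ")
  cells <- .pair_cells(dist, ligand, site)
  alpha <- .odds_ratio(cells)
  rep_ <- list(ligand = ligand, site = site, alpha = alpha,
               u_eff = u_eff_from_alpha(alpha, dist$beta), beta = dist$beta)
  if (!is.null(decompose) && !isFALSE(decompose)) {
    meds <- if (isTRUE(decompose))
      setdiff(component_names(dist), c(ligand, site)) else decompose
    a_dir <- direct_efficacy(dist, ligand, site, meds)
    rep_$mediators <- meds
    rep_$alpha_direct <- a_dir
    rep_$alpha_indirect <- alpha / a_dir
    if (length(meds) == 1L) {
      rep_$conditional <- c(
        down = conditional_efficacy(dist, ligand, site, meds, -1),
        up = conditional_efficacy(dist, ligand, site, meds, 1))
    }
  }
  structure(rep_, class = "efficacy_report")
}

#' @export
print.efficacy_report <- function(x, ...) {
  cat(sprintf("Allosteric efficacy %s -> %s (beta = %g)\n", x$ligand, x$site,
              x$beta))
  cat(sprintf("  alpha  = %.10g\n  u_eff  = %.10g\n", x$alpha, x$u_eff))
  if (!is.null(x$alpha_direct))
    cat(sprintf("  direct = %.10g, indirect = %.10g  (mediators: %s)\n",
                x$alpha_direct, x$alpha_indirect,
                paste(x$mediators, collapse = ", ")))
  invisible(x)
}

#' Conditional allosteric efficacy given one channel state
#'
#' The ligand/site odds ratio evaluated in the sub-ensemble where a mediating
#' channel is fixed in one state.  In an Ising system this equals
#' `exp(-4 beta u_int(L,A))` for either channel state.
#'
#' @param dist an `aim_dist`.
#' @param ligand,site,channel three distinct component names.
#' @param state channel state: -1/+1, "down"/"up", or the channel's labels.
#' @return scalar conditional efficacy.
#' @export
conditional_efficacy <- function(dist, ligand, site, channel, state) {
  stopifnot(inherits(dist, "aim_dist"))
  if (length(unique(c(ligand, site, channel))) != 3L)
    .stopf("ligand, site, and channel must be three distinct components")
  given <- list(state); names(given) <- channel
  mask <- .assignment_mask(dist, given)
  if (sum(dist$p[mask]) <= 0) .stopf("conditioning state has zero probability")
  .odds_ratio(.pair_cells(dist, ligand, site, mask), "conditional")
}

#' Direct (mediator-conditioned) allosteric efficacy
#'
#' The probability-weighted average, over the joint states of the mediators,
#' of the state-conditioned ligand/site odds ratios.  With no mediators this
#' is the plain marginal efficacy.  In Ising systems the value reduces to
#' `exp(-4 beta u_int(L,A))` regardless of the mediators.
#'
#' @param dist an `aim_dist`.
#' @param ligand,site component names.
#' @param mediators character vector of mediating components, disjoint from
#'   ligand and site.
#' @return scalar direct efficacy.
#' @export
direct_efficacy <- function(dist, ligand, site, mediators = character()) {
  stopifnot(inherits(dist, "aim_dist"))
  if (length(intersect(mediators, c(ligand, site))))
    .stopf("mediators must be disjoint from ligand and site")
  if (length(mediators) == 0L)
    return(.odds_ratio(.pair_cells(dist, ligand, site)))
  G <- .spin_grid(length(mediators))
  total <- 0
  for (r in seq_len(nrow(G))) {
    given <- as.list(G[r, ]); names(given) <- mediators
    mask <- .assignment_mask(dist, given)
    w <- sum(dist$p[mask])
    if (w <= 0) next
    total <- total + w * .odds_ratio(.pair_cells(dist, ligand, site, mask),
                                     "conditional")
  }
  total
}

#' Two-component closed form for the allosteric efficacy
#'
#' In the two-component ligand/receptor Ising system the efficacy depends only
#' on the pair coupling: `alpha = exp(-4 beta u_int)`.  Negative interaction
#' energy gives agonism (alpha > 1), positive gives inverse agonism.
#'
#' @param u_int ligand-receptor coupling (1/beta units).
#' @param beta inverse temperature.
#' @return scalar efficacy; vectorised over `u_int`.
#' @export
alpha_two_component <- function(u_int, beta = 1) {
  .check_finite(u_int, "u_int")
  exp(-4 * beta * u_int)
}

#' Specify a single allosteric channel
#'
#' Bundles the three Ising parameters of a mediating channel C between a
#' ligand L and a site A.
#'
#' @param u_conf_c channel conformational energy.
#' @param u_lc ligand-channel coupling.
#' @param u_ca channel-site coupling.
#' @return a `channel_spec` list.
#' @export
channel_spec <- function(u_conf_c = 0, u_lc = 0, u_ca = 0) {
  .check_finite(c(u_conf_c, u_lc, u_ca), "channel energies")
  structure(list(u_conf_c = u_conf_c, u_lc = u_lc, u_ca = u_ca),
            class = "channel_spec")
}

#' Indirect allosteric efficacy through one channel
#'
#' The cosh-ratio factor contributed by a mediating channel:
#' `[cosh(2b(u_lc + u_ca)) + cosh(2b u_conf_c)] /
#'  [cosh(2b(u_lc - u_ca)) + cosh(2b u_conf_c)]`.
#' It equals 1 when either coupling vanishes and tends to 1 as the channel is
#' frozen (`|u_conf_c| -> Inf`); reversing the sign of one coupling inverts
#' it.
#'
#' @param channel a [channel_spec()].
#' @param beta inverse temperature.
#' @return scalar indirect efficacy.
#' @export
alpha_indirect <- function(channel, beta = 1) {
  stopifnot(inherits(channel, "channel_spec"))
  exp(.log_channel_factor(channel$u_lc, channel$u_ca, channel$u_conf_c, beta))
}

#' Three-component closed form for the allosteric efficacy
#'
#' Exact efficacy of the ligand/channel/site Ising triangle:
#' `alpha = exp(-4 beta u_la) * alpha_indirect(channel)`.
#'
#' @param u_la direct ligand-site coupling.
#' @param channel a [channel_spec()].
#' @param beta inverse temperature.
#' @return scalar efficacy.
#' @export
alpha_three_component <- function(u_la, channel, beta = 1) {
  .check_finite(u_la, "u_la")
  exp(-4 * beta * u_la) * alpha_indirect(channel, beta)
}

#' Estimate the efficacy of a channel system from direct efficacies
#'
#' Reconstructs the full ligand/site efficacy of a three-component system from
#' measurable conditional (direct) efficacies: each direct efficacy is
#' converted to an interaction energy via `u = -log(alpha)/(4 beta)` and
#' substituted into the channel closed form.  For non-Ising systems the
#' channel conformational energy is supplied as
#' `(U_conf(C = up) - U_conf(C = down)) / 2`.  The estimate is exact on Ising
#' systems.
#'
#' @param alpha_la_direct,alpha_lc_direct,alpha_ca_direct positive direct
#'   efficacies of the three pairs.
#' @param u_conf_c channel conformational energy (1/beta units).
#' @param beta inverse temperature.
#' @return estimated efficacy alpha(L, A); vectorised over its arguments.
#' @export
estimate_from_direct <- function(alpha_la_direct, alpha_lc_direct,
                                 alpha_ca_direct, u_conf_c, beta = 1) {
  if (any(c(alpha_la_direct, alpha_lc_direct, alpha_ca_direct) <= 0))
    .stopf("direct efficacies must be positive")
  u_lc <- u_eff_from_alpha(alpha_lc_direct, beta)
  u_ca <- u_eff_from_alpha(alpha_ca_direct, beta)
  alpha_la_direct * exp(.log_channel_factor(u_lc, u_ca, u_conf_c, beta))
}

#' Multi-channel efficacy from independent channel contributions
#'
#' For N mutually non-interacting channels the effective interaction energy is
#' additive, `u_eff = u_la + sum_i u_indirect_i`, and the efficacy is the
#' corresponding product `alpha = exp(-4 beta u_eff)`; both are exact for
#' Ising systems.
#'
#' @param u_la direct ligand-site coupling (1/beta units).
#' @param channels list of [channel_spec()] objects.
#' @param beta inverse temperature.
#' @return list with `u_eff` and `alpha`.
#' @export
multichannel_estimate <- function(u_la, channels, beta = 1) {
  .check_finite(u_la, "u_la")
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  u_ind <- vapply(channels, function(ch) {
    stopifnot(inherits(ch, "channel_spec"))
    -.log_channel_factor(ch$u_lc, ch$u_ca, ch$u_conf_c, beta) / (4 * beta)
  }, numeric(1))
  u_eff <- u_la + sum(u_ind)
  list(u_eff = u_eff, alpha = exp(-4 * beta * u_eff))
}

#' Effective end-to-end interaction energy of a serial chain
#'
#' Enumerates a one-dimensional chain of two-state components and converts the
#' end-to-end marginal odds ratio into an effective interaction energy.  For
#' zero conformational energies this obeys the transfer-matrix identity
#' `tanh(-beta u_eff) = prod_i tanh(-beta u_i)`, so the coupling decays
#' exponentially with chain length.
#'
#' @param couplings numeric vector of nearest-neighbour couplings (length
#'   `n - 1` for a chain of `n` components).
#' @param conf_energies optional per-component conformational energies
#'   (default all zero).
#' @param beta inverse temperature.
#' @return scalar effective interaction energy between the chain ends.
#' @export
chain_effective_energy <- function(couplings, conf_energies = NULL, beta = 1) {
  n <- length(couplings) + 1L
  if (n < 2L) .stopf("a chain needs at least one coupling")
  if (is.null(conf_energies)) conf_energies <- rep(0, n)
  if (length(conf_energies) != n)
    .stopf("conf_energies must have length %d", n)
  nm <- paste0("X", seq_len(n))
  cp <- data.frame(i = nm[-n], j = nm[-1L], value = couplings)
  sys <- ising_system(nm, conf_energy = conf_energies, couplings = cp,
                      beta = beta)
  allosteric_efficacy(sys, nm[1L], nm[n])$u_eff
}

#' Exponential decay of allosteric coupling along serial chains
#'
#' Tabulates the end-to-end effective interaction energy of uniform zero-field
#' chains whose links all carry the same conditional allosteric efficacy
#' (converted to a coupling via `u = -log(alpha)/(4 beta)`).
#'
#' @param alpha_per_link per-link conditional efficacy (vectorised).
#' @param lengths chain lengths (component counts >= 2) to evaluate.
#' @param beta inverse temperature.
#' @return data frame with columns `alpha_per_link`, `length`, `u_eff`.
#' @export
chain_decay_profile <- function(alpha_per_link, lengths = 2:12, beta = 1) {
  if (any(alpha_per_link <= 0)) .stopf("alpha_per_link must be positive")
  if (any(lengths < 2L)) .stopf("chain lengths must be at least 2")
  grid <- expand.grid(alpha_per_link = alpha_per_link, length = lengths,
                      KEEP.OUT.ATTRS = FALSE)
  grid$u_eff <- mapply(function(a, n) {
    u <- u_eff_from_alpha(a, beta)
    chain_effective_energy(rep(u, n - 1L), beta = beta)
  }, grid$alpha_per_link, grid$length)
  grid[order(grid$alpha_per_link, grid$length), , drop = FALSE]
}

#' Effective interaction energy of two interacting channels
#'
#' Builds the four-component system L, C1, C2, A in which both channels
#' couple to the allosteric site with magnitude-1 energies (`both_positive`:
#' both negative couplings; `opposite`: C1 negative, C2 positive), the ligand
#' couples to one or both channels with energy `-magnitude`, and the two
#' channels interact with a swept coupling.  The direct L-A coupling and all
#' conformational energies are zero.  Returns the exact `u_eff(L, A)` per
#' swept value.
#'
#' @param kind `"both_positive"` or `"opposite"` channel pair.
#' @param ligand_coupling which channels the ligand engages: `"both"`,
#'   `"one"`/`"positive_only"` (C1, the positive channel), or
#'   `"negative_only"` (C2).
#' @param inter_channel_energies numeric vector of C1-C2 couplings to sweep.
#' @param beta inverse temperature.
#' @param magnitude magnitude of the fixed couplings (default 1).
#' @return data frame with columns `u_inter`, `alpha`, `u_eff`.
#' @export
two_channel_scan <- function(kind = c("both_positive", "opposite"),
                             ligand_coupling = c("both", "one",
                                                 "positive_only",
                                                 "negative_only"),
                             inter_channel_energies = seq(-2, 2, by = 0.25),
                             beta = 1, magnitude = 1) {
  kind <- match.arg(kind)
  ligand_coupling <- match.arg(ligand_coupling)
  .check_finite(inter_channel_energies, "inter-channel energies")
  m <- magnitude
  u_c1a <- -m
  u_c2a <- if (kind == "both_positive") -m else +m
  u_lc1 <- if (ligand_coupling %in% c("both", "one", "positive_only")) -m else 0
  u_lc2 <- if (ligand_coupling %in% c("both", "negative_only")) -m else 0
  out <- data.frame(u_inter = inter_channel_energies, alpha = NA_real_,
                    u_eff = NA_real_)
  for (r in seq_len(nrow(out))) {
    sys <- ising_system(
      c("L", "C1", "C2", "A"), conf_energy = 0,
      couplings = c("L:C1" = u_lc1, "L:C2" = u_lc2, "C1:A" = u_c1a,
                    "C2:A" = u_c2a, "C1:C2" = out$u_inter[r]),
      beta = beta)
    eff <- allosteric_efficacy(sys, "L", "A")
    out$alpha[r] <- eff$alpha
    out$u_eff[r] <- eff$u_eff
  }
  out
}
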