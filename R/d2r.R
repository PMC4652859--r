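# Coarse-grained models of dopamine D2 receptor (D2R) signaling: a monomer
# that activates a G protein, and an asymmetric homodimer in which only
# protomer A binds the G protein while protomer B modulates signaling through
# a repulsive transmembrane interface.
#
# Components of the monomer: a ligand L, the transmembrane domain TM, two
# intracellular regions (IL3 and the merged conserved binding motifs, CBM),
# and a two-part G protein (Gbind, which docks on the receptor, and Gact,
# which activates).  The receptor components prefer their off state
# (u_conf = +1) and every wired pair prefers matched states (u_int = -1);
# the G-protein components carry no intrinsic conformational bias in the
# monomer.  Ligand pharmacology enters through the L-TM coupling: agonist
# -1, neutral antagonist 0, inverse agonist +1.
#
# In the homodimer, protomer B's ligand is treated with the physical
# (bound-state-only) interaction convention: a symmetric Ising ligand with
# zero conformational energy integrates out to a constant and would leave
# the signaling readout exactly unchanged, whereas the physical convention
# correctly shifts TM_B's conformational balance by half the coupling.
# Protomer B's contact with the G protein is state-independent and is
# carried entirely by the Gbind conformational term u_Gbinding^conf
# (default 1); raising it models weaker state-independent binding.

.ligand_coupling <- function(ligand, u_int = -1) {
  switch(ligand,
         agonist = u_int,
         antagonist = 0,
         inverse_agonist = -u_int,
         none = 0,
         .stopf("unknown ligand type '%s'", ligand))
}

#' Describe a D2R homodimer scenario
#'
#' @param ligand_a,ligand_b ligand bound to protomer A / B: `"agonist"`,
#'   `"antagonist"`, `"inverse_agonist"`, or `"none"`.
#' @param perturbation optional [d2r_perturbation()].
#' @param g_binding_conf state-independent G-binding energy carried by the
#'   Gbind component's conformational term (default 1); larger values mean
#'   weaker state-independent binding of the G protein.
#' @return a `d2r_scenario` list.
#' @export
d2r_scenario <- function(ligand_a = "agonist", ligand_b = "antagonist",
                         perturbation = NULL, g_binding_conf = 1) {
  .check_finite(g_binding_conf, "g_binding_conf")
  for (l in c(ligand_a, ligand_b)) .ligand_coupling(l)  # validates
  if (!is.null(perturbation) && !inherits(perturbation, "d2r_perturbation"))
    .stopf("perturbation must come from d2r_perturbation()")
  structure(list(ligand_a = ligand_a, ligand_b = ligand_b,
                 perturbation = perturbation,
                 g_binding_conf = g_binding_conf),
            class = "d2r_scenario")
}

#' Describe a perturbation of an intracellular motif
#'
#' Perturbations model IL3 removal and CBM mutations as either stabilising
#' the target's off state (adding `+delta` to its conformational energy),
#' stabilising its on state (`-delta`), zeroing its conformational coupling
#' to the G-binding component, or (CBM only) reducing the state-independent
#' G binding by raising the Gbind conformational energy by `delta`.
#'
#' @param protomer `"A"` or `"B"`.
#' @param target `"IL3"` or `"CBM"`.
#' @param mode one of `"stabilize_off"`, `"stabilize_on"`,
#'   `"zero_interaction"`, `"reduce_state_independent_binding"`.
#' @param delta perturbation magnitude in the model's energy unit (default 1).
#' @return a `d2r_perturbation` list.
#' @export
d2r_perturbation <- function(protomer = c("A", "B"),
                             target = c("IL3", "CBM"),
                             mode = c("stabilize_off", "stabilize_on",
                                      "zero_interaction",
                                      "reduce_state_independent_binding"),
                             delta = 1) {
  protomer <- match.arg(protomer)
  target <- match.arg(target)
  mode <- match.arg(mode)
  if (mode == "reduce_state_independent_binding" && target != "CBM")
    .stopf("reduce_state_independent_binding applies only to the CBM target")
  if (!is.numeric(delta) || !is.finite(delta) || delta <= 0)
    .stopf("delta must be a positive number")
  structure(list(protomer = protomer, target = target, mode = mode,
                 delta = delta),
            class = "d2r_perturbation")
}

#' Build the D2R monomer model
#'
#' @param ligand ligand type bound to the receptor.
#' @param u_conf conformational energy of the receptor components TM, IL3,
#'   CBM (default +1, preferring the off state).
#' @param u_int coupling on every wired pair (default -1, preferring matched
#'   states).
#' @param beta inverse temperature.
#' @return an `aim_ising` system with components L, TM, IL3, CBM, Gbind,
#'   Gact wired L-TM, TM-IL3, TM-CBM, IL3-Gbind, CBM-Gbind, Gbind-Gact.
#' @examples
#' d2r_efficacy(build_monomer("agonist"))
#' @export
build_monomer <- function(ligand = "agonist", u_conf = 1, u_int = -1,
                          beta = 1) {
  comps <- c("L", "TM", "IL3", "CBM", "Gbind", "Gact")
  ising_system(
    comps,
    conf_energy = c(L = 0, TM = u_conf, IL3 = u_conf, CBM = u_conf,
                    Gbind = 0, Gact = 0),
    couplings = c("L:TM" = .ligand_coupling(ligand, u_int),
                  "TM:IL3" = u_int, "TM:CBM" = u_int,
                  "IL3:Gbind" = u_int, "CBM:Gbind" = u_int,
                  "Gbind:Gact" = u_int),
    beta = beta,
    roles = c(L = "ligand", Gact = "site"),
    down_label = "off", up_label = "on")
}

#' Build the asymmetric D2R homodimer model
#'
#' Protomer A carries the full monomer wiring and the G protein; protomer B
#' (L_B, TM_B, IL3_B, CBM_B) couples to A through a positive (negatively
#' cooperative) TM_A-TM_B interaction.  Protomer B's ligand uses the
#' physical bound-state convention (coupling `u/2` plus `u/2` on TM_B's
#' conformational energy); its G-protein contact is state-independent, so
#' neither IL3_B nor CBM_B has a conformational coupling to Gbind — that
#' contact is the scenario's `g_binding_conf` term on Gbind.
#'
#' @param scenario a [d2r_scenario()].
#' @param u_conf,u_int,beta as in [build_monomer()].
#' @param u_dimer TM_A-TM_B interface coupling (default +1).
#' @return an `aim_ising` system with ten components.
#' @export
build_homodimer <- function(scenario = d2r_scenario(), u_conf = 1,
                            u_int = -1, u_dimer = 1, beta = 1) {
  stopifnot(inherits(scenario, "d2r_scenario"))
  ub <- .ligand_coupling(scenario$ligand_b, u_int)
  comps <- c("L_A", "TM_A", "IL3_A", "CBM_A",
             "L_B", "TM_B", "IL3_B", "CBM_B", "Gbind", "Gact")
  sys <- ising_system(
    comps,
    conf_energy = c(L_A = 0, TM_A = u_conf, IL3_A = u_conf, CBM_A = u_conf,
                    L_B = 0, TM_B = u_conf + ub / 2, IL3_B = u_conf,
                    CBM_B = u_conf, Gbind = scenario$g_binding_conf,
                    Gact = 0),
    couplings = c("L_A:TM_A" = .ligand_coupling(scenario$ligand_a, u_int),
                  "TM_A:IL3_A" = u_int, "TM_A:CBM_A" = u_int,
                  "IL3_A:Gbind" = u_int, "CBM_A:Gbind" = u_int,
                  "Gbind:Gact" = u_int,
                  "TM_A:TM_B" = u_dimer,
                  "L_B:TM_B" = ub / 2,
                  "TM_B:IL3_B" = u_int, "TM_B:CBM_B" = u_int),
    beta = beta,
    roles = c(L_A = "ligand", Gact = "site"),
    down_label = "off", up_label = "on")
  if (!is.null(scenario$perturbation))
    sys <- apply_perturbation(sys, scenario$perturbation)
  sys
}

#' Apply a perturbation to a D2R model
#'
#' Resolves the target component (`IL3`/`CBM` in the monomer,
#' `IL3_A`/`CBM_B`/... in the dimer) and modifies the system:
#' `stabilize_off` adds `+delta` to its conformational energy,
#' `stabilize_on` adds `-delta`, `zero_interaction` removes its coupling to
#' `Gbind` (a no-op for protomer-B motifs, whose G contact is already
#' state-independent), and `reduce_state_independent_binding` adds `+delta`
#' to the Gbind conformational energy.
#'
#' @param system an `aim_ising` D2R model.
#' @param perturbation a [d2r_perturbation()].
#' @return the perturbed `aim_ising` system.
#' @export
apply_perturbation <- function(system, perturbation) {
  stopifnot(inherits(system, "aim_ising"),
            inherits(perturbation, "d2r_perturbation"))
  nm <- component_names(system)
  cand <- paste(perturbation$target, perturbation$protomer, sep = "_")
  target <- if (cand %in% nm) cand
            else if (perturbation$target %in% nm) perturbation$target
            else .stopf("target component '%s' not found in the system", cand)
  d <- perturbation$delta
  switch(perturbation$mode,
         stabilize_off = { system$conf[target] <- system$conf[target] + d },
         stabilize_on = { system$conf[target] <- system$conf[target] - d },
         zero_interaction = {
           if (!"Gbind" %in% nm)
             .stopf("system has no Gbind component to decouple from")
           system$J[target, "Gbind"] <- 0
           system$J["Gbind", target] <- 0
         },
         reduce_state_independent_binding = {
           if (!"Gbind" %in% nm)
             .stopf("system has no Gbind component")
           system$conf["Gbind"] <- system$conf["Gbind"] + d
         })
  system
}

#' Ligand-to-activation efficacy of a D2R model
#'
#' @param system a monomer or homodimer `aim_ising` system.
#' @param readout readout component: `"Gact"` (G-protein activation, the
#'   default) or `"Gbind"` (G-protein engagement).  Note that the odds-ratio
#'   efficacy is exactly invariant to the readout component's own
#'   conformational energy, so the `g_binding_conf` term is only visible
#'   through the `"Gact"` readout.
#' @return an `efficacy_report` between the protomer-A ligand and the
#'   readout component.
#' @export
d2r_efficacy <- function(system, readout = c("Gact", "Gbind")) {
  readout <- match.arg(readout)
  lig <- if ("L_A" %in% component_names(system)) "L_A" else "L"
  allosteric_efficacy(system, lig, readout)
}

#' Evaluate the monomer and homodimer scenario panels
#'
#' The monomer panel covers the three ligand classes plus the IL3/CBM
#' perturbations (G-decoupling and off-state stabilisation, with an agonist
#' bound).  The dimer panel covers an agonist in protomer A combined with
#' each ligand class in protomer B, the protomer-B motif perturbations, the
#' reduced state-independent binding scenario, and off-state stabilisation
#' in protomer A.
#'
#' @param readout passed to [d2r_efficacy()].
#' @param beta inverse temperature.
#' @return data frame with columns `panel`, `scenario`, `ligand_a`,
#'   `ligand_b`, `alpha`, `u_eff`.
#' @export
run_scenarios <- function(readout = "Gact", beta = 1) {
  rows <- list()
  add <- function(panel, scenario, system, ligand_a, ligand_b = NA_character_) {
    eff <- d2r_efficacy(system, readout)
    rows[[length(rows) + 1L]] <<- data.frame(
      panel = panel, scenario = scenario, ligand_a = ligand_a,
      ligand_b = ligand_b, alpha = eff$alpha, u_eff = eff$u_eff,
      stringsAsFactors = FALSE)
  }
  for (lig in c("agonist", "antagonist", "inverse_agonist"))
    add("monomer", lig, build_monomer(lig, beta = beta), lig)
  for (tgt in c("IL3", "CBM")) {
    add("monomer", paste0(tgt, "_decoupled"),
        apply_perturbation(build_monomer("agonist", beta = beta),
                           d2r_perturbation("A", tgt, "zero_interaction")),
        "agonist")
    add("monomer", paste0(tgt, "_stabilized_off"),
        apply_perturbation(build_monomer("agonist", beta = beta),
                           d2r_perturbation("A", tgt, "stabilize_off")),
        "agonist")
  }
  for (ligb in c("agonist", "antagonist", "inverse_agonist"))
    add("dimer", paste0("B_", ligb),
        build_homodimer(d2r_scenario("agonist", ligb), beta = beta),
        "agonist", ligb)
  perts <- list(
    A_IL3_stabilized_off = d2r_perturbation("A", "IL3", "stabilize_off"),
    A_CBM_stabilized_off = d2r_perturbation("A", "CBM", "stabilize_off"),
    B_IL3_stabilized_off = d2r_perturbation("B", "IL3", "stabilize_off"),
    B_IL3_decoupled = d2r_perturbation("B", "IL3", "zero_interaction"),
    B_CBM_stabilized_off = d2r_perturbation("B", "CBM", "stabilize_off"),
    B_CBM_reduced_binding = d2r_perturbation(
      "B", "CBM", "reduce_state_independent_binding"))
  for (nmp in names(perts))
    add("dimer", nmp,
        build_homodimer(d2r_scenario("agonist", "antagonist",
                                     perturbation = perts[[nmp]]),
                        beta = beta),
        "agonist", "antagonist")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
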