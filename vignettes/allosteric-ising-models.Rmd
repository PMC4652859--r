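---
title: "Allosteric Ising models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allosteric Ising models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aim)
```

## The model

An allosteric Ising model represents a biomolecular system as a small network
of coarse-grained structural components — a helix, a loop, a binding site, a
ligand — each of which occupies one of two states.  The down state (spin
$s = -1$) is the off/unbound state, the up state ($s = +1$) is on/bound; this
mapping is fixed package-wide.  A configuration $X$ of $n$ components has
potential energy

$$U(X) = \sum_i u_i^{\mathrm{conf}} s_i + \sum_{i<j} u_{ij}^{\mathrm{int}} s_i s_j,$$

with conformational energies $u^{\mathrm{conf}}$ (a positive value prefers
the off state) and pairwise couplings $u^{\mathrm{int}}$ (a negative value
prefers matched states).  All energies are stored in units of $1/\beta$ and
$\beta$ defaults to 1, so the numbers in a model file are directly thermal.
Configuration probabilities follow the Boltzmann distribution
$p(X) = e^{-\beta U(X)}/Z$, which the package computes *exactly* by
enumerating all $2^n$ states — there is no sampling error anywhere in the
package.

The Ising form imposes two symmetries: the two states of a component have
opposite conformational energy, and the four cells of a pair's interaction
table are $\pm u^{\mathrm{int}}$.  `general_system()` lifts both
restrictions (independent per-state energies and full $2\times 2$ tables);
`ising_to_general()` embeds an Ising model in that superset, and
`zero_unbound_ligand()` applies the physical ligand convention in which a
ligand interacts only while bound.  `ligandize()` maps a physical ligand
back into Ising form: writing the bound-only pair term
$u\,\frac{s_L+1}{2}s_R$ as $\frac{u}{2}s_R + \frac{u}{2}s_L s_R$ shows the
physical system equals an Ising system whose neighbour gains half the
coupling as a conformational offset.

## Allosteric efficacy and effective interaction energy

The allosteric efficacy between a ligand $L$ and a site $A$ is the odds
ratio

$$\alpha_{L,A} = \frac{p(L\!\uparrow, A\!\uparrow)\,p(L\!\downarrow, A\!\downarrow)}
                      {p(L\!\uparrow, A\!\downarrow)\,p(L\!\downarrow, A\!\uparrow)},$$

computed from the marginal over every other component: $\alpha > 1$ is
agonism, $\alpha < 1$ inverse agonism, $\alpha = 1$ neutral antagonism.  In
the two-component system $\alpha = e^{-4\beta u^{\mathrm{int}}}$ exactly, and
the package defines the *effective interaction energy* of any pair in any
system by inverting that relation, $u^* = -\ln\alpha/(4\beta)$: the single
Ising coupling that would reproduce the observed efficacy.  Two useful exact
invariances follow from the odds-ratio form: $\alpha$ is independent of the
conformational energies of the two components it connects (only the network
*between* them matters), and uncoupled bystander sites leave it unchanged.

A mediating channel $C$ with parameters $(u_C^{\mathrm{conf}}, u_{LC},
u_{CA})$ contributes a closed-form factor

$$\alpha^{\mathrm{ind}} =
 \frac{\cosh(2\beta(u_{LC}+u_{CA})) + \cosh(2\beta u_C^{\mathrm{conf}})}
      {\cosh(2\beta(u_{LC}-u_{CA})) + \cosh(2\beta u_C^{\mathrm{conf}})},$$

so that $\alpha_{L,A} = e^{-4\beta u_{LA}}\,\alpha^{\mathrm{ind}}$ for the
three-component triangle (`alpha_three_component()`).  The factor tends to 1
as the channel freezes ($|u_C^{\mathrm{conf}}| \to \infty$) and inverts
under a sign flip of either coupling — reversing an allosteric signal.
`allosteric_efficacy(..., decompose =)` splits any efficacy into the
mediator-conditioned *direct* part (`direct_efficacy()`, the
probability-weighted conditional odds ratio) and the *indirect* remainder.

For $N$ mutually non-interacting channels the effective energies add,
$u^*_{L,A} = u_{LA} + \sum_i u^{\mathrm{ind}}_i$, hence the efficacies
multiply (`multichannel_estimate()`).  Although the additive form is usually
quoted for channels without a direct ligand–site term, decimating each
channel spin is an exact renormalisation for arbitrary $u_{LA}$, and the
test suite verifies additivity by enumeration with nonzero direct couplings.

Serial channels behave oppositely: for a zero-field chain the end-to-end
coupling obeys the transfer-matrix identity
$\tanh(-\beta u^*) = \prod_i \tanh(-\beta u_i)$, so coupling decays
exponentially with length (`chain_effective_energy()`,
`chain_decay_profile()`).  `two_channel_scan()` explores the remaining
regime — channels that interact with each other — including the exact
antisymmetric cancellation: two channels of equal magnitude and opposite
sign engaged equally by the ligand transmit nothing at *any*
channel–channel coupling, because flipping the site spin while exchanging
the channels is a symmetry of the system.

## Information-theoretic measures

`entropy()`, `mutual_information()` and `symmetric_uncertainty()` are
computed from the same exact distributions (no trajectory estimation).
Entropies are in nats internally; the base is a parameter wherever raw
entropies are reported, and the symmetric uncertainty
$SU = 2I/(H_i + H_j)$ is base-invariant by construction.  Mutual
information values within $10^{-12}$ below zero are clipped to zero;
anything larger is a genuine error and is not masked.

## The estimator experiments

The Ising closed forms remain useful as *estimators* for systems that break
the Ising symmetries.  `run_estimator_experiment()` samples every
conformational-state entry and interaction-table cell of a general system
independently from $\mathcal{N}(0, \sigma)$ — the maximally non-Ising
convention — zeroes the unbound-ligand cells (the physical convention), and
compares the exact enumerated $u^*_{L,A}$ with the value reconstructed from
measurable direct efficacies via the channel formulas, mapping a general
channel's conformational term through
$u_C^{\mathrm{conf}} \approx (U^{\mathrm{conf}}(C\!\uparrow) -
U^{\mathrm{conf}}(C\!\downarrow))/2$.  On Ising inputs the estimator is
exact to enumeration precision, which every run can use as an internal
control.  On general inputs at $\sigma = 1/\beta$ the agreement is tight
(correlation above 0.99 in the triangle topology); at $\sigma = 3/\beta$
and $5/\beta$ two discrepancy groups appear — false positives (true
$u^* \approx 0$, estimate non-zero) and true negatives (the reverse) —
while the *sign* of the modulation remains conserved where both values are
appreciable.  `classify_discrepancies()` counts these groups at a threshold
of $0.1/\beta$ by default; sign agreement is scored only where both
magnitudes exceed the threshold, since sign is meaningless at zero.

`run_su_experiment()` relates dependence to allosteric strength in
two-component ensembles: within each decile of symmetric uncertainty it
records the minimum $|u^*|$, and the nondecreasing decile-minimum profile
expresses the lower bound that mutual information places on allosteric
efficacy.

Ensemble defaults are part of the study conditions: energies are
$\mathcal{N}(0, \sigma)$ with $\sigma = 1/\beta$ unless stated, and the
default ensemble size is 10,000 systems — all per-system quantities are
computed column-parallel from one $2^n \times M$ Boltzmann matrix, so this
resolves the distributional patterns in a few seconds; larger ensembles are
one `n_systems =` away.  Degenerate draws (any required probability cell
below $10^{-300}$) are dropped and counted, never silently resampled, and a
fixed seed reproduces an ensemble bit-exactly.  What the generator does
*not* emulate is as important as what it does: real proteins have
correlated, structured energy terms, more than two states per element, and
kinetics; passing ensembles show that the closed forms degrade gracefully
under symmetry breaking, not that any particular protein is two-state.

## The D2R monomer and homodimer

The case study models asymmetric signaling in the dopamine D2 receptor
homodimer.  The monomer wires a ligand to a transmembrane domain, the
transmembrane domain to two intracellular motifs (IL3 and the merged
conserved binding motifs, CBM), both motifs to a G-protein binding
component, and that component to a G-protein activation component.
Receptor components prefer their off state ($u^{\mathrm{conf}} = +1$),
every wired pair prefers matched states ($u^{\mathrm{int}} = -1$), and
ligand classes set the ligand–TM coupling to $-1$ (agonist), $0$
(antagonist) or $+1$ (inverse agonist).  The G-protein components carry no
intrinsic conformational bias in the monomer: the off-state preference is a
property of the receptor protomer, and giving the G components the same
bias over-damps the network to the point where *removing* a signaling
contact raises the efficacy (see below).  The readout is
$\alpha(L, \mathrm{Gact})$; with these choices the monomer reproduces the
agonist/antagonist/inverse-agonist ordering, the exact reciprocal
$\alpha_{\mathrm{inverse}} = 1/\alpha_{\mathrm{agonist}}$, and reduced
signaling under either decoupling or off-state stabilisation of IL3 or the
CBMs.

Three design points in the homodimer deserve explanation:

* **Protomer B's ligand is physical, not symmetric.**  A symmetric Ising
  ligand with zero conformational energy integrates out of the partition
  function as a constant ($\sum_s e^{-\beta u s s'} = 2\cosh\beta u$ for
  either neighbour state), so it cannot modulate anything.  Protomer B's
  ligand therefore uses the bound-only convention, contributing $u/2$ as a
  coupling and $u/2$ to TM\_B's conformational energy.  An agonist in B then
  stabilises TM\_B's on state, which the repulsive ($+1$) TM–TM interface
  converts into suppression of protomer A — the observed negative
  cooperativity.  Protomer A's ligand keeps the symmetric convention, whose
  bound/unbound contrast is exactly what its efficacy readout measures.
* **Protomer B binds the G protein state-independently.**  Neither IL3\_B
  nor CBM\_B has a conformational coupling to Gbind; the B–G contact is the
  `g_binding_conf` term on Gbind (default 1), and the CBM\_B mutation is
  modelled as weakening that binding (raising the term to 2), which
  suppresses activation.  This also makes decoupling IL3\_B an exact no-op,
  matching the experimental null effect, while *off-state stabilisation* of
  either B motif (the rejected perturbation model) spuriously increases
  activation through the dimer interface.
* **The readout must be Gact.**  A conformational term on the readout
  component itself multiplies whole odds-ratio cells and cancels exactly,
  so $\alpha(L_A, \mathrm{Gbind})$ is provably blind to `g_binding_conf`;
  only the activation readout sees the state-independent binding mechanism.
  The ligand orderings themselves are readout-independent.

One model observation worth knowing: in the dimer, where Gbind carries the
$+1$ state-independent term, *decoupling* IL3\_A or CBM\_A raises
$\alpha(L_A, \mathrm{Gact})$ by about 2% rather than lowering it.  A coupled
motif with an off-state preference both transmits signal and loads an
off-bias onto the G interface; when the interface is already biased, the
relief from removing the load slightly outweighs the lost parallel channel.
Off-state stabilisation of the protomer-A motifs suppresses signaling in
both the monomer and the dimer, and decoupling suppresses it in the
monomer, where the G interface is unloaded.  Protomer B's H8 helix is
folded into its CBM component rather than modelled separately.

## Numerical choices and limitations

* Enumeration accumulates Boltzmann weights in the log domain; energies of
  several hundred $1/\beta$ units produce finite probabilities, and the
  $\cosh$ ratios are evaluated through `log(cosh)` so channel formulas do
  not overflow for strong couplings.
* Exact enumeration is capped at 22 components ($\approx 4$M states) by
  default; every built-in system has $n \le 10$.  The cap is an argument,
  not a constant.
* A zero cell in an odds ratio (a deterministic component) raises an error
  naming the degenerate quantity; nothing is clamped, because clamping
  would silently distort the ensemble experiments.
* The package models K-type allostery at equilibrium only: no kinetics, no
  binding-affinity titration, no V-type (catalytic-rate) modulation, and
  strictly two states per component.  Systems needing more states or
  continuous coordinates are outside its scope by construction.
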