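---
title: "Models and methods behind pkmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pkmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkmech)
```

pkmech implements the analysis chain used to characterise the
K⁺-independent pyruvate kinase of *Thermofilum pendens*: setting assay
conditions by speciation, fitting bisubstrate and inhibition rate laws,
reading the kinetic mechanism off the fitted patterns, and profiling the
structural interactions proposed to explain the enzyme's behaviour. This
vignette documents the models, their assumptions, the tunable parameters,
and the design choices made where the methodology was genuinely open.

## Speciation and assay conditions

Velocities are measured against the *active* ligand species, not analytical
totals: the substrates are the PEP trianion and the ADP–metal complex, and
the free divalent cation is controlled separately. Two computations set the
conditions:

* **1:1 binding equilibrium.** For totals $M_t$, $L_t$ and dissociation
  constant $K_d$, the complex concentration is the physical root of
  $c^2 - c(M_t + L_t + K_d) + M_t L_t = 0$, evaluated as
  $c = 2 M_t L_t / (S + \sqrt{S^2 - 4 M_t L_t})$ with $S = M_t + L_t + K_d$.
  This form avoids the catastrophic cancellation of the textbook quadratic
  formula when $K_d \ll M_t, L_t$ — relevant here because conditions span
  0.02–30 mM against $K_d$ values of tens to hundreds of micromolar.
  `totals_for_design()` inverts the computation, since designs fix the
  *free* metal (30 mM) and the *complex* at chosen levels. Only the 1:1
  equilibrium is modelled; competing equilibria (ADP protonation, other
  ligands, ionic-strength corrections) are out of scope, which is the main
  difference from a full speciation program.
* **Dissociation constants are configuration, not constants.** The Kd of
  ADP-Mg and ADP-Mn are medium-dependent and were not reported with the
  original characterisation. `kd_defaults()` documents literature values
  (0.25 mM for ADP-Mg, 0.045 mM for ADP-Mn, from stability constants near
  neutral pH); they are deliberate assumptions and every function takes the
  Kd explicitly.
* **Ionized PEP** is the Henderson–Hasselbalch fraction
  $\mathrm{PEP}^{3-} = \mathrm{PEP}_t / (1 + 10^{pK - pH})$ with pK 6.3, so
  at the assay pH of 6.0 only about a third of total PEP is active.

## Rate laws

All concentrations are millimolar internally; specificity constants are
converted to M⁻¹s⁻¹ only at reporting.

* Rapid-equilibrium random order:
  $v = V A B / (K_a K_b + K_a B + K_b A + A B)$. The denominator factorises
  as $(K_a + A)(K_b + B)$, which yields the diagnostic property used
  throughout: all double-reciprocal lines at fixed co-substrate share the
  point $(-1/K_a, 0)$ — the pattern intersects *on* the 1/S axis.
* Hill: $v = V S^n /(K_{0.5}^n + S^n)$. The denominator grouping is the
  only reading consistent with saturation; $n = 1$ reduces exactly to
  Michaelis–Menten.
* Dead-end inhibition: competitive
  $v = V S /(K_m(1 + I/K_i) + S)$; noncompetitive/mixed
  $v = V S /(K_m(1 + I/K_i) + S(1 + I/(\alpha K_i)))$ with $\alpha = 1$
  for noncompetitive; uncompetitive (slope unaffected) is included to
  complete Cleland's pattern set even though the enzyme itself shows no
  uncompetitive pattern.
* Catalytic constants: $k_{cat}$ converts a specific activity
  (µmol·min⁻¹·mg⁻¹) through the molar mass of the catalytic unit. The
  published turnover number of this enzyme (626 s⁻¹ from
  183 µmol·min⁻¹·mg⁻¹) is reproduced by the *tetramer* basis
  (4 × 51,340 Da); the per-monomer value would be ≈157 s⁻¹. Because the
  reporting basis is a convention, `n_subunits` is an explicit argument
  with tetramer default.

The simplified ordered
($v = VAB/(K_{ia}K_b + K_b A + K_a B + AB)$) and ping-pong
($v = VAB/(K_a B + K_b A + AB)$) laws exist only as generators for the
mechanism classifier's oracles, not as a general steady-state engine.

## Global fitting

`fit_global()` minimises least squares on untransformed velocities with
bounded Levenberg–Marquardt, restarted from 8 points (a data-driven
heuristic plus seeded log-uniform draws over the bounds) because the Hill
and mixed-inhibition surfaces are multimodal at small n. Defaults:

* **Loss**: unweighted least squares on $v$ (no weighting was specified in
  the original fits); `weights = "relative"` divides residuals by the
  observed velocity, appropriate when the error is a constant fraction of
  the signal, as is typical for coupled-assay velocities.
* **Standard errors** come from the Gauss–Newton approximation (central
  finite-difference Jacobian at the optimum).
* **Model comparison** uses AICc computed from the *weighted* residual sum
  of squares — the same objective the fit minimised. Among inhibition
  kinds, candidates within 2 AICc units of the minimum form an ambiguity
  band, within which the most parsimonious model wins; without this
  parsimony rule a nested pair (competitive ⊂ mixed) would be resolved in
  favour of the larger model in roughly the χ²₁ > 2 tail (≈15% of
  datasets), which no information criterion avoids. Ties among
  equally-sized candidates are reported as `ambiguous`, never silently
  resolved.
* **Identifiability** is checked before fitting (two distinct levels of
  both substrates for the bisubstrate law, non-degenerate inhibitor
  columns), so degenerate designs fail loudly rather than returning a
  boundary solution.

Convergence requires the optimizer's own criteria; non-convergence is
carried in the result, never dropped.

## Pattern classification and the mechanism decision table

The intersection family of a double-reciprocal pattern is what Cleland's
diagnostics read, and the original analysis judged it visually. pkmech
makes the judgement statistical:

* Regressions in reciprocal space are weighted by $v^2$: if velocity error
  is a constant fraction of $v$, the standard deviation of $1/v$ is
  proportional to $1/v$, and unweighted Lineweaver–Burk fits are dominated
  by the lowest velocities. Without this weighting the classifier's error
  rates were an order of magnitude worse in simulation.
* **Parallel** is the failure to reject a common-slope model against
  per-series slopes (F-test, `parallel_alpha = 0.01`).
* **Common intersection** is fitted directly as a pencil of lines
  $1/v = y_0 + m_k(1/S - x_0)$; **on the 1/S axis** is the failure to
  reject $y_0 = 0$ (F-test, `axis_alpha = 0.05`); otherwise the sign of
  $y_0$ gives left-above or left-below. A lack-of-fit test of the pencil
  against unconstrained lines (`ambiguity_alpha = 1e-3`) downgrades
  dispersed patterns to `ambiguous` rather than forcing a family.
* On noiseless data the tests are degenerate, and deterministic tolerances
  take over: relative slope spread below 10⁻⁶ is parallel, and $|y_0|$
  below 5% of the smallest fitted 1/v intercept (`axis_tol`) is on-axis.

Under the study conditions (published five-by-five concentration designs,
5% relative noise), simulated recall is ≥ 92% for all three families with
single measurements and higher with replicates. Parameter estimates are
never taken from reciprocal space; lines are fitted there only for
classification and display.

`classify_inhibition()` combines the model-selection verdict with the
classical replots (slopes and intercepts of per-inhibitor-level reciprocal
lines regressed on [I], t-tests at 0.05): slope effect only = C, intercept
only = UC, both = NC or MT by the α evidence (α̂ ± 2 SE from the mixed
fit). A flat inhibitor yields a no-inhibition call rather than UC.
Disagreement between replots and model selection keeps the model-selection
kind and flags the call inconsistent.

`infer_mechanism()` is a decision table: parallel ⇒ ping-pong; an analog of
one substrate uncompetitive against the other ⇒ ordered (the
uncompetitively-inhibited substrate binds first); an intersecting pattern
with every analog competitive against its own substrate and
noncompetitive/mixed against the co-substrate ⇒ rapid-equilibrium random.
An intersecting pattern *alone* is deliberately ambiguous — initial
velocities cannot separate ordered steady state from random rapid
equilibrium, so the classifier requires dead-end evidence before asserting
random order.

## Structural interaction geometry

* **π–π pairs**: ring centroids are mass centres of the ring atoms;
  ring planes are least-squares fits (for ideal rings this is the exact
  plane); the angle is the acute angle between plane normals (0° stacked,
  90° edge-to-face); pairs are reported within a 7 Å centroid cutoff.
* **Salt bridges**: basic nitrogens (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2)
  against carboxylate oxygens (Asp OD1/OD2, Glu OE1/OE2, C-terminal OXT)
  within 4.0 Å, one record per residue pair at the minimum atom distance.
* **Hydrogen bonds**: heavy-atom N/O/S pairs within 3.4 Å; crystal
  structures carry no hydrogens, so no donor/acceptor orientation is
  imposed; same-residue pairs and sequence-adjacent backbone pairs
  (covalently connected through the peptide bond) are excluded.
* **Interface contacts** follow the LigPlot/Dimplot convention: between
  the published A/B domain definitions (TpPK B 66–164; PaPK B 81–177;
  RMPK B 116–223; `pk_domains()`), a contact is Polar when both atoms are
  N/O within 3.35 Å and Hydrophobic when at least one atom is carbon
  within 3.90 Å. The tool behind the published tables does not document
  its thresholds, so both are flags. Hinge regions can be excluded via
  `exclude` (hinge determination itself is out of scope).
* Chains are analysed separately by default; for multi-copy crystals where
  the analysed chain is unstated, contacts can be collected per chain and
  the best-matching distance taken, which avoids guessing a chain.

All geometry is invariant under rigid rotation and translation, which the
test suite fuzzes explicitly.

## Native contacts

`native_contact_map()` takes all Cα pairs within 8 Å at sequence
separation ≥ 3 (Carma-style defaults, all exposed as arguments since no
criterion was published), and `q_trajectory()` scores per frame the
fraction of native pairs within 1.2× their native distance. Q ≈ 0.7 is the
conventional boundary of the native basin. Trajectory input is multi-MODEL
PDB or a plain xyz table; simulation engines are out of scope, so the
package evaluates trajectories but never produces physical ones.

## Alignment profiles

`column_profile()` maps reference-numbered positions through the reference
sequence's own gaps by counting non-gap characters, then tabulates residue
frequencies (including gaps) across all sequences — exactly the numbers a
sequence-logo stack draws. `covariation()` computes, among sequences
matching an anchor residue, the fraction satisfying joint partner
constraints (the statistic behind statements like "covariant in 77% of the
sequences that contain Lys117"). The published conservation percentages
depend on a 426-sequence alignment that was not deposited, so only the
computation — not those percentages — is testable.

## Synthetic data: what it emulates and what it does not

The generators define the study conditions under which the pipeline is
validated:

* `make_velocity_dataset()` evaluates a rate law on the published
  concentration designs (`design_initial_velocity()`,
  `design_inhibition()`) and adds seeded Gaussian noise, default 5%
  relative, matching the visual scatter of the published initial-velocity
  plots (no error model was stated). Velocities are truncated at zero, a
  small upward bias source at very low signal. The varied-substrate level
  sets of the bisubstrate design are published for one panel each; the
  design being symmetric, each panel's fixed-level set serves as the other
  panel's varied grid. Where replication matters (bias studies, the
  end-to-end scenario) five replicates per point are generated, mirroring
  velocities reported as means of five experiments.
* `make_fixture_structure()` places idealised groups (regular-hexagon Phe
  rings with 1.39 Å bonds, salt-bridge and H-bond pairs at prescribed
  distances, Cα chains) so every geometric assertion has an analytic
  expected value.
* `make_trajectory()` breaks a prescribed fraction of native contacts per
  frame in a seeded, nested order; on references whose contacts form a
  perfect matching the recovered Q equals 1 − schedule exactly.
* `make_alignment()` realises planted column frequencies by exact
  largest-remainder allocation plus a seeded shuffle, so specified
  compositions hold as closely as n allows.

What passing these tests shows is that the *computations* are correct under
their assumed error structure; real data add correlated errors, model
misspecification, imperfect speciation constants and crystallographic
idiosyncrasies (altlocs, missing density) that the generators deliberately
do not emulate.

## Numerical choices and problem sizes

Optimiser tolerances are 10⁻¹⁴ (ftol/ptol) so noiseless recovery is exact
to well below reporting precision; ties in altloc resolution go to 'A';
residue numbering is the author numbering of the PDB file, 1-based and
inclusive. The simulation studies shipped with the package use 200–500
seeded replicates per condition and five-by-five designs — sizes chosen so
the full suite documents estimator bias (< 2% mean relative) and classifier
recall (≥ 90%) with comfortable Monte-Carlo margins while remaining quick
to run on a laptop.

## Known limitations

* Speciation is strictly 1:1; no ionic-strength or multi-equilibrium
  corrections.
* The inhibition classifier's α evidence relies on the Gauss–Newton
  standard error of α̂, which is optimistic for strongly curved surfaces;
  a bootstrap flag exists on the fitting layer for when it matters.
* The crystal-structure comparisons against published interaction tables
  require the PDB entries 3QTG and 2G50, which are not redistributed with
  the package; without them those checks report an unmet data requirement.
* Ordered-mechanism detection from the pattern alone requires
  $K_{ia} \ne K_a$; the degenerate ordered case is indistinguishable from
  random rapid equilibrium in initial velocities, which is a property of
  the kinetics, not of the implementation.
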