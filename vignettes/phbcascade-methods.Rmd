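---
title: "Stoichiometric and kinetic analysis of the maltodextrin-to-PHB cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric and kinetic analysis of the maltodextrin-to-PHB cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phbcascade)
```

## The system

`phbcascade` models a cell-free, ATP-free enzymatic cascade that converts
starch-derived maltodextrin into poly-3-hydroxybutyrate (PHB) through
acetyl-CoA. Nineteen reactions carry the chemistry: phosphorolysis of
maltodextrin glucose units by alpha-glucan phosphorylase (aGP) into G1P,
isomerization to G6P, an oxidative branch (G6PDH, 6PGDH) that supplies the
NADPH the downstream reductase needs while releasing CO2, a pentose/hexose
carbon-rearrangement module (RPE, RPI, TK1, TK2, TAL, TIM, ALD, FBP), the
bifunctional phosphoketolase (XPK on Xu5P, FPK on F6P) that cleaves sugar
phosphates into acetyl phosphate, and the PTA-PhaA-PhaB-PhaC cascade that
converts acetyl phosphate to PHB monomer units. The architecture is
self-balancing: NADP(H), CoA and phosphate cycle internally, which is the
property that removes any need for an external energy or redox input.

Two conventions shape the model. Maltodextrin is a *boundary pool of glucose
units* (mM glucose equivalent): chain-length dynamics are not modelled, and
aGP is written `MD + Pi -> G1P`. PHB is a *boundary pool of monomer units*
(mM monomer equivalent, C4H6O2): `PhaC: 3HB-CoA -> PHB + CoA`. All titers
and yields are in these equivalents.

Element accounting covers C, H, O and P plus opaque moiety tokens for the
CoA and NADP cores (their transferable parts carry explicit C/H/O counts).
A boundary H+ species absorbs the protons released by the two
dehydrogenases and consumed by the reductase, so every one of the 19
reactions balances exactly in all four elements; `atom_balance_check()`
verifies this and localizes any editing mistake to a reaction and element.

## Exact elementary-mode analysis

The stoichiometric questions -- what is the theoretical yield, which
coefficients does each enzyme carry, are the cofactor cycles closed -- are
answered by elementary flux modes (EFMs) of the internal stoichiometric
matrix. `elementary_modes()` implements the double-description (tableau)
method over a cone with reversible reactions split into half-reactions, in
exact integer/rational arithmetic: every returned mode satisfies
`S_internal %*% v == 0` *identically*, not merely to floating-point
tolerance, and printed coefficients such as the signed -2 on the TK2
reaction are exact. Candidate rays are accepted by the standard
minimal-support adjacency test, a final strict support filter guards
elementarity, and modes are ordered lexicographically by support so results
are bit-reproducible. A brute-force oracle (enumeration of all support
subsets with one-dimensional sign-feasible nullspaces) cross-checks the
enumeration on every toy network in the test suite.

On the intact network the two productive routes are obtained under the two
phosphoketolase restrictions (`xpk_only`, `fpk_only`), mirroring the two
extreme activities of the bifunctional enzyme. Normalized to `aGP = 3`,
both give the overall equation

3 glucose units -> 4 PHB + 2 CO2 + 3 H2O,

hence a theoretical molar yield of 400/3 = 133.3% and a carbon conversion
efficiency of 800/9 = 88.9% (exactly 2/3 of the molar yield, since PHB
carries 4 of the 6 carbons). Display values round half-up to one decimal;
exact rationals are retained internally and exposed as numerator strings.

### Essential-pathway variants and boundary choices

The truncated "essential" variants omit the rearrangement module. That
leaves dead-end pools, and the original description does not state how they
were closed, so the builders make the choice explicit:

* `xpk_essential` (PGI and the rearrangement module removed): G3P is a
  boundary byproduct; NADP+/NADPH must also be boundary because the
  truncated route produces three NADPH per two glucose units with no
  internal consumer (no steady state exists otherwise); Pi is boundary
  because one phosphate leaves with each G3P. The unique productive mode
  then converts 2 glucose units to 1 PHB -- a 50% molar yield.
* `fpk_essential` (RPE and the rearrangement module removed): Ru5P and E4P
  are boundary byproducts and Pi is boundary, but NADP(H) stays internal;
  that constraint alone forces the 4:1 PGI:G6PDH split of G6P and the 40%
  molar yield (5 glucose units -> 2 PHB).

`cofactor_closure()` evaluates moiety balances from the boundary net
equation weighted by each boundary species' moiety content (P atoms, CoA
and NADP tokens), so a phosphate atom that leaves inside a G3P byproduct
still counts toward closure. All shipped variants close NADP(H), CoA and
phosphate at exactly zero.

## Kinetic model

Rate laws are standard saturable families with Michaelis constants in mM,
maximal rates in mM/min (numerically equal to loadings in U/mL, the 1:1
conversion `vmax_to_loading()` makes explicit) and equilibrium constants as
mM mass-action ratios:

* irreversible uni / bi: `V S/(K+S)` and `V A B/((K_A+A)(K_B+B))`;
* reversible uni-uni, bi-uni, bi-bi: rapid-equilibrium random forms built
  on the thermodynamic driving force `(AB - PQ/keq)`; they vanish exactly
  at equilibrium and run backwards above it (the PhaA thiolase, with its
  tiny condensation keq, is routinely product-limited this way);
* PHB synthase: Henri-Michaelis-Menten damped by a product-binding factor
  `C_bind/(C_bind + PHB^n)`, modelling the loss of synthase activity as it
  co-precipitates with the growing granules. At `PHB = 0` (or
  `C_bind -> Inf`) it is plain HMM.

H2O and H+ are held constant; maltodextrin, PHB and CO2 are dynamic even
though the stoichiometric analysis fixes them. Integration uses `deSolve`'s
`lsoda` (stiff-capable) with the substrate stop event located by root
finding. The moiety and carbon conservation laws built into the
stoichiometry double as solver diagnostics: trajectories conserve total
carbon, NADP(H), the CoA thioester pool and total phosphate to machine
precision, and the test suite enforces 1e-6 relative drift.

### The stop event

Reactions in this system cease when maltodextrin falls to 40% of its
cumulative initial concentration (the empirical ceiling of phosphorylase
action on shortened chains; `stop_threshold` is a scenario parameter). Two
semantics are implemented. The default `halt-uptake` switches off aGP at
the event and lets the in-flight intermediates drain into PHB; this is the
reading under which the simulated titer approaches the theoretical 4/3 of
consumption -- with the calibrated model and the synthase at 8 mM/min, 60.0
mM consumed yields 79.7 mM PHB at 240 min, a whisker under the 80.0 mM
stoichiometric ceiling, because the reversible pools cannot drain
completely. The alternative `freeze` holds the whole state at the event.
Both the event-time and the horizon PHB are reported, since with full
freezing they coincide and with draining they differ.

Restarts are supported: `stop_reference` pins the event to an absolute
substrate reference so that re-simulating from an event state fires the
event immediately and consumes nothing further.

## Parameter sets (Model 0/1/2)

The shipped YAML files under `inst/extdata/models/` are package-authored,
semi-quantitative stand-ins, not transcriptions of any published table.
Values were chosen once, on these grounds:

* `model0` -- pre-calibration: equilibrium constants at literature
  magnitudes for each step (e.g. near-unity phosphorolysis, G1P->G6P ~17,
  strongly forward aldol/TK2 steps, a vanishingly small thiolase
  condensation keq of 4e-5); Km at BRENDA-typical magnitudes where well
  known and 0.1 mM otherwise, deliberately conservative (large) for the
  phosphoketolase, transketolase, PTA and reductase steps; synthase
  `C_bind = 1000`, `n = 1` (the uninformative initial guess under which
  the binding term is essentially inactive).
* `model1` -- first round: the phosphoketolase/transketolase substrate Km
  reduced (raising attainable titer), PTA and reductase Km reduced
  (raising throughput), and the synthase binding term calibrated
  (`C_bind = 140`, `n = 2`) so that the simulated loading screen reproduces
  the system's reported optimization behaviour: the final-titer screen
  saturates at a synthase loading of 8 U/mL and the run then consumes its
  60 mM at near-theoretical yield. The phosphorylase Km for maltodextrin
  (150 mM) makes uptake the distributed bottleneck, keeping in-flight
  pools small -- the regime in which the cascade actually operates.
* `model2` -- second round: the phosphorylase keq lowered to 0.25
  (stronger product back-pressure late in the run) and the synthase
  `C_bind` reduced to 100, the two parameters revisited in the second
  fitting round.

Loading scenarios (`paper_scenarios()`) pair these models with the study's
conditions: 100 mM maltodextrin glucose equivalents, 10 mM Pi, 2 mM NADP+,
0.5 mM CoA; flat loadings of 1 or 5 U/mL with the bifunctional
phosphoketolase coupling `Vmax(FPK) = 0.12 Vmax(XPK)` and transketolase at
1:1; and the two optimized loading tables computed by `run_round()` itself
and shipped as text.

## Enzyme-loading optimization

`scan_enzyme()` performs the one-at-a-time Vmax scan: one simulation per
grid point (default integer steps, because loadings are pipetted in integer
U/mL), coupled groups moving at fixed ratio, all other enzymes held. The
accepted optimum is the *minimal* Vmax whose metric reaches 99% of the best
achieved in the scanned range -- a rule that deliberately prefers less
enzyme, degenerates to the smallest grid value on flat or decreasing
curves, and thereby flags "kinetic trap" enzymes (those whose higher
loading *lowers* the initial rate, as the G6PDH scan shows) for reduction.
`run_round()` chains the two phases of a full optimization round: a yield
screen fixing the synthase on final titer (240 min in round 1, 480 min in
round 2), then initial-rate scans (PHB formed in the first hour, on a
60-min simulation) for everything else, with accepted optima applied only
between phases so scans never contaminate each other.

## Calibration

The study's model fitting was manual adjustment; `fit_parameters()`
replaces it with a reproducible bounded least-squares surrogate over
exactly the parameter families adjusted per round (substrate Km, keq,
`C_bind`, `n`). The loss is the sum over datasets, time points and the two
observables (PHB and residual maltodextrin) of squared residuals between
the simulation and replicate *means*, scaled by the per-observable maximum
so both observables weigh comparably; replicate SDs are carried for
reporting only. Optimization is Levenberg-Marquardt (`minpack.lm`) on
log-parameters with box bounds and optional seeded multistart. Two
numerical details matter: the fit integrates tightly (`rtol = 1e-9`) and
widens the finite-difference step (`epsfcn = 1e-6`), because Jacobians
differenced at the solver's noise floor otherwise stall the optimizer. On
noise-free synthetic data the fit recovers generating parameters from
twofold-perturbed starts to well under 1%; under the default measurement
noise, joint fitting of two loading conditions keeps recovery within 5%.
Identifiability is the caveat: parameters whose perturbation the
observables barely feel (e.g. the reductase Km, buffered by its
quasi-steady substrate pool) cannot be pinned by any optimizer, so the
recovery tests use a sensitive free set (phosphorylase Km, phosphoketolase
Km, synthase binding).

## Synthetic data

`generate_timecourse()` emulates the study's measurement structure:
triplicates of PHB and residual maltodextrin at bench sampling times
(default 0, 1, 2, 4, 6, 8, 10, 24 h), with multiplicative Gaussian noise
(CV 0.02, matching the magnitude of printed SDs such as 74.9 +/- 0.5 mM)
plus a 0.1 mM absolute floor so near-zero titers still scatter, truncated
at zero with truncations counted. Seeds and the generating condition are
recorded in the dataset attributes and survive the CSV round trip. What
this generator does *not* emulate -- systematic assay bias, enzyme
inactivation over hours, substrate inhibition at 200 mM, turbidity
artifacts -- bounds what a passing calibration test shows about real data:
it validates the estimator, not the model's adequacy for any particular
bench run.

## Problem sizes and reproducibility

All stoichiometric results are desk-scale (the full network has 20 internal
species and 19 reactions; enumeration takes well under a second). Kinetic
test runs use 240-min horizons at 1-5-min output grids, and the calibration
tests fit 2-3 parameters on one or two synthetic datasets of seven time
points -- sizes chosen so the entire suite exercises every code path in a
few minutes while the recovery checks remain sharp. `run_pipeline()` writes
a manifest with MD5 checksums; identical configurations reproduce every
numeric output byte-for-byte, and all stochastic steps take explicit seeds.

## Known limitations

* Maltodextrin chain-length distribution, the auxiliary
  4GT/PPGK second stage, and fed-batch modelling beyond simple timed
  additions are out of scope (additions are supported as plumbing only).
* Temperature/pH dependence, enzyme inactivation and substrate inhibition
  of the phosphorylase are not modelled.
* The shipped Model 0/1/2 parameter values are plausible, behaviour-matched
  stand-ins; quantitative conclusions about a real preparation require
  refitting to that preparation's time courses.
* SBML support covers exactly the constructs this model uses (compartment,
  species with boundary flags, mass-action-free kinetic-law parameter
  lists, one trigger event); anything richer is rejected on import by
  design.
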