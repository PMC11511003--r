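---
title: "Methods: a Boolean model of dehiscence-zone patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Boolean model of dehiscence-zone patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podnet)
```

## The modeling problem

A dry dehiscent fruit opens because four cell types differentiate in a
precise spatial series across the medio-lateral axis of the ovary wall:
valve (V), lignification layer (LL), separation layer (SL) and replum (R).
The regulators involved — FUL, SHP1/2, IND, ALC, SPT, RPL, BP,
JAG/FIL/YAB3, AS1/2, AP2, miR172 (with ARF6/8), and NTT — are individually
well characterized, but whether the *known* interactions among them
suffice to generate all four expression states is a dynamical question.
`podnet` poses it in the standard synchronous Boolean formalism: node
states are binary, all nodes update simultaneously through fixed logical
rules, and the stable cell types must appear as attractors of the
`2^n`-state transition graph.

Synchronous updating is an idealization: it assumes all regulatory delays
are equal.  Its known artifact — spurious cyclic attractors created by
simultaneous switching — is treated explicitly by the continuous embedding
described below.

## Node grouping and the two rule sets

Functionally redundant regulators are merged into single nodes: SHP1/SHP2
→ `SHP`, JAG/FIL/YAB3 → `JFY`, AS1/AS2 → `AS`.  The ARF6/8 requirement for
miR172 activation is folded into the `MIR172` rule (so the repression of
ARF6/8 by AP2 appears there as an AP2 term), which keeps the state space
minimal without losing any constraint that matters for the four profiles.
`SPT` is carried as an output node in both models: none of its target
interactions belong to the validated initial set, but keeping the node
makes the two networks directly comparable and lets the mutant panel
include the *spt* knockout.

The **initial network** (11 nodes) uses only the experimentally validated
interaction records flagged for the first model version in the shipped
catalogue (`dz_interactions()`, `in_initial_model == TRUE`; 22 records).
The **final network** adds `NTT` and a small hypothetical set.  The rule
files are a *reconstruction*: they are constrained by the signed
interaction catalogue, by the published mutant phenotypes, and by the
documented NTT hypotheses, and the package freezes them by truth-table
hash (`network_hash()`), but they are not a verbatim transcription of any
published appendix.  Every rule records its reading of the evidence:

```{r rules}
dz_network("final")
```

* `FUL <- JFY & !NTT & !IND`: lateral factors activate *FUL* only where
  NTT is absent (the valve); margin identity, carried by IND, excludes
  FUL.  The IND term is hypothetical — it implements the observed mutual
  exclusion of valve and margin programs and, with the SHP rule below,
  replaces a direct mutual repression that would oscillate under
  synchronous updating (an even negative feedback between FUL and SHP
  yields a two-cycle; routing the repression through IND makes the loop
  odd-length and the toggle settles).
* `SHP <- JFY & (NTT | !FUL)`: lateral factors activate *SHP*; in the
  presence of NTT this activation overrules FUL's repression.
* `IND <- SHP & !FUL`: the validated activation and repression.  The
  reported quantitative damping of *IND* by ALC/SPT is deliberately left
  out of the default rules; the shipped variant
  (`dz_network("final_variant")`) restores it and demonstrably loses the
  SL fixed point to a cyclic attractor — which is why the default omits
  it.
* `ALC <- IND & SHP & NTT & !FUL`: *ALC* transcripts require both SHP and
  IND; the NTT term is the hypothetical repressor-free mechanism that
  confines ALC to the separation layer, where NTT protein is found.
* `SPT <- (IND | SHP) & !FUL`: partial, redundant activation.
* `RPL <- BP & !JFY`, `BP <- NTT & !JFY & !AS`, `JFY <- !RPL`: the
  medial-lateral antagonism.  BP's maintenance requires NTT (its validated
  activator); BP's own repression of JFY is carried through RPL, the
  direct medial repressor of FIL.
* `AS <- !SHP & !AP2`, `AP2 <- !FUL & !MIR172`, `MIR172 <- FUL & !AP2`:
  the valve-restricted AS/AP2/miR172 module.  AP2's self-repression is
  omitted (under synchronous updating it forbids any fixed point where
  miR172 is off), and AP2/miR172 states are not used as classification
  markers.
* `NTT <- NTT`: validated auto-activation; NTT acts as a lineage flag that
  splits the state space into an NTT-off sector (valve and lignification
  layer) and an NTT-on sector (separation layer and replum).

With these rules the final network has exactly four attractors, all fixed
points, matching the four marker profiles one-to-one; the initial network
yields valve, a merged valve margin and replum, and *cannot* separate LL
from SL — see the rule-search section for why that failure is structural.

## Reference profiles and classification

`dz_profiles()` returns partial marker states: only nodes with stated
tissue activity are constrained (FUL on only in V; SHP/IND on in LL and
SL; ALC only in SL; RPL/BP only in R; NTT in SL and R; JFY lateral; AS in
the valve).  AP2, MIR172 and SPT rows are unconstrained rather than
invented.  A fixed point is labelled with the unique profile it matches on
every constrained marker; anything else is `novel` — there is no
nearest-match fallback, so phenotype matches are never over-claimed.  In
mutant simulations the clamped node is excluded from matching, and the
`canonical` flag records whether the state also agrees with the profile on
the clamped node: non-canonical columns correspond to the asterisked
attractors of published mutant tables.

## Mutant panel

Constitutive mutants clamp a node to 0 (loss of function) or 1
(constitutive expression): the rule is replaced by the constant and the
clamp is recorded.  The standard panel (`mutant_panel()`) runs FUL, SHP
(both directions), NTT gain, and IND/ALC/SPT/RPL loss.  Two readings are
worth noting.  "Valve-like" for the FUL gain-of-function attractors is
judged on the identity-defining markers (IND, ALC, RPL, BP, JFY plus FUL
itself): one of the two recovered attractors is exactly the valve, the
other differs only in the NTT-sector flags.  For *shp*, the default rules
(without the ALC/SPT feedback on IND) keep IND silent in every attractor,
matching the indehiscent phenotype; the variant rule set instead shows the
ectopic IND activity that motivated dropping the feedback.

## Robustness analyses

Both analyses compare the focal network against an ensemble of 1000
topology-matched random networks: same nodes, same regulator sets (hence
identical in-degrees and wiring), truth-table outputs drawn uniformly at
random with constant functions re-drawn.  Preserving exact regulator sets
is the stricter and more informative null; degree-only preservation is
available behind `preserve = "in_degree"`.

**Function perturbation.**  One draw alters `max(1, round(0.1 * n))`
node functions — for these 11/12-node networks, exactly one — by flipping
one uniformly chosen output bit of the truth table.  The minimum-one
convention matters: 10% of 12 rules rounds to a single function, and all
printed recovery values depend on it.  A draw *recovers* when every
original attractor (the identical state cycle) is still an attractor of
the perturbed network; the mean per-draw proportion of recovered
attractors is also reported.  The focal estimate uses 10,000 seeded draws
(standard error below half a percentage point); each ensemble network is
scored against its own attractors with 100 draws, and the ensemble median
is reported.

**Transition perturbation.**  The spec-level operations
`perturb_transitions()` (flip one successor bit in `round(0.1 * 2^n)`
table entries) and `normalized_hamming()` (differing successor bits over
`n * 2^n`) are provided and tested, but as a *comparative* statistic the
table-level distance is uninformative: it equals `fraction / n` for every
network by construction.  The analysis therefore measures how strongly
one-step dynamics diverge under state noise: flip `max(1, round(0.1 * n))`
bits of a state and take the normalized Hamming distance between the
successors of the original and perturbed states.  For single-bit flips the
package computes the exhaustive expectation over all `n * 2^n`
(state, bit) pairs, which is deterministic and cheaper than sampling.
Canalized regulatory logic damps this divergence well below the random
expectation for the same wiring.

Empirical p-values use the add-one estimator
`(1 + #{nulls at least as good}) / (ensemble + 1)`, so they can never be
zero; all draws derive from one recorded seed and identical seeds give
bit-identical summaries.

## Continuous embedding

Each node's rule is relaxed by fuzzy logic (`NOT x -> 1 - x`,
`AND -> min`, `OR -> max`) into `omega_i : [0,1]^n -> [0,1]`, and the
dynamics are

$$\dot x_i = \sigma_h(\omega_i(x)) - \gamma_i x_i,$$

with the sigmoid `1 / (1 + exp(-h (w - 1/2)))` affinely normalized so that
`sigma_h(0) = 0` and `sigma_h(1) = 1`.  On Boolean corners `omega`
reproduces the truth table, so every Boolean fixed point is a steady state
of the embedding, stable for steep gain.  One consequence of the
normalization is worth flagging: for a self-activating node the corners 0
and 1 are pinned as steady states at *every* gain, so the classical
"monostable at shallow gain" picture does not apply; what changes with `h`
is the steepness of the separatrix at 1/2.

Defaults: gain `h = 10` (saturating), decay `gamma = 1` (unit
normalization), steady-state tolerance `1e-6` on `max |dx/dt|` sustained
over the trajectory tail, horizon `t_max = 100` time units, integrated
with `deSolve::lsoda`.  Cyclic attractors are resolved by integrating from
the exact corner embedding of each cycle state plus a jittered replicate
(each coordinate moved 0.01 into the interior) to distinguish knife-edge
from robust convergence; the report states whether all starts reach a
common steady state and which profile its thresholded shadow
(`x > 0.5`) matches.  Under the frozen transcription the wild-type final
network has no cyclic attractor — the cycles appear in mutant simulations
(e.g. SHP overexpression) and in the initial network, and the resolution
machinery is exercised there and on toy oscillators.  A two-node rotation
with no stabilizing structure collapses onto the interior saddle rather
than any corner, and is reported as matching no profile.

## Constraint-based rule search

`enumerate_functions()` enumerates truth tables per node under edge
classes: mandatory edges (MPU/MNU) must be essential and monotone with the
stated sign; optional edges (OPPA/ONPA) may be dropped and their signs are
unconstrained.  `search_networks()` prunes candidates against every
required fixed point that determines a node and its regulators, explores
the remaining assignment space exhaustively (bounded, with the bounding
node reported), and verifies every assembled network by exhaustive
fixed-point enumeration.  Emptiness is a reported result, not an error.
"Meaningful network" is operationalized strictly as satisfaction of the
fixed-point constraints.

Applied to the compiled initial topology with the four cell-type profiles
as required fixed points, the search is empty *at the ALC node*: ALC's
regulators (IND, SHP, FUL) take identical values in the LL and SL
profiles, which demand different ALC outputs — no Boolean function exists,
whatever its form.  This is the precise sense in which the validated
interaction set cannot pattern the dehiscence zone and a missing ALC
regulator (resolved here by NTT) is required.

## Synthetic data, problem sizes, and what the tests show

The package's synthetic-data source is the topology-matched random
ensemble plus seeded random toy networks (regulator sets up to size 3–4,
random non-constant truth tables) and three analytic fixtures (identity,
negation, two-node toggle).  These emulate the combinatorics of small
regulatory networks — wiring, canalization, attractor multiplicity — but
not features of real expression data (noise, graded levels, asynchrony,
spatial coupling), so green tests certify the dynamical machinery and the
model's internal consistency, not biological validity.

Default analysis sizes, chosen as the study conditions: exhaustive
enumeration over `2^12 = 4096` states; 10,000 focal perturbation draws;
1000 random networks with 100 draws each; oracle cross-checks on random
networks up to `n = 8` (256 states), where a brute-force step-iteration
oracle is tractable and fully independent of the traversal
implementation.

## Known limitations

* The rule sets are a reconstruction; all transcription-dependent
  statistics are tied to the shipped truth-table hashes, and a variant
  rule set is provided where the evidence is genuinely ambiguous.
* Two-level logic cannot express the quantitative ALC/SPT damping of IND;
  the variant shows the cost of forcing it.
* Single-cell, non-spatial model: no coupling along the medio-lateral
  axis, no hormone dynamics (GA/auxin/cytokinin are outside the node
  set).
* Synchronous determinism: asynchronous or probabilistic updating are out
  of scope, and cyclic attractors are interpreted only through the
  continuous embedding.
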