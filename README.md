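# podnet

Boolean modeling of the gene regulatory network (GRN) that patterns the
medio-lateral axis of the *Arabidopsis thaliana* fruit — the tissue layout
that makes a dry fruit shatter and release its seeds.  Four cell types have
to emerge side by side from one network: the **valve** (V), the
**lignification layer** (LL) and **separation layer** (SL) of the valve
margin, and the **replum** (R).  `podnet` is for systems biologists and
plant developmental biologists who want to interrogate, perturb and extend
that network with a reproducible logical model.

## The model

Each regulator is a binary node and all nodes update synchronously,

```
x_i(t + 1) = f_i(x_{i1}(t), ..., x_{im}(t)),   x_i ∈ {0, 1},
```

so the `2^n` network states form a deterministic transition graph whose
attractors — fixed points and cycles — are read as the stable cell-type
expression profiles.  The package ships two curated rule sets:

* an **initial** 11-node network compiled strictly from experimentally
  validated interactions, which recovers valve, an undifferentiated valve
  margin and replum — but provably *cannot* separate LL from SL (no
  repressor of *ALC* is known, and ALC's regulators take identical values
  in the two layers);
* a **final** 12-node network adding the NTT transcription factor and a
  small set of hypothetical interactions (JAG/FIL/YAB3 activate *FUL* only
  in NTT's absence, activate *SHP* in its presence; NTT confines *ALC* to
  the separation layer), which recovers exactly the four expected
  fixed-point attractors.

The rule files are a documented reconstruction (see the methods vignette
in `vignettes/`), shipped in the plain-text `targets, factors` dialect
under `inst/extdata/`, together with the signed interaction catalogue and
the reference marker profiles.

Around the core model the package provides: exhaustive attractor and basin
enumeration; constitutive loss-/gain-of-function mutants by node clamping
with profile classification (the nine-mutant panel); robustness analysis
against 1000 topology-matched random networks (truth-table bit flips and
one-step state-perturbation Hamming divergence, with empirical p-values);
conversion of the Boolean model to a continuous fuzzy-logic/sigmoid ODE
system to resolve artifactual cyclic attractors; and a small
constraint-based rule search (mandatory/optional, signed edges plus
required fixed points).

## Worked example

```r
library(podnet)

net <- dz_network("final")
validate_wildtype(net)
#> Wild-type validation
#>   matched profiles:   V, LL, SL, R
#>   unmatched profiles: none
#>   separates LL and SL: TRUE
#> # A tibble: 4 × 5
#>   attractor length basin label canonical
#>       <int>  <int> <int> <chr> <lgl>
#> 1         1      1    64 LL    TRUE
#> 2         2      1  1984 V     TRUE
#> 3         3      1    24 R     TRUE
#> 4         4      1  2024 SL    TRUE
```

All 4096 states flow into exactly four fixed points, one per cell type;
`basin` counts the states draining into each (the valve and separation
layer dominate the landscape).  A *ful* knockout is a one-liner:

```r
glance(simulate_mutant(net, perturbation(c(FUL = 0))))
#> # A tibble: 1 × 5
#>   mutant n_attractors n_fixed_points n_cycles labels
#>   <chr>         <int>          <int>    <int> <chr>
#> 1 ful               3              3        0 LL,R,SL
```

Three attractors and no valve: the valve territory adopts margin identity,
matching the published *ful* phenotype.  `mutant_panel()` runs the full
nine-mutant panel, `run_robustness()` compares the network against its
random-topology null ensemble (`autoplot()` draws the ensemble histogram
with the focal value marked), and `resolve_cyclic_attractors()` integrates
any cyclic attractor's states through the continuous embedding and reports
the cell-type profile of the stationary state they collapse onto.

A thin CLI wraps the same functions for shell use:

```sh
Rscript inst/cli/podnet attractors --model final --out results/
Rscript inst/cli/podnet mutant --model final --lof FUL --out results/
Rscript inst/cli/podnet robustness --model final --mode functions --seed 1 --out results/
```

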