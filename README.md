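# hexfrac

Probabilistic inference of subgenome orthology and biased fractionation after
an ancient hexaploidy (whole-genome triplication, WGT).

## The problem

A hexaploid genome carries three homoeologous copies of every ancestral locus,
one per progenitor *subgenome*. Over time most duplicated copies are lost
(*fractionation*), usually unevenly: one subgenome keeps many more genes than
the others (*biased fractionation*). Given a set of syntenic "pillars" — an
ancestral gene order in which each polyploid genome contributes up to three
gene tracks per locus — the orthology of each track to a subgenome is not
observable directly. `hexfrac` infers it, quantifies the loss biases, asks
whether the order in which the subgenomes hybridised explains them, and
compares repetitive-element (RE) loads between subgenomes in conserved
intergenic regions.

The package is aimed at comparative genomicists working on paleopolyploid
plant (or other) genomes who have pillar/synteny data and want a tested,
scriptable reimplementation of this analysis with a synthetic-data generator
for validation.

## The model

Each pillar evolves along a rooted species tree under a 7-state
continuous-time Markov chain: the triplicated state `T` decays into duplicated
states `D_X.Y` (subgenomes X and Y retain a copy) and then into absorbing
single-copy states `S_X`. All rates are relative to a base loss rate α, which
is absorbed into branch lengths `u = αt`. Nested families constrain the nine
transition rates:

* `WGT_null` — all subgenomes equivalent; one free rate σ (duplicate → single).
* `WGT_1d` — one subgenome (LF) may lose fewer copies (+2 parameters).
* `WGT_3g` — all three subgenomes differ (+2).
* `WGT_arb` — all nine rates free (+3).

Arrival variants model the hexaploidy as a tetraploid intermediate: the two
founder subgenomes evolve as a duplicated pair for a phase of length τ (rates
scaled by κ) before the last subgenome arrives. Because each genome's three
tracks can map to the subgenomes in 3! = 6 ways, a pillar has `6^n` joint
orthology states for `n` genomes (1296 for four). A hidden Markov model along
the pillar order (per-genome track-permutation switch probability θ per
junction) couples neighbouring pillars; emissions come from Felsenstein
pruning over the 7 loss states. All parameters are fitted by maximum
likelihood; families are compared by likelihood-ratio tests.

Downstream, per-gene subgenome assignments and expected surviving-gene counts
are read off the posteriors; subgenome-assigned intergenic regions (SAIRs) are
extracted between confidently assigned neighbouring pillar pairs (joint-state
posterior ≥ 95% at both pillars, genes present and syntenic in every genome);
and RE hit densities (hits/kB of SAIR) are compared between subgenomes with a
placement randomization test.

## Worked example

```r
library(hexfrac)
library(dplyr)

# simulate a 4-genome pillar dataset under the documented study conditions
cfg <- sim_config(n_pillars = 1000, seed = 42)
sim <- simulate_pillars(cfg)
sim$pillars
#> <pillar_set> 1000 pillars, 4 genomes (tomato, eggplant, pepper, petunia),
#>   5560 genes, 3 blocks

# fit the nested families with warm starts and test them against each other
topo <- ape::read.tree(text = "(((tomato,eggplant),pepper),petunia);")
fits <- fit_model_ladder(sim$pillars, topo, n_starts = 2, seed = 1)
lrt(fits$null, fits$`1d`)
#> # A tibble: 1 x 6
#>   lnl_null lnl_alt statistic    df   p_value boundary
#>      <dbl>   <dbl>     <dbl> <int>     <dbl> <lgl>
#> 1   -5623.  -5247.      752.     2 4.98e-164 FALSE

# decode orthology and count survivors per subgenome
pd <- posterior_decode(sim$pillars, fits$arb$model, fits$arb$tree,
                       fits$arb$theta)
count_surviving(pd, sim$pillars) |>
  summarise(count = sum(count), .by = subgenome)
#> # A tibble: 3 x 2
#>   subgenome count
#>   <chr>     <dbl>
#> 1 LF        3087.
#> 2 IF        1476.
#> 3 MF         997.
```

The statistic 752 on 2 d.f. rejects equal loss rates across subgenomes — the
simulated data are strongly biased, and the survivor counts read off the
posterior reproduce the planted LF > IF > MF profile (the generating model
gives MF fewer than a third of LF's survivors). `assign_genes()`,
`find_sairs()`, `re_density()` and `randomization_test()` continue the
pipeline to the repeat-density comparison; `vignette("hexfrac-methods")`
walks through the science and every tunable parameter.

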