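---
title: "Modelling biased fractionation after whole-genome triplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling biased fractionation after whole-genome triplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexfrac)
```

## The inference problem

A hexaploidy leaves three homoeologous copies of every ancestral locus, one
per progenitor subgenome. In modern descendants most copies are gone, and the
losses are usually biased: by convention the subgenomes are called LF, IF and
MF for least-, intermediate- and most-fractionated. The observable data are
*pillars*: columns of an inferred ancestral gene order in which each extant
genome contributes up to three syntenic gene slots ("tracks"). Which track
descends from which subgenome is unobserved; a run of consecutive pillars on
the same chromosomal segment shares its track-to-subgenome arrangement until
a synteny break reshuffles it.

`hexfrac` treats this as a hidden Markov model over the `6^n` joint
track-to-subgenome arrangements of `n` genomes, with emissions given by a
phylogenetic model of gene loss, and estimates everything by maximum
likelihood.

## The loss process

Per pillar and lineage, the copy set evolves under a 7-state continuous-time
Markov chain on `T` (triplicated), `D_LF.IF`, `D_LF.MF`, `D_IF.MF`
(duplicated; subscripts name the surviving subgenomes), and absorbing
`S_LF`, `S_IF`, `S_MF` (single copy). Nine transitions are allowed (three
`T -> D`, six `D -> S`); there are no gains and no whole-pillar extinction,
so every genome retains at least one copy of every pillar. Rates are relative
to the base loss rate α: branch lengths are expressed as `u = αt`
(expected-loss units) and the first `T -> D` rate is fixed to 1 to pin the
scale. Transition probabilities are `P(u) = exp(Qu)` (computed with
`Matrix::expm`; the triangular structure gives the closed form
`P(T -> T) = e^{-(ρ1+ρ2+ρ3)u}` used as a test oracle).

The nested families, with free rate-parameter counts:

| family | constraint | free rates |
|---|---|---|
| `null` | all subgenomes exchangeable; `D -> S` rate σ | 1 |
| `1d` | LF may differ: `f_t` scales the `T -> D` loss of the LF copy, `f_d` the two `D -> S` losses of the LF copy | 3 |
| `3g` | adds the analogous `(g_t, g_d)` pair for IF-copy losses | 5 |
| `arb` | every transition free (first fixed at 1) | 8 |

The deltas (2, 2, 3) are the degrees of freedom of the nested
likelihood-ratio tests; an arrival variant adds (τ, κ), i.e. 2 d.f. The
root-branch variant frees the three `T -> D` rates on the root branch (+3),
keeping the `D -> S` rates shared: because the tip likelihood sees the root
branch only through its 6-dimensional exit distribution, a fully independent
root rate set plus the free root-edge length would be an unidentifiable
ridge, and the initial-loss rates are exactly the quantities the arrival
hypothesis makes predictions about (a late-arriving subgenome has had less
time to lose its copy on the root branch, so transitions preserving it are
relatively favoured there, reversing on the later branches).

**Arrival models.** A hexaploidy forms in two steps: two founder subgenomes
make a tetraploid, the last subgenome arrives later. The variant
`arrival = list(last =, tau =, kappa =)` starts each pillar in the founders'
duplicated state, runs the founder pair for a phase of length τ (the two
relevant `D -> S` rates scaled by κ), and maps the survivors into the
7-state space at the (instantaneous) second hybridisation: both founders
surviving becomes `T`, a single founder `Y` becomes `D_{Y,last}`. With τ = 0
the arrival model collapses exactly onto its base family.

**A caution on arrival-model comparisons.** With all nine rates free, the
three "last-arriving" candidates are images of one another under subgenome
relabelling, so as *global* families they are indistinguishable. They are
meaningful only as local refinements of the plain `arb` optimum, whose fitted
rates anchor the subgenome labels to the data. `compare_arrival_models()`
therefore warm-starts every candidate at the `arb` solution and disables the
composite warm-up stage (see below) so the optimiser cannot hop into a
relabelled basin. The collapse flag (|ΔlnL| < 10⁻³) identifies candidates
whose tetraploid phase fits at zero length.

## The orthology HMM

Each genome's hidden state at a pillar is one of the 6 permutations assigning
its three tracks to {LF, IF, MF}; the joint state is the product over
genomes. Between adjacent pillars a genome keeps its permutation with
probability 1 − θ and switches to each alternative with probability θ/5,
independently across genomes; θ is shared across genomes. The chain starts
uniform and is re-initialised at *contiguity breaks* — positions where the
ancestral order itself is interrupted.

Emissions: for a genome with presence pattern `p` under permutation π, the
leaf vector is the indicator of the loss state whose surviving-subgenome set
is π(occupied tracks); a genome with no gene at the pillar is missing data
(all-ones vector). Felsenstein pruning over the species tree, with the root
distribution above, gives the emission probability of each joint state. The
forward recursion, posterior decoding and the pruning inner loops are
implemented in C++; partial-likelihood arrays are memoized on the distinct
presence patterns, which makes the cost per likelihood evaluation linear in
the number of *distinct* patterns rather than pillars.

**Contiguity breaks are declared, not guessed.** The pillar TSV dialect marks
block starts with `#BREAK` rows, and the simulator emits them at its true
block boundaries. An optional mode (`detect_breaks = TRUE`) additionally
declares a break at any junction across which no genome has a syntenic
neighbour pair. We made detection opt-in after measuring its effect: detected
junctions are exactly the loss-heavy ones, so forcing a chain reset there
conditions on the data and biased several fitted loss rates by 20–30% in
5000-pillar simulations (replacing the detected breaks by the true block
structure removed the bias entirely). Use detection only for files that carry
no block annotation at all, and prefer re-deriving blocks from the synteny
pipeline that produced the pillars.

## Fitting

`fit_loss_model()` maximises the forward log-likelihood jointly over the
family's free rates, all branch lengths (including the root edge, the shared
branch between the hexaploidy and the first speciation), θ, and (τ, κ) for
arrival models, using L-BFGS-B on log-/logit-transformed parameters with a
forward-difference gradient.

Numerical choices worth knowing:

* **Composite warm-up.** Stage one maximises the *independent-pillar*
  likelihood (each pillar's emission averaged over the uniform stationary
  distribution of the HMM kernel). This is a valid marginal composite
  likelihood, costs no forward pass, and lands close to the full optimum;
  stage two polishes everything jointly. Convergence is declared at a
  relative lnL change of about 10⁻⁸ (`factr = 4.5e7`).
* **Label symmetry.** The likelihood is invariant under consistent
  relabelling of subgenomes, so an exactly symmetric start (all rates equal)
  is a saddle that gradient methods cannot leave. The default start applies a
  fixed asymmetric tilt; the second default start sits at the neutral nesting
  point (new parameters at 1), which guarantees a warm-started richer family
  never ends below the simpler optimum. Additional starts jitter randomly.
  After an `arb` fit the labels are canonicalised: LF is the subgenome with
  the highest model-implied survival at the tips, MF the lowest; rates,
  branch lengths and τ are rescaled so the first `T -> D` rate is 1 again.
* **Degenerate inputs.** `u = 0` gives the identity transition matrix;
  θ = 0 freezes the permutation chain within blocks (a dataset inconsistent
  with a single permutation then has likelihood 0, reported as −Inf);
  θ = 1 is rejected. Inside the optimiser, −Inf is replaced by a large
  finite penalty to keep line searches in bounds.
* **MAP ties** are broken towards the lexicographically first joint state.

**A structural fact about tests against `WGT_null`.** At the null MLE the
rate vector sits at the exact label-symmetry point, so the likelihood
gradient is constant within each transition orbit; stationarity in σ forces
the `D -> S` component to zero, and stationarity in the branch lengths (the
global rate-scale direction) then forces the `T -> D` component to zero.
The score in the `1d` test directions therefore vanishes identically, for
every dataset: the `1d`-vs-`null` LRT is second-order degenerate, and its
finite-sample null distribution carries a point mass at zero (about a fifth
to a quarter of null simulations) rather than following χ²(2). The χ²
reference printed by `lrt()` is the field's convention and its *tail*
behaviour is close to nominal (empirically P(stat > 5.99) ≈ 0.05–0.07 under
the null), but a goodness-of-fit test of the full statistic distribution
against χ²(2) will reject. Tests between asymmetric families (`3g` vs `arb`,
arrival vs `arb`) do not share this degeneracy, though τ on the boundary
makes arrival tests conservative (flagged in the output).

## Downstream: assignments, SAIRs, repeats

Gene assignment uses each genome's marginal track-to-subgenome posterior;
`count_surviving()` sums these marginals over occupied tracks, so per-genome
totals are conserved exactly (permutations are bijections). The joint-state
posterior, displayed per pillar, is used for SAIR filtering: a SAIR group
needs a pair of neighbouring pillars (same contiguity block; strict adjacency
by default, `max_gap` relaxes it) where one subgenome has genes present in
all genomes at both pillars, the flanking genes are syntenic neighbours in
every genome, and the joint MAP posterior is at least 95% at both pillars.
The intergenic interval is the gap between the flanking gene bodies, 0-based
half-open; strand is carried but never used.

Repeat analysis consumes external BLASTN (`-outfmt 6`) or nhmmer (`--tblout`)
hit tables with an E ≤ 10⁻⁵ cutoff (closed bound). Regions merge when hits
share at least one base (abutting hits stay separate). Ancestral repeats are
called either by presence parsimony (a passing hit in every genome of the
group) or by conserved local alignment: Smith–Waterman with match +4,
mismatch −5, first gapped base −8, each further gapped base −4, requiring
at least 80 alignment columns *and* score at least 200 in every non-reference
genome. Densities are hits per kilobase of SAIR sequence.

The randomization test shuffles the observed hits and places them uniformly
into the pooled SAIRs of the two compared subgenomes; a hit of length L can
start at `length(SAIR) − L` positions, shorter SAIRs are skipped, and a SAIR
that receives a hit is removed for the rest of the replicate, so placed hits
never overlap. The p-value uses the add-one rule
`(exceedances + 1)/(replicates + 1)`, two-sided by default with 10 000
replicates. Because hit counts are integers the null statistic has atoms:
with the default `ties = "conservative"` tied replicates count as
exceedances, giving a valid but super-uniform p-value; `ties = "random"`
breaks ties uniformly and is exactly uniform under the null — that variant
is what the package's calibration tests check.

## The synthetic-data generator

`simulate_pillars()` draws each pillar's state at the hexaploidy from the
arrival (or point-mass) root distribution, evolves it down the tree by
sampling the transition matrices, runs each genome's permutation chain with
the same kernel the HMM assumes (switch probability θ, uniform over
alternatives, re-drawn at block starts), and emits gene coordinates on
per-track chromosome segments so that synteny breaks are visible to the
coordinate-based adjacency computation exactly where the chain switched.
`simulate_sairs()` plants copies from a bundled 12-element toy repeat library
into random ancestral intergenic sequences at per-subgenome Poisson
densities, evolves each genome's copy by substitutions (per-tip divergence
scaled along the tree) and indels, and emits FASTA-ready sequences plus a
perfect-knowledge hit table, so every repeat-stage function is testable
without an external search.

Default conditions (all overridable in `sim_config()`): four genomes on the
ladder topology with petunia outermost; `arb` rates
(0.65, 0.18, 0.9, 0.28, 2.6, 0.38, 2.4, 1.0 relative to the first rate);
an MF-last arrival with τ = 0.3, κ = 1; θ = 0.05 per genome per junction;
geometric contiguity blocks of mean length 500; 6919 pillars. The rates and
tree depths were calibrated once so the model-implied survivor profile
matches the real data's qualitative description — MF under a third of LF's
survivors, IF a bit under twice MF (here LF/IF/MF tip survival
0.77/0.38/0.23, about 1.4 surviving copies per genome per pillar). This
keeps the generative labels and the canonical (survival-ranked) labels
aligned; with a near-tie between IF and MF survival, dataset-to-dataset
sampling noise would otherwise swap them.

θ deserves a note. Break counts published for real hexaploid pillar sets are
of the order of 0.2 per genome per junction, but they count *gene-order*
adjacency interruptions, most of which do not reassign tracks to subgenomes.
The HMM's θ is the rate at which the hidden arrangement itself switches,
which must be much lower: at a switch rate of 0.2 the joint orthology
posterior essentially never reaches the 95% rule and no SAIRs would survive
filtering, contradicting the thousands of confident SAIRs real datasets
yield. θ = 0.05 reproduces the observed LF ≫ IF > MF profile of
high-confidence SAIR counts.

What the generator does *not* emulate: real pillar construction error
(mis-assembled blocks, missing annotations, genes absent from all pillars),
rate heterogeneity across pillars, gene gains, realistic repeat biology
(bursts, families, insertion preference), or GC/composition structure.
Passing recovery tests on these simulations show the estimator is correct
under its own assumptions, not that real pillar data satisfy them.

## Problem sizes used by the tests

The test suite exercises the exact oracles at enumeration scale (2–3
genomes, 3–4 pillars), parameter recovery at 20 replicates of 5000 pillars
and 4 genomes, LRT calibration at 200 two-genome null simulations of 250
pillars, arrival/reversal recovery at 20 replicates of 3000 pillars and 3
genomes, and the repeat stage at a few hundred simulated SAIRs; the
acceptance script runs the full four-genome pipeline at 3000 pillars. These
sizes are the package's documented desk-scale study conditions.

## Known limitations

* Branch lengths are expected-loss units; the package never converts to time.
* θ is shared across genomes and branches (a per-genome θ is a documented
  extension point, not implemented).
* The state space is enumerated densely; beyond 5 genomes (7776 states)
  memory and time grow steeply.
* The chi-square reference for tests against `null` is conventional, not
  exact (see above).
* SAIR extraction ignores unplaced genes inside the intergenic gap.
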