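---
title: "The senesim model: how and when aging evolves on a lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The senesim model: how and when aging evolves on a lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`senesim` simulates haploid, individual-based populations on an `N x N`
toroidal lattice to ask under what conditions a heritable *rate of aging* is
positively selected.  Each individual carries a single binary chromosome of
`Lf` fecundity loci and `La` senescence loci in a randomized, run-fixed
order.  Two quantities follow from the genome:

* **Fecundity.**  The environment defines a binary optimum vector
  (the *target*) over the fecundity loci.  An individual matching the target
  at `s` loci has fecundity `b^s` (multiplicative fitness; `b = 1.2` by
  default), normalised by the maximum `b^Lf` where a bounded quantity is
  needed.
* **Mortality.**  The per-generation death probability (hazard) is
  `delta(tau) = delta0 + alpha * tau` for age `tau` up to the maximum
  lifespan `tau_max = floor((1 - delta0) / alpha)`, and 1 beyond it.
  The aging rate `alpha = 0.01 * (number of ON senescence alleles)` is the
  evolving trait; `alpha = 0` means a genetically immortal individual
  exposed only to the extrinsic hazard `delta0`.

Selection can be **directional** — the target starts at the zero vector and
one randomly chosen locus flips every `T` generations, sweeping to all-ones
and back, so a full environmental period spans `2 * T * Lf` generations —
or **stabilizing**, with a static random target.  Population *viscosity*
does the rest: because offspring are placed at most `n` sites from their
parents, neighbours are kin, and an individual that dies early hands its
site to a neighbour's (likely related) offspring.

## The update loop

A generation consists of `N^2` elementary Monte Carlo updates at uniformly
random sites (i.i.d. draws with replacement), followed by a synchronous age
increment.  Each update:

1. If the focal site is occupied, the occupant dies with its hazard
   `delta_i`.
2. If the focal site is now empty — whether just vacated or found empty —
   the occupied sites of its `n`-Moore neighbourhood compete to fill it.
   One parent is drawn with probability proportional to raw fecundity
   `b^s`.  Under asexual reproduction the offspring is a mutated copy;
   under sexual reproduction a second, distinct parent is drawn
   fecundity-proportionally from the remaining candidates (dioecy), the
   offspring chromosome is formed by single-point recombination (with
   probability `prec`, a cut at one of the `Lf + La - 1` internal
   inter-locus positions, orientation chosen uniformly, so each parent
   contributes at least one gene) and then mutated.  If no parent (or no
   sexual pair) is available the site stays empty.
3. `D` diffusion swap trials follow: a random site exchanges contents with
   a random one of its 8 adjacent sites.  `D` may exceed 1 (it is an
   expected count; `floor(D)` swaps plus a Bernoulli remainder), and
   `D = 0.5` calibrates to one lattice step per site per generation.

Mutation is a per-bit flip with probability `pf` (fecundity loci) and `pa`
(senescence loci), applied at birth only.

Two design points deserve emphasis, since the update discipline is the part
of such models that prose descriptions underdetermine:

* **Death frees a site that is contested immediately.**  The alternative —
  making death and birth mutually exclusive within an update, so a vacated
  site waits to be redrawn — leaves an equilibrium fraction
  `mortality / (1 + mortality)` of sites empty (5% even for a non-aging
  population, ~25% for an evolved aging one).  With immediate contest the
  lattice stays saturated (occupancy above 0.999 at every parameter set we
  screen), which is the regime this model family is about: reproduction is
  a zero-sum contest for sites freed by death.  Both disciplines are
  implemented in the engine (`immediate_refill`), the immediate contest
  being the supported default.
* **Site order.**  With i.i.d. site draws an occupant receives a
  Poisson-distributed number of death trials per generation, so a few
  individuals outlive `tau_max` between trials; a per-generation random
  permutation (also available internally, `site_order`) gives exactly one
  trial per occupant.  The two differ only marginally in every quantity we
  track.

## Initialisation and variants

Runs start from a fully occupied lattice: ages `floor(U(0, 1/delta0))`,
all senescence alleles OFF (aging must arise de novo by mutation), and
fecundity alleles i.i.d. fair coins.  Variants used by the experiment
protocols:

* `config_field` — parent candidates are 8 random lattice-wide sites
  instead of the local neighbourhood; this destroys relatedness while
  keeping every other rule, and is the mean-field control for kin
  selection.
* `monomorphic_fertility` — all individuals share an all-zero, non-mutating
  fecundity genotype (`pf = 0` required), so fecundity weights cancel and
  only the senescence alleles evolve; used for the extrinsic-mortality
  sweeps.
* `evolvable_baseline` — the senescence alleles instead encode an
  age-*independent* individual baseline mortality
  `0.002 + 0.01 * sum(a_j)` (the 0.002 floor prevents infinite longevity),
  with the age-dependent term off; this separates "evolving higher
  mortality" from "evolving age-dependent mortality".
* `fixed_alpha` — every individual starts with the same preset number of
  ON senescence alleles and `pa = 0`, pinning the aging rate; used to show
  that a faster-aging population tracks the moving target more closely.

## Observables

Per generation the engine records, over occupied sites only: occupancy,
mean aging rate, mean age, mean hazard (evaluated at each occupant's
current age), mean normalised fecundity, the population Pearson
correlation between aging rate and normalised fecundity (emitted as `NA`
when a variance is zero, never silently 0), mean target match `s` and its
complement the Hamming distance to the target, the tagged-lineage
frequency, and death/birth/swap counts.  From final states the package
computes age histograms and the spatial gradient profile of the aging rate
(mean `|d alpha|` between occupied sites at exact Chebyshev distance `d`,
the torus metric matching the Moore geometry).  Gradient profiles are
computed exactly for all pairs by lattice shifts rather than by pair
sampling: the shift formulation is `O(d_max^2 N^2)` vectorised work, which
is cheap even at `N = 200`, so sampling noise would buy nothing.

## Experiment protocols

`run_sweep()` runs value x replicate grids with deterministically derived
seeds and, for every value, a matched stabilizing control; equilibrium
means are taken over a configurable window (default: the last 40% of the
run, comfortably after the transient, which at standard parameters ends by
roughly generation 600 on a 100 x 100 grid and by roughly 2000 at
200 x 200).  `sweep_threshold()` implements the transition estimator used
throughout: the smallest swept value whose directional mean no longer
exceeds the control mean by 2 across-replicate control standard
deviations.

`run_invasion()` equilibrates a resident, replaces the *genomes* of a
random fraction of occupied sites with an invader genotype — ages are
kept, so the perturbation is purely genetic — and follows the system.  Two
trackers are reported.  A neutral descent tag (offspring tagged if any
parent is tagged) is a genealogical diagnostic only: under sexual
reproduction the descendants-of-invaders fraction grows toward 1 for any
sizable founding fraction no matter how strongly selection removes the
invader alleles, so it cannot certify a failed invasion.  The
establishment verdict therefore uses the frequency of carriers of ON
senescence alleles, which is an exact census of invader-derived aging
alleles whenever the resident is non-aging with `pa = 0`.

## What the simulations show, and their limits

At the standard parameters (directional, sexual, 100 x 100 grid) the
package reproduces the model family's signature behaviour: aging rises
from zero to a stable level, equilibrium mean age falls to about 2.3
generations, occupancy stays above 0.999, and the stabilizing control
stays at a low mutation–selection balance near `alpha = 0.01`.  The
orderings asexual > sexual, and decreasing aging with larger `n`, larger
`D`, or the configuration-field limit, all hold; adaptation to the moving
target collapses below a per-bit mutation rate of about 0.006, and the
stabilizing regime shows error-threshold-like jumps in the aging rate near
`p = 0.012` (sexual) and about 0.02 (asexual).

One quantitative caveat matters for interpretation.  The dynamics are
bistable: a high-turnover aging state and a low-aging state are each
locally stable, and once the early adaptation burst has nucleated the
aging state it self-sustains even if the target is subsequently frozen
(we verified this directly in both sexual and asexual populations).
Consequently the critical period dilution `T` above which aging fails to
evolve from a non-aging start is a *nucleation* threshold and is sensitive
to micro-details of the update loop; in this implementation it sits near
`T = 64`–`128` on a 100 x 100 grid rather than at `T = 32`.  The
mutation-rate and extrinsic-mortality transitions, which are set by
mutation–selection balance rather than nucleation, are insensitive to
these details.

The synthetic environment is deliberately minimal: a single species, no
resources, no trade-off between fecundity and survival loci, one locus
flip per `T` generations.  Passing the scaled-down checks shows the
mechanism — kin selection plus directional selection favouring evolved
senescence — operates in this idealised setting; it says nothing about
parameter values in real populations, where the strengths of directional
selection and relatedness are empirical questions.

## Numerical choices

* Problem sizes: tests and the acceptance script use 60–100 site grids for
  2000–4000 generations with 2–3 replicate seeds, sizes at which every
  reported equilibrium is well past its transient; full-scale figures
  (200 x 200, 10^4 generations, 100 replicates) are the same code with
  larger arguments.
* Reproducibility: one RNG stream per run, seeded once (`set.seed`);
  replicate seeds are `base_seed` plus small documented offsets; the C++
  engine draws from R's stream, so a run is bit-reproducible from
  `(params, seed)` across the R/C++ boundary.
* Parent selection uses raw weights `b^s` (normalisation cancels in
  proportional choice); weights are taken from a precomputed power table
  and match counts are cached per individual and updated incrementally at
  target flips.
* Degenerate inputs: an empty candidate set leaves the site empty; a lone
  candidate under sexual reproduction is not a pair and leaves the site
  empty; zero-variance correlations are `NA`; an empty lattice yields `NA`
  summaries and occupancy 0.
* Target flips occur before the updates of generations `k*T + 1`
  (`k >= 1`), i.e. the target is constant for the first `T` generations;
  the phase reverses on the flip that reaches saturation, with no
  double-flip at the turning points.
```
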