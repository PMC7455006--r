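---
title: "Methods: sequence-explicit replicase-parasite dynamics on a torus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-explicit replicase-parasite dynamics on a torus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaworld)
```

## The scientific question

A central puzzle of the RNA World hypothesis is how polymerase ribozymes
(replicases) could persist once their own error-prone copying produced
parasites — molecules that are copied but do not copy. In well-mixed
systems parasites win; spatially extended replicase-parasite (RP) models in
the Takeuchi–Hogeweg tradition showed that locality of interactions can
stabilize coexistence. `rnaworld` implements a sequence-explicit extension
of that model family: agents are not abstract parameter bundles but
50-nucleotide RNA strands, and every behavioural parameter is a function of
the sequence, so that mutation acts on genotypes and phenotypes follow.

## The model

### From sequence to phenotype

Each agent derives three parameters from its sequence at birth; they never
change during its lifetime (the sequence does not change either — mutation
happens only at replication).

**Folded fraction `l`** (unitless, in [0, 1]). A secondary structure is
predicted and `l` is the fraction of paired nucleotides. The builtin
predictor maximizes the number of base pairs (Nussinov-style dynamic
programming) subject to

* a minimum hairpin loop of `min_loop = 3` unpaired nucleotides — the
  standard steric constraint;
* allowed pairs A·U, G·C and, by default, the G·U wobble pair;
* nestedness (no pseudoknots).

Maximum base-pairing rather than a thermodynamic model is used because only
the paired-nucleotide *count* enters the model, and the count for the
designed replicase stem (below) is recovered exactly. Traceback prefers the
leftmost admissible partner, so prediction is fully deterministic. An
exhaustive enumeration oracle (`enumerate_structures()`, sequences up to
16 nt) verifies the dynamic program in the test suite. Any function mapping
a sequence to a pair list can replace the builtin predictor
(`folding_options(backend = )`); a wrapper around the ViennaRNA `RNAfold`
binary ships with the package. A missing external backend is a
configuration error, never a silent fallback.

**Replicase efficiency `a`** (probability per step). The first 20 nt are
compared position by position — no alignment — with the catalytic motif
`UCAUUGAAAAAAAAAGACAA` (the 5' segment of the engineered polymerase
ribozyme tC19Z; any motif of the same length can be configured, since what
matters for the dynamics is the sequence-function coupling, not the
particular string). With `m` matching positions the replication rate is

```
k_R = 10 m   if m >= 7,      k_R = 0 otherwise,
```

and the per-step replication probability follows constant-hazard kinetics,
`a = 1 - exp(-k_R * dt)`. Agents with `a = 0` are parasites. Both the
threshold (7) and the per-match rate (10) are configuration fields of
`replicase_motif()`.

**Decay rate `b`** (per time unit). `b = d + sum of d(NN)` over the 49
ordered neighbouring dinucleotides, where `d` is the base decay rate and
`d(NN)` a dinucleotide-specific hydrolysis rate. `kierzek_rates()` ships
the measured non-enzymatic cleavage rates (pyrimidine–A most labile,
pyrimidine–C intermediate, purine-initiated bonds stable); the default
table is all zeros. Orientation matters: `d(UA) != d(AU)`.

An *ideal replicase* is motif + reverse complement + a uniform random
10-nt tail. The two designed segments form an 18-bp stem (the two
innermost rungs violate the loop constraint), so at least 36 of 50
nucleotides are paired (`l = 0.72`); the random tail adds on average about
one pair, giving a population mean `l` of about 0.81 under the builtin
predictor (thermodynamic predictors, which disfavour isolated tail pairs,
sit closer to the designed-stem value).

### Dynamics

Time advances in steps of `dt = 0.1`. Each step has two phases, each
visiting agents in a fresh uniformly random order.

*Phase 1 — decay, replication, diffusion.* A complexed enzyme decrements
its complex's countdown; at zero the template is copied (per-nucleotide
substitution probability `seq_mut`, replacement uniform over the three
other bases), the offspring is placed at the template's exact position
with parameters derived from its own sequence, and the complex dissociates.
A free agent decrements its lifetime — sampled at birth as
`floor(-ln(X)/(b dt)) + 1` steps, `X ~ U(0,1]` — and is removed at zero,
otherwise it moves by a Brownian kick `|w| = sqrt(6 dt D p)` (`p ~ U[0,1]`,
direction uniform) and wraps onto the torus. Per-step mean squared
displacement is therefore `3 dt D`; over many steps the summed displacement
is Gaussian by the CLT. Complexed agents neither move nor age.

*Phase 2 — crowding and complex formation.* For each free agent, all other
agents strictly within `int_radius = 3` are collected (uniform-grid index;
an all-pairs scan verifies it in the tests). More than `neigh = 4`
neighbours — free or complexed, since complexed molecules still occupy
space — removes the agent (the density cap). Otherwise the agent scans its
neighbours in random order and binds the first free one that accepts:

```
P(complex) = a_E * l_E * (1 - l_T)
```

— the initiating agent is always the enzyme and must be folded; the
template must be unfolded to be copyable. One enzyme binds at most one
template per step. With the replication rate `K = Inf` (the default) every
complex replicates exactly one step after it forms; finite `K` draws a
countdown from the same exponential-waiting-time sampler. Offspring born
in phase 1 participate in phase 2 of the same step but neither age nor
diffuse until the next step.

The run ends after `max_steps` steps or when the population reaches zero.
All randomness — shuffles, lifetimes, kicks, mutation, binding — flows
through R's RNG in a fixed documented order, so a seed fixes the entire
trajectory bit for bit. The per-step trajectory records class counts,
class means of `a` and `l`, and the births/decays/removals ledger, which
satisfies `N(t+1) - N(t) = births - decays - removals` exactly.

## Scenarios and scaling

The reference system is 100,000 agents on a 1000×1000 torus (density 0.1
per unit²). Because the dynamics are density-driven (radius-based binding
and crowding), scenarios scale down density-preservingly: `scale = s`
multiplies the population by `s` and each side by `sqrt(s)`. The four
builders are: (1) ideal replicases only; (2) fully random sequences, of
which a fraction `P(Binom(20, 1/4) >= 7) ≈ 0.214` are accidental
replicases; (3) as (1) with the measured hydrolysis table installed; and
(4) as (1) at a smaller scale, swept over `d` or `D`.

Problem sizes used by the test suite and the acceptance script: the scaled
replicase-pool runs use `scale = 0.09` (9,000 agents, 300×300, 3,000
steps, three seeds); sweeps use `scale = 0.01` (1,000 agents, 100×100).
Scenario 2's initial count defaults to the same scaled size, which yields
hundreds of accidental replicases; the builder reports the realized count.

## What the simulations show — and where the model deviates from its lineage

The acceptance runs at the reference parameters (`d = 0.01`,
`seq_mut = 0.01`, `D = 4`) show a characteristic trajectory: the replicase
pool overshoots the density cap, parasites generated by motif erosion
surge, and the replicase class then collapses, leaving a slowly decaying
parasite remnant. Earlier reports in this model family describe stable
coexistence with high equilibrium efficiency at these same parameters; two
structural observations explain why this implementation behaves
differently, and both follow from taking the printed rules literally.

First, the efficiency rule is *flat*: with `k_R = 10 m` and `dt = 0.1`,
every replicase (m ≥ 7) has `a ≥ 1 - e^-7 ≈ 0.999`. Losing motif matches
therefore costs a replicase essentially nothing until it falls off the
7-match cliff, so the motif erodes neutrally at ~0.2 motif mutations per
copy. Reported equilibrium efficiencies of 0.82–0.86 in this model lineage
are only attainable if efficiency is *graded* in the match count (e.g. an
exponent of `m/10` rather than `10 m dt`), which creates the
mutation-selection balance those numbers imply; under the flat rule the
class mean over replicases can never fall below 0.999. We implement the
rule as printed and report what it produces.

Second, coexistence requires the parasite wake to clear. At `d = 0.01`
a parasite lives ~1000 steps while generations take only a few steps, so
parasites accumulate faster than kin-structured selection can purge them.
Raising the base decay rate restores the published phenomenology: at
`d = 0.6` the same scaled system reaches stable replicase-parasite
coexistence within 3,000 steps (asserted in the test suite), and `D = 0`
(no dispersal) drives the system extinct, as does sufficiently large `d`.
The survival window in `d` is thus shifted upward relative to the
lineage's reported window, which collapses already at `d = 0.7` — a value
at which this implementation still coexists.

These deviations are documented rather than patched: the package's purpose
is a faithful, deterministic, testable implementation of the stated rules,
with every disputed constant (`rate_per_match`, `match_threshold`,
`min_loop`, wobble, hydrolysis table) exposed as configuration so the
alternative readings can be explored.

## Numerical choices and degenerate inputs

* Waiting times: `floor(t/dt) + 1` guarantees at least one step;
  `k = Inf` maps to one step; `k = 0` ("no reaction") is an error for the
  sampler and a never-scheduled event for the engine (`b = 0` agents are
  immortal).
* Strict inequality at the interaction radius: agents at exactly
  `int_radius` are not neighbours.
* Toroidal wrapping by flooring division, with a guard against the
  floating seam at `x = size`.
* The grid cell size is at least the query radius, so queries inspect at
  most 9 cells; areas smaller than 3×3 cells fall back to an all-pairs
  scan.
* Folding is computed once per distinct sequence (memoized in the engine);
  an unmutated copy inherits its template's parameters outright.
* Empty population: the run terminates at the first step with zero counts
  and `NA` class means; empty classes always yield `NA` means, and sweep
  tables print them as missing.

## What the synthetic scenarios do and do not emulate

The scenario builders generate idealized initial conditions — uniform
random placement, designed or uniform random sequences — and the
hydrolysis table is the only empirically measured ingredient. Passing
tests therefore demonstrate the internal consistency of the engine and the
qualitative regimes of the model, not fidelity to any wet-lab system:
real prebiotic pools had length variation, non-uniform base composition,
tertiary interactions, and compartment effects, all outside this model's
scope (as are insertions/deletions, strand polarity, and
parallel-execution semantics).
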