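---
title: "Ancestry-based forward simulation: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-based forward simulation: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(begsim)
```

## The model

begsim simulates a diploid, panmictic Wright–Fisher population with
discrete, non-overlapping generations.  Each generation, every one of the
$N'$ offspring draws two parents independently, with replacement, with
probability proportional to parental fitness (selfing is allowed — the
standard Wright–Fisher convention).  Each transmitted gamete starts from
one of the parent's two homologous haplotypes (fair coin), may recombine
with the homolog at Poisson$(rL)$ breakpoints placed uniformly on
$[1, L-1]$, and then receives Poisson$(\mu L)$ new mutations at uniform
positions.  Fitness is multiplicative over mutations on both haplotypes,

$$ w = \prod_i (1 - s_i), $$

with the convention that deleterious mutations have $s > 0$, beneficial
mutations $s < 0$, and neutral mutations $s = 0$ (factor 1).  There is no
dominance: the model is per-haplotype multiplicative, which is what makes
fitness updates a single product per gamete.

Two selection-coefficient models are provided.  `selection_fixed(s,
p_positive)` draws $\pm s$ with the stated probability of a beneficial
sign.  `selection_normal(mean, sd)` is deliberately parameterized on the
*fitness effect* $e = w - 1 \sim \mathcal N(\text{mean}, \text{sd})$, so
that a negative mean is deleterious — the literature is not consistent
about the sign of $s$ in $w = 1 - s$, and parameterizing the effect
removes the ambiguity.  Internally $s = -e$; draws that would make
fitness non-positive ($s \ge 1$) are redrawn, a truncation that is
irrelevant for any realistic parameter choice but keeps the product
strictly positive.

### Scaled rates

Scaled population rates are quoted as $\theta = 4 N_e \mu L$ and $\rho =
4 N_e r L$ per locus.  The per-*gamete* event rates are $\mu L$ and $r
L$; summed over the $2N$ transmitted gametes of a generation these give
the usual coalescent-scaled totals, and this is the reading under which
the simulator reproduces the neutral closed forms $E[S] = \theta\,
a_{n-1}$ and $E[\pi] = \theta$ (checked in the test suite).

### Mutation model

Sites are finite: a mutation picks a uniform base-pair position, so
repeat hits at segregating positions occur and overwrite the lineage's
derived state toward a new base drawn uniformly from the alternatives.
One deliberate restriction: the new base is never the reference base, so
derived-state polarity stays well defined — the unfolded site frequency
spectrum requires known ancestral states, and allowing back-mutation to
the reference would conflate loss of the derived allele with its
persistence.  At chromosome-scale locus lengths the difference is
unmeasurable (collision probability per pair of mutations is $1/L$); at
the tiny locus lengths used by some of the stress tests it is exactly
what keeps the forward and ancestry-based paths comparable bit by bit.

## The ancestry-based neutral path

Neutral mutations do not alter sampling probabilities, so they need not
be carried through the forward phase at all.  The engine records, per
generation, the surjective parent map $a_i$ from child haplotypes to
parent haplotypes (stored as parent individual plus one homolog-choice
bit per locus, which is also what makes multiple unlinked loci cheap),
every recombination event (generation, haplotype, breakpoints) and every
selected-mutation event.  Haplotype indices pair homologs as $(2k, 2k +
1)$, so a parent's recombination partner is always `parent XOR 1`.

After the forward phase, three passes reconstruct the neutral picture:

1.  **Backtracking.**  Starting from the present generation, whose
    haplotypes get the maximal region $[0, L]$, surviving regions are
    propagated to parents.  A haplotype's true surviving material may be
    fragmented; only the *super-region* $(r_S, r_E)$ — first segment
    start to last segment end — is tracked, which over-approximates the
    truth and is corrected later, at extraction.  A recombination is
    *kept* (becomes an R-node) only when a breakpoint actually splits
    the child's region so that both donors receive material; otherwise
    the event is transparent and the child is re-attached directly to
    whichever donor carried its material.  Getting that donor right
    matters: a single breakpoint below $r_S$ means the child inherited
    everything from the homolog, not from the mapped parent.
2.  **Placement.**  For each generation $i$ and each survivor, neutral
    mutation counts are drawn at the full per-gamete rate $\mu L \cdot
    f_{neutral}$ and positions uniform on $[0, L)$; draws outside the
    survivor's super-region are discarded (draw-then-filter).  Relative
    to simulating everyone, the effort shrinks by $F = |S_i| / (2 N_i)$,
    which decays quickly toward a recombination-rate-dependent plateau.
    Draws inside a super-region "hole" are allowed into the graph — the
    over-approximation — and are filtered during extraction.
3.  **Graph construction.**  Forward over generations, node references
    are propagated along $a_i$; kept recombinations become R-nodes
    (out-degree 2: one edge to the donor of $[0, b_1)$, one to the
    homolog's reference) and placed mutations become M-nodes (out-degree
    1) stacked on their haplotype's current reference — mutations apply
    after recombination within a generation.  Node 0 is the founder
    sentinel; edges always point to earlier nodes, so acyclicity is
    structural and asserted on every build.

**Extraction** then walks the graph from each requested present-day
entry, maintaining the *exact*, possibly fragmented region of interest:
R-nodes split the region between their donors, and an M-node contributes
its bit only if its position lies inside the current region — this is
where super-region over-approximation is corrected exactly.  Two
optimizations change cost, never results: traversals from entries whose
leading M-chain ends in an already-extracted node copy that row and
append their own bits; and the top `explicit_node_fraction` (default 5%)
of nodes by traversal visit count $v$ are materialized as packed-bit
rows at which later traversals stop, OR-merging the cached row
restricted to the region of interest.  Ties at the selection boundary
break toward younger nodes, and entry traversal order is fixed, so runs
are reproducible; the test suite asserts that extraction output is
identical for explicit fractions of 0, 0.05 and 1.

The decisive correctness instrument is the **exact replay oracle**: run
one simulation with neutral mutations carried forward (ground truth by
naive propagation), then feed the identical committed events (generation,
haplotype, position, base) plus the recorded ancestry into the graph
pipeline and require bit-identical present-day neutral sequences.
Distributional tests compare laws; the oracle compares realizations, and
it is sensitive — deleting a single observable M-node makes it fail.
A second, fully independent route to the same ground truth is the pure-R
reference engine (`run_forward(engine = "r")`), which consumes the random
stream in the same order as the compiled engine and must agree with it
bit for bit.

## Parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `N_e` | — | Diploid effective size; the founder generation has this size. |
| `L`, `locus_lengths` | — | Locus length(s), bp.  One BEG per unlinked locus. |
| `mu`, `r` | — | Per-base per-generation rates; per-gamete rates are `mu*L`, `r*L`. |
| `neutral_fraction` | 1 | Probability a new mutation is neutral; the selected share is thinned out of the neutral Poisson stream. |
| `n_generations` | `10*N_e` | Long enough for a mutation-free founder population to reach approximate neutral equilibrium (the residual truncation of coalescent tails is at the percent level for the sample sizes used here). |
| `cleanup_interval` | 100 | Generations between fixed-mutation sweeps; pure bookkeeping (consumes no randomness, leaves segregating sites untouched — asserted by a stream-identical paired run). |
| `explicit_node_fraction` | 0.05 | Extraction cache size; a runtime/memory trade-off with no effect on output. |
| `mode` | `"anc"` | `"for"` carries neutral mutations forward, `"anc"` places all of them a posteriori, `"mix"` splits the neutral rate (`mix_forward_fraction`, default 0.5). |
| `sample_size` | 50 | Haplotypes drawn without replacement from the present generation. |
| `seed` | 1 | Everything — engine, placement, sampling — runs off one seeded stream; identical invocations are byte-identical. |

Demographies compose an initial constant size with instantaneous factor
changes and exponential growth, with event times quoted in generations
before the present (`demog_step(gens_ago, factor)`,
`demog_exp(gens_ago, rate)`, or the compact `"step:200:2"` form).
Sizes round to the nearest integer and are floored at 1.

## The validation battery

The five neutral scenarios use $N_e = 500$, $L = 10^6$, $\mu = r =
10^{-8}$, $10 N_e$ generations and 50 sampled haplotypes (75 under
growth): (i) no recombination, (ii) mutation and recombination, (iii) a
doubling $0.2 N_p$ generations ago, (iv) a factor-2 bottleneck $0.25
N_p$ generations ago, (v) exponential growth from $0.5 N_p$ generations
ago.  The growth *rate* is a free choice; begsim uses
$\ln 2 / (0.5 N_p)$ — growth to exactly a doubling over the stated
window — so that scenario (v), like (iii), ends at twice the initial
size.  The selection scenarios use $N_e = 250$, $L = 10^5$, $\mu = r =
10^{-6}$ per base (read as per-base rates; the per-sequence totals are
then 0.1 per gamete), all mutations selected, with either fixed $|s| =
0.01$ (20% beneficial) or normal fitness effects with mean $-0.01$ and
sd $0.001$.

Instead of an external coalescent simulator as referee, the test suite
compares against the neutral closed forms ($E[S] = \theta a_{n-1}$,
$E[\pi] = \theta$, $E[\xi_i] = \theta / i$) and tests the three modes
against *each other* with two-sample Kolmogorov–Smirnov tests,
Bonferroni-corrected across the whole family of (scenario × mode-pair ×
statistic) comparisons at $\alpha = 0.01$.  An ms-format reader/writer
is included so externally generated coalescent output can be compared
with the same statistics machinery.

**Problem sizes.**  The distributional battery runs 80 replicates per
(scenario, mode) arm in the test suite and 100 per arm in the
acceptance script — enough for the closed-form means to resolve at the
3-standard-error level, while keeping the full battery in the minutes
range on one CPU.  At these replicate counts the KS tests only have
power against fairly gross distributional differences; the exact replay
oracle, not the KS battery, is what pins per-instance correctness.  The
SFS check uses replicate-level standard errors rather than a pooled
multinomial $\chi^2$, because site counts within a replicate are
correlated through their shared genealogy.

The genome-scale benchmark simulates 23 unlinked loci in human-chromosome
length proportions (3.037 Gbp total), $\mu = r = 2.5 \times 10^{-8}$, 100
diploid individuals, 1000 generations, 10% of mutations non-neutral.  Two
choices here are the package's own.  First, the non-neutral coefficient
defaults to $N_e |s| = 0.1$, i.e. effectively neutral: at a deleterious
genomic rate of several mutations per gamete per generation, any
appreciable $|s|$ depresses genome-wide diversity through background
selection, which this throughput benchmark is not meant to model.
Second, published site totals for such runs are quoted for the *neutral*
output (the packed-bit sequences the ancestry path produces), so
`run_genome_scale()` reports `total_S_neutral` alongside `total_S`.  The
acceptance checks run it at 10–20% locus length — neutral segregating
sites scale linearly in $L$, and the per-locus coalescent variance
$\theta_i a_{n-1} + \theta_i^2 b_n$ puts the scaled estimate's relative
SD near 5%, hence a three-SD acceptance band of 15%.

## Numerical and representational choices

* Coordinates are 0-based; recombination segments are half-open
  $[b_k, b_{k+1})$.  Surviving-region arithmetic uses closed integer
  intervals internally (`(Inf, 0)` encodes the empty region); conversion
  to bit-array indexing happens only at extraction.
* Haplotypes store position-sorted references into a mutation registry;
  splicing a recombinant is a ranged copy per segment and insertion is
  binary-search plus overwrite-on-collision.
* Duplicate breakpoints within one gamete are collapsed (a double
  crossover at the same point is the identity).
* The ancestry's storage contract — minimal integer width per generation
  for the parent map, one bit per locus for the homolog choice — is
  exposed by `ancestry_storage_report()` and asserted in tests.
* The packed-bit output format is little-endian, bit 0 of byte 0 being
  the first site, rows padded to whole bytes, with an 8-byte magic,
  version, dimensions and sequence length in the header; positions and
  per-site metadata travel in a TSV sidecar, and an ms-format mirror is
  written for interoperability (positions normalized to $[0, 1)$).
* Degenerate inputs: zero total fitness raises a degenerate-population
  error; `n_generations = 0` returns the founder state with an empty
  ancestry; loci shorter than 2 bp cannot recombine; stubs referencing
  non-survivors and malformed graphs raise contract errors rather than
  producing silent nonsense.

## What the generator does and does not emulate

The simulator produces exact Wright–Fisher realizations of panmictic
diploid populations with multiplicative selection — the setting in which
the a-posteriori neutral placement is provably equivalent to forward
simulation.  It does not model dominance or epistasis, balancing
selection, population structure or migration, gene conversion, or sex
chromosomes; and the founder population is monomorphic rather than drawn
from stationarity, so runs shorter than a few $N_e$ generations are far
from equilibrium by construction.  Passing the validation battery
therefore says nothing about those regimes; it says that under the
stated model the ancestry-based path and plain forward simulation are
the same distribution, and per instance the same bits.

## Known limitations

* The ancestry of a long run is kept in memory (that is what makes the
  backward pass exact); at $10 N_e$ generations and large $N_e$ this is
  the dominant allocation.  A sectioned/streaming variant is out of
  scope.
* Under extreme recombination rates (many crossovers per gamete per
  generation) most haplotypes survive, $F \to 1$, and the ancestry path
  loses its advantage — the classical regime limitation of
  survivor-based approaches.
* KS-based equivalence testing at desk-scale replicate counts has
  limited power (see above); the replay oracle carries the per-instance
  correctness burden.
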