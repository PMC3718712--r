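# begsim

Forward-in-time Wright–Fisher simulation of diploid populations under
selection, mutation and recombination, with an ancestry-based algorithm
that avoids simulating neutral mutations forward at all: the engine
records the complete ancestry of the run, backtracks which haplotypes of
which past generations still contribute sequence to the present (the
*survivors* and their *surviving regions*), places neutral mutations only
there, and assembles a **Backward Event Graph (BEG)** — a DAG of mutation
(M) and recombination (R) nodes encoding the observable history of every
present-day haplotype — from which the neutral sequences are extracted as
packed bit rows.  The result is distributionally equivalent to carrying
every neutral mutation through the forward phase, and per instance
bit-identical when the same committed event stream is replayed through
both paths.

It is aimed at population geneticists who need forward simulation (i.e.
selection beyond single-sweep coalescent machinery) at chromosome- to
genome-scale locus lengths, and at method developers who want the full
observable event history of a simulated sample, not just its end state.

## Model in brief

Discrete generations; each of the `N'` offspring draws two parents with
probability proportional to fitness `w = Π (1 − s_i)` over the non-neutral
mutations on both haplotypes (`s > 0` deleterious, `s < 0` beneficial).
Per gamete: a fair-coin homolog choice, `Poisson(rL)` recombination
breakpoints, `Poisson(μL)` new mutations at uniform finite-sites
positions.  Scaled rates are `θ = 4·N_e·μ·L` and `ρ = 4·N_e·r·L` per
locus; under neutrality the simulator reproduces `E[S] = θ·a_{n−1}`,
`E[π] = θ` and `E[ξ_i] = θ/i`.

## Worked example

```r
library(begsim)

p <- sim_params(N_e = 500, L = 1e6, mu = 1e-8, r = 1e-8,
                n_generations = 5000, sample_size = 50,
                mode = "anc", seed = 7)
res <- simulate_population(p)
res
#> <sim_result: 1 loci, sample of 50 haplotypes, mode AF-ANC>
#>   total segregating sites: 94

summary_stats(res$matrices[[1]])
#> # A tibble: 1 × 4
#>       n     S    pi     K
#>   <int> <int> <dbl> <int>
#> 1    50    94  21.1    36
```

`S = 94` segregating sites against the neutral expectation
`watterson_expected_s(theta_locus(p), 50)` = `20 × a_49` ≈ 89.6, and a
nucleotide diversity of 21.1 against `θ = 20` — one draw from the equilibrium
distribution.  `mode = "anc"` means not one of those 87 mutations was
carried through the 5000 forward generations; they were placed on the
surviving lineages afterwards.  The per-stage API exposes the pipeline:

```r
fr  <- run_forward(p)                       # ancestry + selected mutations
ss  <- backtrack_survivors(fr)              # survivors and regions per generation
mu  <- place_neutral_mutations(ss, p)       # a-posteriori neutral draws
beg <- build_beg(fr, ss, mu)                # the Backward Event Graph
hm  <- extract_sequences(beg)               # packed-bit haplotype matrix
```

`write_outputs()` writes the packed-bit matrix with TSV sidecar, a
mutation table, the BEG edge list and an ms-format mirror.  A shell
interface with the same capabilities is installed at `exec/begsim`:

```sh
begsim simulate --Ne 500 --L 1000000 --mu 1e-8 --rho 1e-8 \
       --neutral-fraction 1.0 --mode anc --sample 50 --seed 7 --out run
begsim stats --in run
```

The exact replay oracle — the package's decisive correctness check —
is one call:

```r
replay_oracle(sim_params(N_e = 25, L = 1e4, mu = 5e-5, r = 1e-4,
                         n_generations = 250, sample_size = 10, seed = 1))$pass
#> [1] TRUE
```

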