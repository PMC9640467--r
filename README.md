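# pepmc

Iterative Monte Carlo design of protein-bound peptides containing
non-natural amino acids (NNAAs), driven by a consensus of multiple
protein–ligand scoring functions or by a Metropolis–Hastings criterion.

Therapeutic peptides are potent and specific but easy to proteolyse;
replacing selected residues with side-chain-modified monomers can fix that
without disturbing the backbone. `pepmc` is for structural bioinformaticians
who have a protein–peptide complex and want to explore single-point
substitutions over a curated monomer alphabet, accepting or rejecting each
candidate from noisy, mutually disagreeing affinity scores.

## The method

Starting from a prepared complex, each iteration

1. proposes a single-point mutation: a position uniform over the mutable
   set, a replacement uniform over the allowed monomer alphabet;
2. rebuilds and samples the mutated complex through a pluggable backend
   (contract: fixed-backbone substitution, flexible-side-chain relax, Backrub
   sampling with 20,000 trials at kT 1.2, scoring the **last** frame);
3. scores the new frame with the registered scoring functions, oriented so
   lower is always better (scorers whose raw output rises with affinity are
   negated);
4. decides acceptance. With *N* scorers and per-scorer deltas
   Δᵢ = scoreᵢ(candidate) − scoreᵢ(reference), the **consensus rule** accepts
   iff |{i : Δᵢ < 0}| ≥ n (default 4 of 6). With a single scorer the
   **Metropolis rule** accepts surely when Δ ≤ 0 and with probability
   exp(−Δ/T) otherwise, T an effective temperature in score units (usual
   range 1–10).

Accepted candidates become the new reference; after a fixed attempt budget
(default 100 proposals) the accepted chain is reported as a candidate pool,
ranked by consensus strength.

Around the engine the package provides:

- **Monomer library** — load/compute/classify monomer chemistry from SMILES
  (logP and formal charge at pH 7 on the acetyl/methylamide-capped residue,
  molecular weight of the free monomer, isoelectric point), a strict
  below-300 Da filter for NNAAs, three-axis grouping
  (hydrophobicity/charge/size) with editable thresholds, and a
  glycine-flanked **G-X-G** tripeptide builder (MDL MOL plus backbone /
  connection flags) for downstream parameterization.
- **Benchmark harness** — for pairs of complexes with known affinities,
  count how many scorers rank the tight binder correctly (strict sign
  agreement; ties never match) and summarize a dataset at a consensus
  threshold.
- **Synthetic planted landscape** — an additive energy table with a known
  optimum plus Gaussian-noise scorer ensembles, so the whole loop is testable
  with no molecular-modelling software installed.

## Worked example

Design over the bundled synthetic protease–peptide complex, restricting the
alphabet to neutral, hydrophobic, medium-size monomers, with the mock
backend and a six-scorer synthetic ensemble:

```r
library(pepmc)

lib   <- filter_by_mw(example_monomer_library(), 300)
alpha <- subset_alphabet(lib, hydrophobicity = "hydrophobic",
                         charge = "neutral", size = "medium")
state <- prepare(system.file("extdata", "granzymeH_complex_synthetic.pdb",
                             package = "pepmc"), "B")
land  <- generate_landscape(length(state$sequence),
                            union(alpha$code, unclass(state$sequence)),
                            gap = 1, seed = 10)
scorers <- make_ensemble(land, n_scorers = 6, noise_sd = 0.25, seed = 10)

cfg <- design_config(mutable_positions = c(2, 4, 6, 8), alphabet = alpha,
                     acceptance = list(mode = "consensus", n_required = 4),
                     attempts = 100, seed = 10)
res <- run_design(state, cfg, scorers)
res
#> design_result: 100 attempts, 7 accepted
#>   start: PTSYAGDDS
#>   final: P[G5G]SIA[MKD]D[MKD]S
summarize_accepted(res)
#>    step      mutation                  sequence
#> 1     1     G-6-[41H]             PTSYA[41H]DDS
#> 2     2         T-2-I             PISYA[41H]DDS
#> 3     3     D-8-[MKD]         PISYA[41H]D[MKD]S
#> 4     4     Y-4-[NLE]     PIS[NLE]A[41H]D[MKD]S
#> 6     6     I-2-[G5G] P[G5G]S[NLE]A[41H]D[MKD]S
#> 11   11 [41H]-6-[MKD] P[G5G]S[NLE]A[MKD]D[MKD]S
#> 43   43     [NLE]-4-I     P[G5G]SIA[MKD]D[MKD]S
```

Of 100 attempted mutations, 7 were accepted by the 4-of-6 consensus; each
row is one accepted event (`[old]-position-[new]`, then the updated
sequence, NNAAs bracketed). `score_trajectory(res)` returns each scorer's
oriented score at step 0 and at every accepted step — series may be
non-monotone per scorer even though the consensus improved, which is exactly
the failure mode the consensus is there to absorb. `write_design_run(res,
dir)` emits `records.tsv`, `accepted.tsv`, `trajectory.csv`, the resolved
config and the seed.

Thin command-line wrappers over the same functions live in `inst/cli/`
(`classify-monomers.R`, `design.R`, `make-fixtures.R`).

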