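---
title: "Consensus-driven Monte Carlo design of modified peptides: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-driven Monte Carlo design of modified peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmc)
```

## The design problem

A peptide bound to a protein target is optimized by iterated single-point
substitution. The search space is the set of sequences over a monomer
alphabet (natural amino acids plus side-chain-modified non-natural amino
acids, NNAAs) at a fixed set of mutable positions; the objective — binding
affinity — is only available through noisy, mutually inconsistent scoring
functions evaluated on sampled conformations. `pepmc` treats this as a
stochastic hill-climb with two acceptance rules:

* **Consensus.** With $N$ oriented scorers (lower = better) and deltas
  $\Delta_i = s_i(\text{candidate}) - s_i(\text{reference})$, accept iff
  $\#\{i : \Delta_i < 0\} \ge n$. The rule uses only delta *signs*, so it is
  invariant to per-scorer rescaling and insensitive to scorers with wild
  magnitudes. Under pure symmetric noise each sign is a fair coin, so the
  null acceptance rate is $P(\mathrm{Bin}(N, 1/2) \ge n)$ — for the default
  4-of-6, $22/64 \approx 0.344$. That number is the yardstick the tests hold
  the engine to.
* **Metropolis–Hastings** (single scorer). Accept surely when
  $\Delta \le 0$, else with probability $\exp(-\Delta/T)$. $T$ is an
  *effective temperature in oriented-score units*; no cross-scorer
  normalization is applied, which is why this mode is restricted to one
  scoring function. The constructor warns outside the usual range
  $1 \le T \le 10$ but allows any $T > 0$; as $T \to 0^+$ the rule becomes
  greedy strict descent.

Tie handling is strict in both modes of the consensus count: $\Delta_i = 0$
is *not* favorable. Consequences: an identity substitution can never be
consensus-accepted, and a scorer returning identical values on both frames
votes against the move. A `ties_favorable` flag restores non-strict
comparison for sensitivity analyses.

A scorer that fails (non-finite raw value) *abstains*: its delta is `NA`,
it contributes no favorable vote, and the required count `n` is unchanged.
Abstention can therefore only hinder acceptance, which is the conservative
direction for a screening tool.

## Loop state and reference handling

The reference complex is scored from its own sampled frame at
initialization, so the first comparison is frame-to-frame rather than
frame-to-crystal. On acceptance, the candidate's frame and scores become the
reference without resampling; on rejection the reference is reused. Reusing
the reference avoids random-walk drift of the baseline but correlates
consecutive attempts through the shared reference noise. The engine
therefore exposes `rescore_reference`: when `TRUE`, the reference frame is
re-scored on every attempt, making attempts statistically independent — the
configuration under which the zero-signal null calibration is exact. The
default is `FALSE` (reuse), the behavior appropriate for production runs.

The attempt budget counts *proposals*, not acceptances (100 proposals
typically yield a handful of accepted moves at 4-of-6). The candidate pool
ranks accepted records by consensus count, breaking ties by the sum of
z-scored oriented deltas; the protocol computes both quantities anyway, and
the z-scoring keeps scorers with large score units from dominating the
tie-break.

Reproducibility: one root seed is split into three independent
L'Ecuyer-CMRG streams — proposals, Metropolis draws, synthetic scorer
noise — so changing the scorer set does not perturb the proposal sequence,
and two runs with identical configuration and seed produce byte-identical
logs (a tested invariant). When a scorer ensemble is passed to `run_design`,
its noise stream is re-derived from the design seed for the same reason.

## Monomer chemistry and classification

Properties are computed from SMILES through OpenBabel. Input SMILES follow a
documented convention: the free amino acid written N-to-C, starting at the
backbone nitrogen and ending with the carboxylic acid (`...C(=O)O`). Under
that convention, N-acetyl / C-methylamide capping and glycine-flanked
tripeptide assembly are exact string operations whose products are
re-parsed and validated; inputs violating the convention raise a chemistry
error rather than a silently wrong molecule.

Per monomer:

* **logP** — OpenBabel's atom-contribution estimate on the capped residue,
  so the value reflects the residue in a peptide context rather than the
  zwitterionic free acid.
* **Net charge at pH 7** — Henderson–Hasselbalch over SMARTS-detected
  side-chain ionizable groups on the capped form (carboxyl pKa 4.0, aliphatic
  amine 10.5, guanidinium 12.5, imidazole 6.0, phenol 10.0, thiol 8.3).
  Backbone amine and acid are amides after capping and match no pattern, so
  capping automatically restricts the inventory to the side chain. Formal
  charge at pH 7, not partial-charge sums, is the implemented reading of
  "charge".
* **Isoelectric point** — computed on the *free* monomer's inventory
  (side-chain groups plus backbone α-amine pKa 9.0 and α-carboxyl pKa 2.3),
  solved by bisection of the net-charge curve on pH 0–14. A capped residue
  with a non-ionizable side chain has identically zero charge and hence no
  defined pI; the free-monomer pI is the only well-defined per-monomer
  quantity, and it reproduces the familiar ordering (aspartate ≈ 3.1,
  glycine ≈ 5.7, arginine ≈ 10.8).
* **Molecular weight** — of the free monomer; this is the quantity the
  design-alphabet filter uses. The filter is strict (`< 300` Da) and applies
  to NNAAs only — the natural alphabet is always retained.

Classification assigns exactly one label per axis. Charge: net charge
≥ +0.5 → positive, ≤ −0.5 → negative, else neutral (pI cutoffs 8.0/6.0 are a
fallback when net charge is unavailable). Hydrophobicity: any non-neutral
charge group → *charged* (so "charged" always implies a non-neutral charge
label); otherwise capped logP ≥ 1.0 → hydrophobic, else polar. Size:
MW ≤ 120 Da → small, ≥ 180 Da → large, else medium. These cutoffs are
package defaults, chosen to reproduce textbook assignments for the natural
alphabet (leucine hydrophobic/neutral, glycine small, arginine positive,
tryptophan large); they are *not* canonical constants, and
`classification_thresholds()` + YAML round-trip make them fully editable.
Chirality is recorded but never used in classification — all properties here
are 2D.

Several bundled NNAA codes (54C, G5G, C1J, KHB) carry synthetic stand-in
structures: plausible side-chain-only modified α-amino acids used for
examples and tests, not the chemical-component-dictionary entries of the
same name. ORN (ornithine), MKD (2-amino-2-methyloctanoic acid) and 41H
(α-methyl-phenylalanine) use their known identities.

## The sampling backend contract

`mutate_and_sample` must return the *last frame* of the sampling trajectory
with the mutated sequence; how the backend gets there is its own business.
The Rosetta adapter builds command templates (fixed-backbone design from a
per-mutation resfile, flexible-side-chain relax, Backrub with
`-backrub:ntrials 20000 -backrub:mc_kt 1.2` by default — parameters
previously tuned for protein–peptide complexes) and is exercised in tests
only at the command-construction level; no external software is run. The
mock backend is a pure function of (state, mutation, seed) returning a
deterministic frame token, which is what makes whole-run byte-identity
testable. Protonation is a backend responsibility; the mock is a no-op.

## What the synthetic landscape does and does not emulate

`generate_landscape` draws iid normal per-(position, code) energies and
enforces a minimum per-position gap between the best code and the runner-up,
so the global optimum is the unique per-position argmin. Scorer ensembles
add iid Gaussian noise (optionally per-scorer biases) to the true energy,
independently for every evaluation — including the reference's, mirroring a
protocol that re-scores sampled frames. This gives closed forms the tests
lean on: the probability a scorer favors a true improvement $d$ under two
independently noised evaluations is $\Phi(|d|/(\sigma\sqrt{2}))$, and the
zero-signal acceptance null is exact.

Deliberately missing from the emulation: epistasis (real binding
free-energy surfaces are not additive over positions), structure-dependent
or heavy-tailed scorer error, inter-scorer error correlation, and any
relationship between monomer chemistry and landscape energy. Tests passing
on this landscape therefore validate the *engine* — bookkeeping, acceptance
statistics, reproducibility, signal-vs-noise behavior — not the accuracy of
any real scoring function on real complexes.

Benchmark affinities are mapped from true energies by a fixed exponential
(one energy unit = 10-fold in nM by default) so scenarios with prescribed
fold-differences can be posed; affinities are compared only within a pair.

## Problem sizes and tolerances used by the checks

The statistical suites run at: 10,000 attempts for the zero-signal null
(binomial 3σ ≈ 0.014 around 0.34375); 100,000 draws for Metropolis
calibration at $\Delta = T\ln 2$ (3σ ≈ 0.0047 around 0.5); and, for
planted-optimum recovery, a length-9 landscape over the 20-letter natural
alphabet with unit minimum gap, per-scorer noise σ = 0.25 × gap, 4 mutable
positions, 300 attempts, 50 seeded runs, requiring ≥ 80% of runs to end at
the optimum and the 4-of-6 consensus to beat the noisiest single scorer
(greedy, same budget) on mean final true energy, paired over seeds. These
sizes were chosen so each check's sampling error is several times smaller
than the effect it measures.

## Known limitations

* Single-point substitutions only: no insertions, deletions, multi-point
  moves, or backbone modification; the monomer convention assumes an intact
  α-backbone.
* The pKa table covers the common ionizable side-chain motifs; exotic
  ionizable groups (e.g. phosphonates) would need new SMARTS/pKa entries.
* Metropolis mode has no per-scorer temperature calibration; consensus mode
  has no weighting — every scorer's vote counts equally, including a
  systematically wrong one (the benchmark harness exists to detect those).
* The Rosetta adapter is a contract, not a tested integration; running it
  requires a local installation and parameter files for every NNAA.
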