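Package: pepmc
Title: Monte Carlo Design of Protein-Bound Modified Peptides with Consensus Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative single-point-mutation optimization of peptides bound to
    protein targets, supporting non-natural amino acids (NNAAs). Mutations are
    proposed over a user-defined alphabet of monomers, candidate complexes are
    sampled through a pluggable conformational backend, and moves are accepted
    either by a consensus of multiple protein-ligand scoring functions or by a
    Metropolis-Hastings criterion with an effective temperature. Includes a
    monomer classification pipeline (logP, formal charge at pH 7, isoelectric
    point, molecular weight, and three-axis physico-chemical grouping computed
    from SMILES), a glycine-flanked tripeptide builder for monomer
    parameterization, a benchmark harness that scores rank-agreement of scorer
    ensembles on pairs of complexes with known binding affinities, and a
    synthetic planted additive landscape with noisy scorer ensembles so the
    whole engine is testable without external molecular-modelling software.
License: MIT
Encoding: UTF-8
Imports:
    ChemmineR,
    bio3d,
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
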