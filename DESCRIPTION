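Package: maexpr
Title: Mutational Effects on Gene Expression in Mutation Accumulation Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for transcriptome data from mutation
    accumulation (MA) experiments. Estimates the mutational variance of
    per-gene expression with a Poisson mixed model carrying a per-line
    random slope and an observation-level random effect, infers the
    distribution of expression effects (DEE) of single de novo mutations
    as a zero-spike shifted-gamma mixture fitted by seeded stochastic
    annealing, calls per-line differentially expressed genes against the
    unmutated ancestor with a simplified negative-binomial Wald test,
    runs permutation tests for cis-acting mutation proximity, UTR
    enrichment and structural-variant overlap, builds a soft-threshold
    co-expression network (topological overlap, modules, hubs) and tests
    DEG clustering by expression-matched shortest-path permutation, and
    regresses line fitness on expression divergence. A synthetic-data
    module generates complete toy experiments with known truth so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    igraph,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
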