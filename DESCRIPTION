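Package: epiGRN
Title: Hub-Centered Genetic Regulatory Networks from SNP Association and
    Epistasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dissects the genetic regulatory network around a transcription
    factor hub gene in a panel of unrelated individuals. Candidate targets are
    nominated by exact promoter motif scanning intersected with strong
    co-expression; each SNP is tested for genotypic, additive and dominance
    effects by least squares with population-structure covariates; SNP pairs
    are decomposed into additive-by-additive, additive-by-dominance,
    dominance-by-additive and dominance-by-dominance epistatic components
    with allele/genotype combination effect tables; multiple testing is
    controlled by Benjamini-Hochberg FDR; linkage disequilibrium decay is
    fitted with the Hill-Weir expected-r2 curve; and significant epistatic
    pairs are assembled into a layered, hub-centered gene-gene interaction
    network. A synthetic-data module simulates genotypes under
    Hardy-Weinberg equilibrium with optional LD blocks, phenotypes from
    additive/dominance/epistatic genetic values, tissue expression profiles
    with planted hub correlations, and promoters with motifs planted at known
    offsets, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    igraph,
    jsonlite,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
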