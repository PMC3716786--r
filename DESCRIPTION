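Package: linehap
Title: Haplotype Population Size Estimation via Line-Graph Editing of
    Clark-Consistency Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the number of distinct haplotypes underlying a sample
    of unphased genotypes without phasing them. Builds the Clark-consistency
    graph of potential haplotype sharing between individuals, transforms it
    into a line graph by a minimum number of edge and/or node deletions
    (exact integer programming, solved with GLPK), reconstructs the root
    graph whose nodes are haplotypes, and counts them. Also provides the
    pure-parsimony haplotype count, a constraint-generation phasing loop,
    and coalescent population simulators (bottleneck and recombinant
    scenarios) with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
SystemRequirements: GLPK standalone solver (glpsol) on the PATH; optional
    Python with msprime for the recombinant-population simulator.
Config/testthat/edition: 3
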