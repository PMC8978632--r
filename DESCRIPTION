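Package: streamlinr
Title: Genome Streamlining Analysis Along a pH Gradient
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for comparative-genomics analyses of genome
    streamlining in acidophilic bacteria. From per-genome sequences (FASTA),
    gene features (GFF3), predicted proteomes and annotation tables it builds
    quality-gated, ANI-defined species clusters, within-proteome homolog
    families by the reciprocal-best-hit rule, subcellular and functional
    (COG/Pfam) proteome profiles, and genome-size decomposition metrics, then
    screens traits and conserved protein families for trends against optimal
    growth pH using Pearson correlation, feasible generalized least squares,
    exact binomial tests, Benjamini-Hochberg false-discovery control and
    principal component analysis. A synthetic-cohort generator plants known
    pH-dependent effects so every stage can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
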