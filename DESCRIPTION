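Package: CoexDiff
Title: Untargeted Detection of Differentially Coexpressed Gene Modules
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Clusters genes into modules by changes in their pairwise
    coexpression between two or more sample conditions, rather than by
    coexpression itself. Builds a soft-thresholded adjacency matrix of
    signed-squared correlation changes, converts it to a topological
    overlap dissimilarity, extracts modules by hierarchical clustering
    with an adaptive tree cut (or PAM), and assesses module-level and
    module-to-module coexpression change with a dispersion statistic
    against a sample-permutation null. Includes a latent-factor
    simulator that plants differential-coexpression scenarios with
    ground-truth module labels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, cluster
Suggests: testthat (>= 3.0.0), mclust, jsonlite, optparse
Config/testthat/edition: 3
biocViews: GeneExpression, Network, Clustering, DifferentialExpression
RoxygenNote: 7.3.3
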