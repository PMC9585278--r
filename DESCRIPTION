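Package: ProtSphere
Title: Fuzzy Spherically Truncated Multi-Linear 3D Protein Descriptors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free three-dimensional protein descriptors computed
    from spherically truncated inter-residue (dis)similarity tensors. Each
    protein is reduced to one point per residue (C-alpha, C-beta, amide-bond
    midpoint or heavy-atom centroid), embedded in a sphere centred on its
    geometric centre, and residue pair/triple relationships are smoothed by
    fuzzy membership functions of the residue-to-centre distance before
    bilinear and trilinear algebraic forms weighted by amino-acid property
    scales are aggregated into global descriptors. Includes thirteen fuzzy
    membership functions and three molecular-dynamics smoothing functions,
    tensor normalization and Hadamard powers, lag and group filters, a
    deterministic descriptor naming grammar, and exploratory statistics
    (distance-bin distributions, membership summaries, Ward clustering of
    truncation functions, Shannon-entropy variability, varimax-rotated PCA
    loadings).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
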