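Package: pheseq
Title: Bayesian Deep-Learning Fusion of Association p-Values and Phenotype Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses per-gene association p-values from sequence analysis with
    phenotype-description embeddings to prioritize gene-disease associations.
    A beta-uniform mixture models the p-values, a latent switch variable
    routes each gene through the significant or null component, and a neural
    perception network maps each gene's embedding to its mixture parameters.
    Two fitting strategies are provided: a Static variant with fixed input
    embeddings trained by Monte-Carlo maximum-likelihood gradient ascent, and
    a Dynamic variant that jointly learns a variational-autoencoder latent
    embedding by alternating MAP updates and stochastic gradient steps on the
    evidence lower bound. Includes significance calling (Benjamini-Hochberg
    and fixed-cutoff), benchmark recall evaluation, a synthetic-data
    generator reproducing the assumed data structure, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
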