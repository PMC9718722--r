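Package: htmarginal
Title: Low-Rank Tensor Computation of Time-Marginal Distributions for
    Interacting-Automata Markov Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the time-marginal distribution of continuous-time Markov
    chains with separable transition rates, such as Mutual Hazard Networks for
    tumor progression and more general stochastic automata networks. The
    infinitesimal generator is assembled as a sum of Kronecker products (CP
    format), distributions are represented in the hierarchical Tucker tensor
    format with SVD-based truncation, and the marginal distribution -- the
    solution of (Id - Q) p = p(0) -- is computed by a normalized truncated
    uniformization (Neumann-series) iteration whose iterates sum to one.
    Includes dense reference solvers for validation at small dimension,
    generators for block-structured synthetic parameter matrices, and
    diagnostics (node singular values, effective ranks, storage models, and
    Kullback-Leibler divergence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
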