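Package: olfec
Title: Layer-Wise Efficient Coding of Early Olfactory Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and optimization toolkit for studying efficient coding
    in early olfactory processing. Generates structured sparse odor
    environments (Gamma-distributed odorant frequencies, Gaussian-copula block
    correlations, log-normal concentrations), encodes them through a
    receptor/neuron/glomerulus circuit with Hill-function receptor activation
    and Gaussian neural noise, and maximizes a variational Jensen-Shannon
    lower bound on mutual information over each circuit layer under
    positivity and simplex constraints via mirror descent. Includes the
    diagnostic statistics used to characterize optimized circuits: sensing
    sparsity, specialist receptors, odorant dynamic range, canonical
    expression score, robust receptor coexpression, effective rank,
    glomerular purity, and activity-histogram entropy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
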