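Package: mutnet
Title: Eco-Evolutionary Assembly, Architecture and Invasibility of
    Bipartite Mutualistic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the assembly of bipartite mutualistic networks
    (animals and plants) by adaptive-dynamics trait evolution with
    Lotka-Volterra competition and a Holling type II mutualistic
    functional response. Communities diversify by evolutionary branching
    at convergence-stable fitness minima; the emerging quantitative
    interaction networks are scored with weighted architecture metrics
    (H2' specialization, quantitative connectance, WNODF nestedness,
    Barber bipartite modularity) and stability metrics (resilience,
    robustness, disruptiveness, invasibility). An invasion-trial engine
    introduces alien animal species under configurable trait,
    generalization, propagule-size and introduction-schedule scenarios
    and measures invasiveness and impact on the native community.
    Ensemble tools sweep the interaction-kernel parameter space and
    correlate architecture, stability and invasion outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    vegan,
    optparse,
    yaml
Config/testthat/edition: 3
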