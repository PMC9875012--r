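Package: neuroenergy
Title: Energy Efficiency and Information Coding of Hodgkin-Huxley Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of Hodgkin-Huxley neurons coupled by gap
    junctions (electrical synapses) on directed graphs and analyses their
    metabolic energy budget and information throughput. Provides generators
    for directed Barabasi-Albert, Erdos-Renyi and Watts-Strogatz graphs
    matched to the Caenorhabditis elegans connectome scale (297 neurons,
    about 2,345 directed edges) plus a connectome file loader; a fast RK4
    integrator for the coupled membrane equations with optional Gaussian
    white noise current; an equivalent-circuit decomposition of the power
    budget (stimulus power, ion-channel power, gap-junction and amplifier
    terms, Nernst-potential versus passive-transport split); the
    negative-energy-ratio synchronization index; binned-word entropy-rate
    estimation of spike trains; and orchestration of coupling-strength,
    bin-width and noise sweeps yielding tidy result tables of energy
    consumption rate, information rate and energy efficiency (bits per nJ).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
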