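Package: pcpsim
Title: Stochastic Reaction-Diffusion Simulation of Planar Cell Polarity on
    Periodic Epithelial Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the establishment of planar cell polarity (PCP) by
    binding/unbinding kinetics of cross-junctional membrane-protein complexes
    on periodic polygonal tissues.  Cells exchange Frizzled- and Van
    Gogh-type complexes across shared junctions; complexes on different
    junctions of the same cell interact through nonlocal cytoplasmic
    kernels with an exponential length scale.  The package generates
    hexagonal and geometrically disordered tissues (periodic Voronoi
    construction), applies area-preserving elongation and mutant clones,
    integrates the stochastic dynamics with a fourth-order Runge-Kutta
    scheme plus additive Gaussian noise, and computes polarity observables:
    cell dipoles, global order parameters, angular statistics and the
    orientational correlation length.  Bifurcation tools locate the
    junctional polarization threshold, and scripted experiment drivers
    reproduce interaction-length sweeps, stability comparisons, cue
    detection, elongated-tissue and mutant-clone studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
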