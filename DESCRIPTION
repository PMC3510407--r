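Package: glioxide
Title: Vaso-Occlusion, Hypoxic Cell Waves and Pseudopalisade Morphometry in
    Glioblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a one-dimensional continuum model of glioblastoma
    growth between two boundary capillaries: normoxic and hypoxic tumour
    phenotypes switch under oxygen control, hypoxic cells die under
    persistent anoxia and accumulate as necrotic tissue, and the oxygen
    field obeys reaction-diffusion dynamics with Michaelis-Menten uptake
    and transmural capillary exchange at the boundaries. Vessels can
    thrombose on a schedule, triggering hypoxic cell waves that assemble
    into perinecrotic pseudopalisades. The package provides the
    semi-discrete finite-difference model, explicit Runge-Kutta and stiff
    integrators, scenario constructors for the canonical single-occlusion,
    two-colony and no-occlusion experiments, and morphometric analyses
    (palisade width and lifetime, necrotic core width, phenotype-switch
    completion, vessel invasion time, inter-vessel distance sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
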