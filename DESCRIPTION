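Package: wallscrew
Title: Dipolar Order Parameters and Chemical-Shift Conformation Analysis for
    Cell-Wall Polysaccharide MAS NMR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and fitting tools for solid-state magic-angle-spinning
    (MAS) NMR studies of plant cell-wall polysaccharide conformation and
    mobility. Simulates DIPSHIFT C-H dipolar dephasing curves under MAS with
    powder averaging (single C-H pairs and exact two-proton CH2 systems),
    fits dipolar order parameters S_CH with a chi-square-scan uncertainty
    estimate, fits spin-lattice relaxation times T1 from saturation-recovery
    series, computes conformation-dependent 13C chemical-shift differences
    (twofold versus threefold helical screw xylan), classifies observed shift
    sets by nearest reference conformation, and predicts refocused INADEQUATE
    double-quantum peak lists from bonded-carbon assignments. A seeded
    synthetic-data generator emulates rigid cellulose-bound twofold xylan and
    mobile threefold xylan populations for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
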