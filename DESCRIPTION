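Package: tadecomp
Title: Decomposition of Femtosecond Transient-Absorption Data from Retinal Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to isolate pure-species photodynamics from femtosecond
    pump-probe transient-absorption (TA) maps of mixed retinal-protein samples,
    as arises for dark-adapted bacteriorhodopsin (an all-trans / 13-cis isomer
    mixture) and for two-pump probing of the K photocycle intermediate.
    Provides dynamic-difference-spectrum (delta-delta-OD) scale-factor
    inference, coherent-oscillation and NIR stimulated-emission population
    markers, weighted spectral subtraction, steady-state absorption
    decomposition, multi-exponential kinetic fitting by variable projection,
    damped-cosine coherence analysis, pump-probe anisotropy, and band-integral
    photoisomerization quantum-yield estimation, together with a synthetic
    TA-map generator that emulates the experiments so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
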