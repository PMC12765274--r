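Package: chirpsifter
Title: Shaped-Pulse Design, Bloch Simulation and Processing for Broadband
    Pulsed Dipolar EPR (SIFTER)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for broadband pulsed dipolar electron paramagnetic
    resonance with linearly chirped WURST pulses. Constructs and
    resonator-corrects chirp waveforms; propagates spin ensembles through
    pulse sequences by Bloch-vector simulation, including B1-inhomogeneity
    averaging and echo phase/fidelity analysis; solves the linear
    refocusing condition for pulse-length ratios over arbitrary coherence
    pathways with exact rational arithmetic; simulates orientation-selective
    two-dimensional SIFTER data for rigid nitroxide spin pairs; and
    processes 2D SIFTER data (echo Fourier transform, excitation-profile
    correction, SIDRE and exponential background division, 2D dipolar
    Fourier transform, and Tikhonov inversion to distance distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
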