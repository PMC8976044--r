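Package: ringblock
Title: Block-Based Single-Particle Reconstruction and Analysis of Cyclic
    Ring Assemblies
Version: 0.1.0
Authors@R:
    person("Ringblock", "Developers", email = "ringblock@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for block-based (subparticle) cryo-EM
    reconstruction of large cyclic assemblies such as the nuclear pore
    complex rings, and for the structural analyses performed on the
    resulting composite models.  Provides particle-metadata (STAR dialect),
    density-volume (MRC2014) and atomic-model (PDB/mmCIF) input/output; a
    synthetic-data generator for C8 ring volumes, tilted-collection
    particle stacks with CTF and noise, and toy atomic models; a toy
    imaging engine (CTF evaluation, central-slice projection,
    Wiener-weighted Fourier-insertion reconstruction, Fourier shell
    correlation); layered raised-cosine masks for focused refinement;
    symmetry expansion, subparticle re-centering with defocus bookkeeping,
    extraction and confined local refinement; composite ring assembly; and
    structural measurements (Kabsch superposition, interface contacts,
    flexible-linker reachability, model census).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
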