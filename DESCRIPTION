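Package: cableml
Title: NeuroML v1.x Model Descriptions and a Reference Compartmental Simulator
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Read, validate, write and execute neuronal models expressed in
    the NeuroML v1.x model-description language. Level 1 (MorphML) branched
    morphologies with integrity checking and path-distance metrics; Level 2
    biophysical cells with ChannelML voltage- and ligand-gated conductances
    (Hodgkin-Huxley gates, Markov kinetic schemes, Q10 scaling, decaying
    calcium pools), chemical synapses with multi-exponential conductance
    waveforms, NMDA-receptor magnesium block, Tsodyks-Markram short-term
    plasticity, additive spike-timing-dependent plasticity and gap junctions;
    Level 3 (NetworkML) instance- and template-based network descriptions
    with seeded 3D instantiation. A reference simulator discretizes cells
    into equivalent-cylinder compartment trees under symmetric or asymmetric
    axial-resistance conventions, integrates the branched cable equation
    implicitly, and compares runs by a spike-time convergence criterion
    suited to cross-simulator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
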