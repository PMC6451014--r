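Package: protspace
Title: Protein Sequence Space Maps from Evolutionary Distances
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds low-dimensional "sequence space" maps of aligned protein
    families. Pairwise evolutionary distances are estimated by maximum
    likelihood under the empirical Dayhoff (PAM) amino-acid replacement
    model, embedded into two or three dimensions by Sammon non-linear
    mapping, and a phylogenetic tree (imported from Newick or built by
    neighbor-joining) is overlaid on the embedded points. Quantitative
    diagnostics (Sammon stress, Shepard data, restart stability,
    Procrustes superposition, per-group spread statistics) turn visual
    claims about compact versus widely spread lineages into measurable
    quantities. A forward sequence-evolution simulator generates alignments
    along known trees so every step can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
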