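Package: scaffoldTrees
Title: Molecular Scaffold Extraction, Dissection and Scaffold Tree/Network Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts five kinds of molecular scaffolds (scaffold, Murcko
    framework, elemental wireframe, basic framework, basic wireframe) from
    molecules read from SDF or SMILES input, dissects scaffolds into rings,
    linkers and terminal side chains, generates parent scaffolds either
    enumeratively or with the 13 Schuffenhauer prioritisation rules, and
    assembles the results into scaffold trees, forests and networks with
    virtual/non-virtual origin tracking, frequency counts and adjacency,
    DOT and GraphML export. Ring perception uses relevant cycles (the union
    of all minimum cycle bases) with a minimum-cycle-basis fallback.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
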