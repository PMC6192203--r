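Package: CliqueSite
Title: Ligand Binding-Site and Catalytic-Site Detection by Clique-Based Template Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects active sites and small-molecule ligand binding sites in
    protein structures by matching residue templates of known sites against a
    query structure. Candidate residue correspondences are modelled as an
    association (product) graph whose maximal cliques are rigid sub-structure
    matches; matches are superposed by the Kabsch algorithm and ranked by a
    composite score combining clique size, RMSD and the relative size of the
    SMILES-similarity cluster containing the template's ligand. Includes a
    template-library builder and file format, ligand fingerprint clustering,
    an interface mode for sites spanning several chains, and a synthetic
    planted-site fixture generator for benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ChemmineOB
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
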