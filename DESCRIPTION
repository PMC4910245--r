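Package: sbgnq
Title: Qualitative Dynamics Semantics for SBGN Process Description Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds executable qualitative models from SBGN Process
    Description (SBGN-PD) reaction maps. Two semantics are provided: a
    general semantics in which every entity pool node is a Boolean
    present/absent variable and every process an occurring/non-occurring
    variable, and a stories semantics in which sets of entity pool nodes
    representing mutually exclusive physical states of one molecular
    entity ("stories") are collapsed into single multi-valued variables.
    Maps are read from SBGN-ML or from a plain-text fixture format,
    stories are enumerated under their defining constraints, and both
    semantics are compiled into asynchronous automata networks whose
    dynamics can be analyzed exhaustively: state transition graphs,
    attractors, reachability of markers and phases, and export to
    1-bounded Petri nets (PNML) and JSON.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
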