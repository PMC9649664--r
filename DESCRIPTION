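Package: isatree
Title: Standardised Project/Investigation/Study/Assay Directory Trees for
    FAIR Data Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Creates, inspects, validates, exports and synchronises
    standardised directory trees for life-science research projects
    following the ISA model (project/Investigation/Study/Assay).  Each
    level carries a tab-delimited key-value metadata file generated from
    editable text templates.  Tools are provided to scaffold new levels,
    render the tree, aggregate and cross-check metadata completeness,
    check path-length portability limits, convert an investigation to
    ISA-Tab, and plan or execute bulk uploads to a SEEK/FAIRDOMHub-style
    repository (with an offline mock endpoint for testing).  Deterministic
    example-project generators are included for demonstration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
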