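# isatree

Standardised project directory trees for FAIR life-science data
management, in R.

## The problem

During a research project, data and metadata usually live on a lab
share long before they reach a public repository — often with no
agreed structure and no metadata at all. `isatree` organises each
**p**roject as a directory tree of three nested ISA-model levels —
**I**nvestigation, **S**tudy, **A**ssay — where every level directory
carries a fixed prefix (`_p_`, `_I_`, `_S_`, `_A_`) and a plain-text
metadata file of tab-delimited key-value pairs:

```
Title:	<value>
Upload to FAIRDOMHub:	Yes
Sharing permission:	Private
```

Assays come in two classes — `wet` (laboratory experiment, with an
`output/raw` directory for instrument data) and `dry` (data analysis,
with `input`, `scripts` and `output`) — refined into editable
text-template *types* (RNA isolation, qPCR, sequencing analysis, ...)
that define the questions asked at creation time. The master sample
table (`phenodata_yyyymmdd.txt`) and the measured-variable table
(`featuredata_yyyymmdd.txt`) live at the investigation level so that
sample identifiers are unique across studies; filename date stamps
version them.

On top of this layout the package provides:

- **Scaffolding** — `init_tree_root()`, `make_level()`: create levels
  with prompts resolved from templates, strict p→I→S→A nesting, no
  overwrites.
- **Inspection** — `show_tree()` (TREE.TXT), `show_metadata()`
  (plain/markdown), `xcheck_metadata()` (missing mandatory fields),
  `check_path_lengths()` (the 247-character Windows path limit).
- **Programmatic access** — `resolve_chain()`, `get_meta()`,
  `latest_table()` for use inside analysis pipelines.
- **ISA-Tab export** — `build_isatab()` / `write_isatab()` /
  `validate_isatab_structure()` convert one investigation into
  `i_`/`s_`/`a_` files, mapping metadata keys via an editable flat
  mapping file and preserving unmapped pairs as `Comment[...]` fields.
- **Repository upload** — `files_to_upload()`, `build_upload_plan()`
  and `execute_plan()` plan and run a bulk upload of an investigation
  to a SEEK/FAIRDOMHub-style endpoint, honouring `seekignore.txt`
  patterns, per-level `Upload to FAIRDOMHub` gates, and the
  assay-only file-attachment convention (synthetic "Investigation
  files" study, study-named assays). An in-memory mock endpoint makes
  the whole flow testable offline.
- **Example generators** — `generate_cpb_fixture()`,
  `generate_strt_fixture()`, `generate_random_tree()` build
  deterministic demonstration trees.

A thin command-line wrapper is available as `exec/pisa`
(`pisa init|make|tree|meta|check|demo`).

## Worked example

```r
library(isatree)

root <- tempfile(); dir.create(root)
p <- generate_cpb_fixture(root)          # pesticide-project example
rep <- show_tree(p$path, levels_only = TRUE)
rep$counts
#>       project investigation         study         assay
#>             1             3            16            16

nrow(xcheck_metadata(p$path))            # mandatory fields all filled
#> [1] 0

inv <- file.path(p$path, "_I_01_LabTrials")
doc <- build_isatab(inv)
doc
#> <ISA-Tab document: 11 studies, 11 assay files>
nrow(validate_isatab_structure(doc, latest_table(inv, "phenodata")))
#> [1] 0

plan <- build_upload_plan(inv, project_id = 252)
plan
#> <upload plan: project 252, 36 containers, 44 files>
ep <- seek_mock_endpoint()
tr <- execute_plan(plan, ep, project_root = p$path)
sum(tr$created)                          # objects created remotely
#> [1] 80
```

The tree report counts the level directories of the generated
example (3 investigations holding 16 studies, 11 of them under
`_I_01_LabTrials`); the ISA-Tab document holds one sample file per
study and one table per assay, and validates with zero structural
findings; the upload plan turns the investigation into 36 remote
containers and 44 file attachments, all attached at assay level.

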