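---
title: "Standardised ISA directory trees: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardised ISA directory trees: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isatree)
```

## The model

`isatree` manages research data as a four-level directory hierarchy
following the ISA model: a **project** contains **investigations**
(a coherent experimental question or work package), an investigation
contains **studies** (one sample collection / experiment each), and a
study contains **assays** (individual measurements or analysis
steps). The hierarchy is encoded directly in directory names through
fixed prefixes — `_p_`, `_I_`, `_S_`, `_A_` — so the structure is
visible in any file browser and recoverable by parsing basenames
alone. Assay directories additionally carry a `-<AssayType>` suffix.
Because assay *names* may themselves contain hyphens, the type is
taken after the **last** hyphen; the corresponding restriction —
assay type names must not contain hyphens — is enforced when
templates are loaded and when directory names are composed.

Each level carries a metadata file (`_<LEVEL>_METADATA.TXT`) of
tab-delimited key-value pairs, one per line, serialised as
`key + ":" + TAB + value`. The colon belongs to the on-disk form,
not to the key. The files are meant to be edited by hand, which
drives several tolerant-reader choices:

- LF and CRLF both parse; a UTF-8 byte-order mark is stripped
  (files written on Windows often carry one); output is UTF-8
  without BOM and LF-terminated (configurable).
- Metadata filenames are matched case-insensitively on read and
  written in a single canonical upper-case form, so hand-renamed
  files still resolve while output stays deterministic.
- Lines without a tab separator are not errors: they are recorded as
  warnings, kept verbatim in a raw-lines annex at their original
  position, and re-emitted on write, so a parse/write cycle never
  destroys a hand-edited file.
- Duplicate keys are preserved in order and flagged; lookup returns
  the first value with a warning. Erroring here would make a
  hand-edited file unreadable, which is the worse failure mode.
- Key lookup trims surrounding whitespace on both sides; values are
  returned verbatim.
- Values must not contain tabs or newlines — they would be
  indistinguishable from field separators in the dialect — and the
  writer rejects them. Whether hand-editors may insert tabs in
  values is undefined behaviour for the format; we chose to forbid
  and check.

## Templates and prompts

All level questions and assay-type definitions live in a `Templates`
directory (`x.lib` for the four level templates, `WET` and `DRY` for
assay classes) as plain text files in the same key-value dialect, so
extending the system needs no code: dropping a new
`<Type>_Template.txt` into a class directory makes the type
available on the next load. A prompt line's value defines its kind:

- empty value — free-text prompt;
- `a/b/c` — a menu; the `other:<text>` escape always allows an
  answer outside the menu (interactively, "other" is the last menu
  entry);
- a single non-empty value — a one-entry menu whose entry doubles as
  the **default** for unanswered prompts. This is how
  `Upload to FAIRDOMHub: Yes` becomes the default state of every
  freshly created level.

A leading `!` marks a key mandatory. The format itself does not
record which keys a minimum-reporting standard requires, so some
marking convention is needed; an in-band `!` keeps each template a
single editable text file. Unanswered mandatory prompts are written
with empty values rather than rejected — immediate hard requirements
discourage early scaffolding — and the completeness check
(`xcheck_metadata()`) reports them later.

`common.ini` (same dialect, at the Templates root or beside it)
holds pairs injected into every created level, appended after the
prompt-derived pairs and never overriding them.

Assay classes fix the default working directories: `wet` assays get
`output` and `output/raw` (instrument data), `dry` assays get
`input`, `scripts` and `output`; both get `reports` and `other`, and
a `<Type>_subdirs.txt` file can override the set per type.
Investigations get `reports`, `presentations` and `other`; studies
get `reports`. (Where the published layout table and its prose
disagree on which levels carry `other`, we create the superset; an
extra empty directory is harmless, a missing one is not.) Assay
types may ship seed files from a `<Type>_Files/` directory — the
bundled RNA-isolation type seeds `analytes.txt`, a template table
for per-sample QC measurements.

Creation is strict: levels nest exactly p→I→S→A (the published
figures show assays only inside studies; we enforce that reading),
existing directories are never overwritten, and creation is atomic —
on any failure the partly built directory is removed. Names pass a
sanitiser (spaces to hyphens, `[A-Za-z0-9._-]` only, Windows
reserved basenames rejected) because trees are routinely carried to
Windows network shares. Investigation creation seeds header-only
`phenodata_<date>.txt` and `featuredata_<date>.txt`; the date
defaults to today and is fixable via the `isatree.date` option so
generated trees are byte-stable. Date stamps in table filenames are
treated as opaque version ordinals — the lexicographically greatest
wins — since whether they mean creation or last edit is a
user convention.

## Inspection and validation

`show_tree()` and `show_metadata()` are read-only apart from writing
their report files (`TREE.TXT`, `METADATA.TXT`/`.md`, which are
excluded from their own listings so repeated runs are
byte-identical). Sibling order is case-insensitive lexicographic
everywhere, which makes every report deterministic. Findings from
`xcheck_metadata()` and `check_path_lengths()` are sorted by path
then key for the same reason.

The path-length check exists because Windows caps paths at 247
characters unless the registry is changed. Since a tree is usually
*checked* on one machine and *used* on another, the check measures
each file's absolute length under a configurable `mount_prefix`
(defaulting to the tree's actual location): a path of 247 characters
passes, 248 is flagged.

## ISA-Tab export

One investigation exports to `i_Investigation.txt` plus one
`s_*.txt` per study and one `a_*.txt` per assay. A flat TSV mapping
file (`map key section field` / `assay type measurement technology`
directives; the bundled default covers the bundled types) routes
metadata keys into investigation-file fields. Three lossless-ness
rules govern everything the mapping does not claim:

- unmapped investigation/study pairs become `Comment[pISA:<key>]`
  fields in their block;
- project-level pairs that cannot be placed become
  `Comment[pISA project:<key>]`;
- assay metadata (ISA-Tab assay files are sample/data tables with no
  metadata section) is carried as
  `Comment[pISA assay <dir>:<key>]` on the owning STUDY block.

Study sample tables are derived from the investigation's phenodata:
a `Study` column (case-insensitive) attributes rows to studies by
study name or directory name; without one, every sample attaches to
every study with a warning — lossy defaults were rejected. Assay
tables pair the study's samples with files found under `output/raw`
(wet, `Raw Data File`) or `output` (dry, `Derived Data File`); when
counts differ the longer side determines the row count and the
shorter is padded, keeping the table total and the sample references
closed. Assay filenames are qualified by study
(`a_<studyDir>.<assayDir>.txt`) because assay directory names are
only unique within a study. The structural validator checks required
sections, referenced-file existence and sample-name closure
(assay ⊆ study ⊆ phenodata); the exporter's output re-parses to an
equal document and re-exports byte-identically. Running an external
ISA validator and importing *from* ISA-Tab are out of scope.

## Repository upload

Upload planning is pure and offline; only `execute_plan()` touches
an endpoint. `seekignore.txt` supplies one glob per line, matched
per path segment at any depth against project-root-relative paths
(so `output/raw` excludes any assay's raw data); there is no
negation — a predictable subset beats gitignore emulation. Levels
opt out via `Upload to FAIRDOMHub: No`, inherited by everything
below.

The remote model attaches files only at assay level, so the plan
synthesises containers: an `Investigation files` study holding an
assay named after the investigation (for investigation-level files,
its own metadata file included), and per study an assay named after
the study (for study-level files). Sharing policy comes from the
owning level's `Sharing permission` key (default `Private` — the
conservative choice) and license from its `License` key (absent key,
no license attribute). Re-running an upload matches existing remote
objects by title within their parent container and creates nothing
new; title-match is a documented convention, chosen because periodic
re-synchronisation is the expected workflow. On failure the
transcript of completed steps travels with the error condition, so a
run is resumable. The package ships an in-memory mock endpoint
implementing the needed API subset (create object, attach blob,
simulated mid-run failure); the remote project itself must pre-exist
(it defines user roles and permissions) and is never created.

## Example generators and what they show

`generate_cpb_fixture()` reproduces the shape of a published
insect-pesticide project: 3 investigations, 16 studies in total, 11
under `_I_01_LabTrials` of which the first three cover dsRNA design
(dry assays) and the remaining eight are feeding trials with wet
RNA-isolation assays carrying `analytes.txt`; each investigation has
a populated phenodata table. `generate_strt_fixture()` reproduces a
transcriptome-assembly project: one investigation, four studies (the
four consecutive bioinformatics procedures), dry assays only, two
per study. Names and counts beyond those published facts are neutral
inventions; file *contents* are short deterministic placeholders
derived from seed and path, so the same seed regenerates a
byte-identical tree. `generate_random_tree()` draws arbitrary shapes
from a spec for property tests, fully answered so the result is
clean under `xcheck_metadata()`.

The generators emulate tree *shape and metadata flow*, not data:
passing tests demonstrate that scaffolding, inspection, export and
upload planning are mutually consistent on realistic shapes, not
that any biological content survives a round trip — there is none.

## Problem sizes and numerical choices

Test and verification runs use desk-scale trees: the two example
projects (36 and 14 level directories), random trees of one to two
investigations with up to two studies each, a 1000-record metadata
round-trip, and a four-file path-length probe around the
247-character threshold. All randomness is seeded; reports and
regenerated trees are byte-stable. There is no floating-point
numerics in the package — all checks are exact string, count and
set comparisons.

## Known limitations

- No file locking or concurrent-writer protection; ordering
  discipline is delegated to a data steward.
- No version control of arbitrary files beyond the date-stamped
  phenodata/featuredata convention.
- The ISA-Tab mapping is representative, not a reproduction of any
  particular historical mapping; users with an established field
  mapping should edit the mapping file.
- The live HTTP client for a real SEEK endpoint is out of scope;
  `seek_payload()` renders the JSON bodies, and the endpoint
  interface is a single object type that a networked implementation
  can provide.
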