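# Level kinds and directory-name conventions of the four-level tree:
# project > investigation > study > assay.

LEVEL_KINDS <- c("project", "investigation", "study", "assay")

LEVEL_PREFIXES <- c(
  project       = "_p_",
  investigation = "_I_",
  study         = "_S_",
  assay         = "_A_"
)

#' Level kinds in hierarchical order
#'
#' The four levels of the tree, ordered from the outermost (`project`)
#' to the innermost (`assay`).
#'
#' @return Character vector of the four level kinds.
#' @export
level_kinds <- function() LEVEL_KINDS

#' Directory prefix of a level kind
#'
#' Every level directory carries a fixed short prefix (`_p_`, `_I_`,
#' `_S_`, `_A_`) so the hierarchy is visible in any file browser.
#'
#' @param kind One of `"project"`, `"investigation"`, `"study"`, `"assay"`.
#' @return The prefix string.
#' @export
level_prefix <- function(kind) {
  kind <- match.arg(kind, LEVEL_KINDS)
  unname(LEVEL_PREFIXES[kind])
}

level_index <- function(kind) match(kind, LEVEL_KINDS)

#' Successor of a level kind
#'
#' @param kind A level kind.
#' @return The next (nested) kind, or `NA_character_` for `"assay"`,
#'   which has no children.
#' @export
level_successor <- function(kind) {
  i <- level_index(match.arg(kind, LEVEL_KINDS))
  if (i >= length(LEVEL_KINDS)) NA_character_ else LEVEL_KINDS[i + 1L]
}

#' Canonical metadata filename of a level
#'
#' Metadata files are written as `_<LEVEL>_METADATA.TXT` with the level
#' name in upper case; reading is case-insensitive (see
#' [find_metadata_file()]).
#'
#' @param kind A level kind.
#' @return Filename string, e.g. `"_INVESTIGATION_METADATA.TXT"`.
#' @export
metadata_filename <- function(kind) {
  kind <- match.arg(kind, LEVEL_KINDS)
  paste0("_", toupper(kind), "_METADATA.TXT")
}

#' Locate the metadata file of a level directory
#'
#' Matches `_<LEVEL>_METADATA.TXT` case-insensitively, so files written
#' by hand (or by older tools with mixed-case names) are found.
#'
#' @param dir Path of a level directory.
#' @param kind The level kind expected in `dir`.
#' @return Full path of the metadata file, or `NA_character_` if absent.
#' @export
find_metadata_file <- function(dir, kind) {
  kind <- match.arg(kind, LEVEL_KINDS)
  want <- toupper(metadata_filename(kind))
  files <- list.files(dir, all.files = TRUE, no.. = TRUE)
  hit <- files[toupper(files) == want]
  if (length(hit) == 0L) return(NA_character_)
  file.path(dir, hit[[1L]])
}

#' Classify a directory basename as a tree level
#'
#' Applies the fixed prefix convention: `_p_` project, `_I_`
#' investigation, `_S_` study, `_A_` assay.  For assays the directory
#' name carries a `-<AssayType>` suffix; the substring after the *last*
#' hyphen is the assay type (assay names may themselves contain
#' hyphens, assay type names must not).
#'
#' @param basename A single directory basename (not a path).
#' @return `NULL` when the name carries no level prefix, otherwise a
#'   list with elements `kind`, `name` and `assay_type`
#'   (`NA_character_` except for assays).  An `_A_` name without a
#'   hyphen is classified as an assay with `assay_type = NA` and a
#'   warning.
#' @export
#' @examples
#' classify_dirname("_I_01_LabTrials")
#' classify_dirname("_A_Trial1-RNAisol")
#' classify_dirname("reports")
classify_dirname <- function(basename) {
  stopifnot(is.character(basename), length(basename) == 1L)
  hits <- LEVEL_PREFIXES[startsWith(basename, LEVEL_PREFIXES)]
  if (length(hits) == 0L) return(NULL)
  # longest prefix wins (all four are length 3, but be explicit)
  prefix <- hits[[which.max(nchar(hits))]]
  kind <- names(LEVEL_PREFIXES)[LEVEL_PREFIXES == prefix]
  rest <- substring(basename, nchar(prefix) + 1L)
  if (!nzchar(rest)) return(NULL)
  if (kind != "assay") {
    return(list(kind = kind, name = rest, assay_type = NA_character_))
  }
  cut <- regexpr("-[^-]*$", rest)
  if (cut < 0L) {
    warning("assay directory name without '-<AssayType>' suffix: ",
            sQuote(basename), call. = FALSE)
    return(list(kind = kind, name = rest, assay_type = NA_character_))
  }
  name <- substring(rest, 1L, cut - 1L)
  type <- substring(rest, cut + 1L)
  if (!nzchar(name)) return(NULL)
  list(kind = kind, name = name,
       assay_type = if (nzchar(type)) type else NA_character_)
}

#' Compose the directory basename of a level
#'
#' Inverse of [classify_dirname()]: prefix + name, with a
#' `-<AssayType>` suffix for assays.
#'
#' @param kind Level kind.
#' @param name Display name (no prefix).
#' @param assay_type Assay type name; required for assays.
#' @return Directory basename string.
#' @export
compose_dirname <- function(kind, name, assay_type = NULL) {
  kind <- match.arg(kind, LEVEL_KINDS)
  stopifnot(nzchar(name))
  if (kind == "assay") {
    if (is.null(assay_type) || !nzchar(assay_type)) {
      stop("assay directories need an assay type", call. = FALSE)
    }
    if (grepl("-", assay_type, fixed = TRUE)) {
      stop("assay type names must not contain hyphens: ",
           sQuote(assay_type), call. = FALSE)
    }
    return(paste0(level_prefix(kind), name, "-", assay_type))
  }
  paste0(level_prefix(kind), name)
}
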