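# Scaffolding: creation of levels on disk with prefixes, metadata
# files, level-appropriate subdirectories and seed tables.  Creation
# is strict (project > investigation > study > assay, no skipping),
# never overwrites, and is atomic per level: on any error the partly
# built directory is removed.

WINDOWS_RESERVED <- c("CON", "PRN", "AUX", "NUL",
                      paste0("COM", 1:9), paste0("LPT", 1:9))

#' Sanitise a level name for use in a directory name
#'
#' Spaces become hyphens; characters outside `[A-Za-z0-9._-]` are
#' removed; leading/trailing dots and hyphens are stripped.  Names
#' that are empty after sanitisation, or that collide with a reserved
#' Windows basename (`CON`, `NUL`, ...), are rejected — trees are
#' meant to be portable across operating systems.
#'
#' @param raw Proposed name.
#' @return Sanitised name.
#' @export
#' @examples
#' sanitise_name("Lab Trials 2020")
sanitise_name <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  x <- gsub(" ", "-", raw, fixed = TRUE)
  x <- gsub("[^A-Za-z0-9._-]", "", x)
  x <- gsub("^[.-]+|[.-]+$", "", x)
  if (!nzchar(x)) {
    stop("name is empty after sanitisation: ", sQuote(raw), call. = FALSE)
  }
  if (toupper(x) %in% WINDOWS_RESERVED) {
    stop("name is a reserved basename on Windows: ", sQuote(x), call. = FALSE)
  }
  x
}

# Subdirectories created at each non-assay level.
level_extra_subdirs <- function(kind) {
  switch(kind,
         project = character(),
         investigation = c("reports", "presentations", "other"),
         study = "reports",
         assay = character())  # assay subdirs come from the type spec
}

stamp_date <- function(date = NULL) {
  d <- date %||% getOption("isatree.date", Sys.Date())
  format(as.Date(d), "%Y%m%d")
}

#' Initialise a tree root
#'
#' Installs a copy of the bundled Templates repository into `path`, so
#' that projects created beside it are self-contained and the whole
#' root can be moved freely (no absolute paths are recorded anywhere).
#' A second call on the same root is a no-op with a message.
#'
#' @param path Writable directory that will hold projects.
#' @return Path of the installed `Templates` directory, invisibly.
#' @export
init_tree_root <- function(path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create tree root: ", path, call. = FALSE)
  }
  if (file.access(path, mode = 2L) != 0L) {
    stop("tree root is not writable: ", path, call. = FALSE)
  }
  target <- file.path(path, "Templates")
  if (dir.exists(target)) {
    message("Templates already present at ", target, "; leaving untouched")
    return(invisible(target))
  }
  src <- bundled_templates_path()
  ok <- file.copy(src, path, recursive = TRUE)
  if (!all(ok)) stop("failed to copy Templates into ", path, call. = FALSE)
  invisible(target)
}

#' Create one level of a tree on disk
#'
#' The directory gets the level prefix (and, for assays, the
#' `-<AssayType>` suffix), a metadata file built from the template
#' prompts and the supplied answers, and the level-appropriate
#' subdirectories: `reports`/`presentations`/`other` at investigation,
#' `reports` at study, and the assay-class subdirectories
#' (`output` + `output/raw` for wet, `input` + `scripts` + `output`
#' for dry, plus `reports` and `other`) at assay.  Creating an
#' investigation also seeds header-only `phenodata_<date>.txt` and
#' `featuredata_<date>.txt` tables; assay types that bundle seed
#' files (e.g. `analytes.txt`) have them copied in.
#'
#' Levels nest strictly: investigations under the project, studies
#' under investigations, assays under studies.  Existing directories
#' are never overwritten, and nothing is left behind on error.
#'
#' @param parent Parent directory: the tree root for a project, or the
#'   level directory of the preceding kind otherwise.
#' @param kind Level kind to create.
#' @param name Display name (sanitised with [sanitise_name()]).
#' @param assay_class,assay_type Assay class (`"wet"`/`"dry"`) and
#'   type; required for (and only for) assays.
#' @param answers Named list of prompt answers (see
#'   [resolve_answers()]).
#' @param templates An `isatree_templates` repository; located
#'   automatically (tree root, then bundled default) when `NULL`.
#' @param date Date used for seeded table stamps; defaults to the
#'   `isatree.date` option, then to today.
#' @return The created `isatree_node`, invisibly.
#' @export
make_level <- function(parent, kind, name, assay_class = NULL,
                       assay_type = NULL, answers = list(),
                       templates = NULL, date = NULL) {
  kind <- match.arg(kind, LEVEL_KINDS)
  name <- sanitise_name(name)
  if (kind == "assay") {
    if (is.null(assay_class) || is.null(assay_type)) {
      stop("assays need assay_class and assay_type", call. = FALSE)
    }
    assay_class <- match.arg(assay_class, c("wet", "dry"))
  } else if (!is.null(assay_class) || !is.null(assay_type)) {
    stop("assay_class/assay_type only apply to assays", call. = FALSE)
  }

  if (!dir.exists(parent)) stop("parent does not exist: ", parent, call. = FALSE)
  parent_cls <- classify_dirname(basename(norm_path(parent)))
  if (kind == "project") {
    if (!is.null(parent_cls)) {
      stop("projects are created at the tree root, not inside a level",
           call. = FALSE)
    }
  } else {
    want <- LEVEL_KINDS[level_index(kind) - 1L]
    if (is.null(parent_cls) || parent_cls$kind != want) {
      stop(sprintf("a %s can only be created inside a %s directory",
                   kind, want), call. = FALSE)
    }
  }

  templates <- templates %||% locate_templates(parent)

  type_spec <- NULL
  if (kind == "assay") {
    type_spec <- get_assay_type(templates, assay_class, assay_type)
    dirname <- compose_dirname(kind, name, type_spec$type_name)
  } else {
    dirname <- compose_dirname(kind, name)
  }
  target <- file.path(parent, dirname)
  if (file.exists(target)) {
    stop("target already exists, refusing to overwrite: ", target,
         call. = FALSE)
  }

  prompts <- templates$level_prompts[[kind]]
  if (!is.null(type_spec)) prompts <- c(prompts, type_spec$prompts)
  record <- resolve_answers(prompts, answers,
                            common = templates$common_pairs, level = kind)
  if (kind == "assay") {
    record <- set_meta(record, "Assay class", assay_class)
    record <- set_meta(record, "Assay type", type_spec$type_name)
  }

  ok <- dir.create(target, showWarnings = FALSE)
  if (!ok) stop("cannot create directory: ", target, call. = FALSE)
  tryCatch({
    save_metadata(record, file.path(target, metadata_filename(kind)))
    subdirs <- c(level_extra_subdirs(kind),
                 if (!is.null(type_spec)) type_spec$subdirs)
    for (sd in subdirs) {
      dir.create(file.path(target, sd), recursive = TRUE,
                 showWarnings = FALSE)
    }
    if (kind == "investigation") {
      stamp <- stamp_date(date)
      writeLines("Sample ID\tStudy\tTreatment\tDescription",
                 file.path(target, sprintf("phenodata_%s.txt", stamp)))
      writeLines("Variable ID\tAssay\tUnit\tDescription",
                 file.path(target, sprintf("featuredata_%s.txt", stamp)))
    }
    if (!is.null(type_spec)) {
      for (fn in names(type_spec$extra_files)) {
        writeLines(type_spec$extra_files[[fn]], file.path(target, fn))
      }
    }
  }, error = function(e) {
    unlink(target, recursive = TRUE)
    stop(e)
  })

  root <- if (kind == "project") target else find_project_root(target)
  invisible(load_node_shallow(target, root))
}

# Find the Templates repository governing a path: walk up from the
# path looking for a Templates/ sibling, else fall back to the
# bundled default.
locate_templates <- function(path) {
  p <- norm_path(path)
  repeat {
    cand <- file.path(p, "Templates")
    if (dir.exists(file.path(cand, "DRY")) &&
        dir.exists(file.path(cand, "WET"))) {
      return(load_repository(cand))
    }
    parent <- dirname(p)
    if (parent == p) break
    p <- parent
  }
  load_repository(bundled_templates_path())
}
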