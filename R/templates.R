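# The Templates repository: level prompt templates (x.lib), wet and
# dry assay-type templates, and common.ini.
#
# A template file is a sequence of key-value lines.  The value of a
# line defines the prompt: empty value = free text; "/"-separated
# values = menu choices (the user may always escape the menu with
# "other:<free text>"); a single non-empty value = a one-entry menu
# whose entry doubles as the default.  A leading "!" on the key marks
# the prompt as mandatory for the completeness check.

new_prompt <- function(key, choices = character(), mandatory = FALSE,
                       default = NA_character_) {
  structure(
    list(key = key, choices = choices,
         allows_other = length(choices) > 0L,
         mandatory = mandatory, default = default),
    class = "isatree_prompt"
  )
}

#' Parse one template line into a prompt definition
#'
#' @param line A line in the key-value dialect; a leading `!` on the
#'   key marks the prompt mandatory.
#' @param file,lineno Source location used in error messages.
#' @return An `isatree_prompt`: `key`, `choices`, `allows_other`,
#'   `mandatory`, `default`.
#' @export
#' @examples
#' parse_prompt_line("Assay class:\twet/dry")
#' parse_prompt_line("!Description:\t")
parse_prompt_line <- function(line, file = "<template>", lineno = NA) {
  rec <- parse_metadata(line)
  if (length(rec$keys) != 1L) {
    stop(sprintf("%s line %s: malformed template line: %s",
                 file, lineno, line), call. = FALSE)
  }
  key <- rec$keys[[1L]]
  value <- rec$values[[1L]]
  mandatory <- startsWith(key, "!")
  if (mandatory) key <- substring(key, 2L)
  if (!nzchar(key)) {
    stop(sprintf("%s line %s: empty prompt key", file, lineno), call. = FALSE)
  }
  if (!nzchar(value)) {
    return(new_prompt(key, mandatory = mandatory))
  }
  choices <- strsplit(value, "/", fixed = TRUE)[[1L]]
  choices <- choices[nzchar(choices)]
  default <- if (length(choices) == 1L) choices[[1L]] else NA_character_
  new_prompt(key, choices = choices, mandatory = mandatory, default = default)
}

parse_prompt_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines)) lines[1L] <- strip_bom(lines[1L])
  prompts <- list()
  for (i in seq_along(lines)) {
    ln <- sub("\r$", "", lines[[i]])
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    prompts <- c(prompts, list(parse_prompt_line(ln, file = path, lineno = i)))
  }
  prompts
}

# Default subdirectories per assay class; a "<Type>_subdirs.txt" file
# beside the template overrides them.
default_assay_subdirs <- function(class_name) {
  switch(class_name,
         wet = c("output", "output/raw", "reports", "other"),
         dry = c("input", "scripts", "output", "reports", "other"))
}

load_assay_type <- function(template_path, class_name) {
  base <- basename(template_path)
  type_name <- sub("_Template\\.txt$", "", base)
  if (grepl("-", type_name, fixed = TRUE)) {
    stop("assay type names must not contain hyphens: ", sQuote(type_name),
         call. = FALSE)
  }
  prompts <- parse_prompt_file(template_path)
  class_dir <- dirname(template_path)
  subdirs_file <- file.path(class_dir, paste0(type_name, "_subdirs.txt"))
  subdirs <- if (file.exists(subdirs_file)) {
    sd <- readLines(subdirs_file, encoding = "UTF-8", warn = FALSE)
    sd <- trimws(sd)
    sd[nzchar(sd) & !startsWith(sd, "#")]
  } else {
    default_assay_subdirs(class_name)
  }
  files_dir <- file.path(class_dir, paste0(type_name, "_Files"))
  extra_files <- list()
  if (dir.exists(files_dir)) {
    for (f in list.files(files_dir)) {
      extra_files[[f]] <- paste(
        readLines(file.path(files_dir, f), encoding = "UTF-8", warn = FALSE),
        collapse = "\n")
    }
  }
  structure(
    list(class_name = class_name, type_name = type_name, prompts = prompts,
         subdirs = subdirs, extra_files = extra_files),
    class = "isatree_assay_type"
  )
}

#' Load a Templates repository
#'
#' The repository layout is `Templates/x.lib` (level prompt templates
#' named `<Level>_Template.txt`), `Templates/DRY` and `Templates/WET`
#' (one `<AssayType>_Template.txt` per assay type, optionally with
#' `<AssayType>_subdirs.txt` and a `<AssayType>_Files/` directory of
#' seed files), plus an optional `common.ini` whose key-value pairs
#' are injected into every level created under the repository.
#'
#' @param root Path of the `Templates` directory, or of a directory
#'   containing one.
#' @return An `isatree_templates` object: `root`, `classes` (named
#'   lists `wet` and `dry` of assay types), `level_prompts`,
#'   `common_pairs`.
#' @export
load_repository <- function(root) {
  if (basename(root) != "Templates" &&
      dir.exists(file.path(root, "Templates"))) {
    root <- file.path(root, "Templates")
  }
  if (!dir.exists(file.path(root, "DRY")) ||
      !dir.exists(file.path(root, "WET"))) {
    stop("not a Templates repository (DRY and WET subdirectories required): ",
         root, call. = FALSE)
  }
  classes <- list(wet = list(), dry = list())
  for (cls in c(wet = "WET", dry = "DRY")) {
    class_name <- names(which(c(wet = "WET", dry = "DRY") == cls))
    dirpath <- file.path(root, cls)
    for (tf in list.files(dirpath, pattern = "_Template\\.txt$",
                          full.names = TRUE)) {
      spec <- load_assay_type(tf, class_name)
      if (!is.null(classes[[class_name]][[spec$type_name]])) {
        stop(sprintf("duplicate assay type %s in class %s",
                     sQuote(spec$type_name), class_name), call. = FALSE)
      }
      classes[[class_name]][[spec$type_name]] <- spec
    }
  }
  level_prompts <- list()
  xlib <- file.path(root, "x.lib")
  for (kind in LEVEL_KINDS) {
    f <- file.path(xlib, paste0(tools::toTitleCase(kind), "_Template.txt"))
    level_prompts[[kind]] <- if (file.exists(f)) parse_prompt_file(f) else list()
  }
  common <- new_metadata_record()
  for (cand in c(file.path(root, "common.ini"),
                 file.path(dirname(root), "common.ini"))) {
    if (file.exists(cand)) {
      common <- read_metadata(cand)
      break
    }
  }
  structure(
    list(root = norm_path(root), classes = classes,
         level_prompts = level_prompts, common_pairs = common),
    class = "isatree_templates"
  )
}

#' @export
print.isatree_templates <- function(x, ...) {
  cat(sprintf("<templates at %s: %d wet, %d dry types, %d common pairs>\n",
              x$root, length(x$classes$wet), length(x$classes$dry),
              length(x$common_pairs$keys)))
  invisible(x)
}

#' Path of the bundled default Templates repository
#'
#' @return Directory path inside the installed package.
#' @export
bundled_templates_path <- function() {
  system.file("extdata", "Templates", package = "isatree", mustWork = TRUE)
}

#' Look up an assay type in a repository
#'
#' @param templates An `isatree_templates` object.
#' @param class_name `"wet"` or `"dry"`.
#' @param type_name Assay type name.
#' @return The `isatree_assay_type`, or an error when unknown.
#' @export
get_assay_type <- function(templates, class_name, type_name) {
  class_name <- match.arg(class_name, c("wet", "dry"))
  spec <- templates$classes[[class_name]][[type_name]]
  if (is.null(spec)) {
    stop(sprintf("unknown assay type %s in class %s (known: %s)",
                 sQuote(type_name), class_name,
                 paste(names(templates$classes[[class_name]]),
                       collapse = ", ")), call. = FALSE)
  }
  spec
}

#' Resolve prompt answers into a metadata record
#'
#' For each prompt in template order: a supplied answer must be one of
#' the menu choices, or arbitrary text via the `other:<text>` escape
#' (free-text prompts accept anything).  Unanswered prompts fall back
#' to the prompt default when one exists, else to the empty value
#' (later caught by the completeness check if mandatory).  Common
#' pairs are appended once, after the prompt pairs, without
#' overriding any prompt-derived key.
#'
#' @param prompts List of `isatree_prompt` objects.
#' @param answers Named character vector or list, key -> answer.
#' @param common An `isatree_metadata` record of common pairs
#'   (optional).
#' @param level Level kind recorded on the result.
#' @return An `isatree_metadata` record.
#' @export
resolve_answers <- function(prompts, answers = list(), common = NULL,
                            level = NA_character_) {
  answers <- as.list(answers)
  keys <- character(); values <- character()
  for (p in prompts) {
    ans <- answers[[p$key]]
    if (is.null(ans)) {
      value <- if (!is.na(p$default)) p$default else ""
    } else if (length(p$choices) == 0L) {
      value <- as.character(ans)
    } else if (startsWith(as.character(ans), "other:")) {
      value <- substring(as.character(ans), nchar("other:") + 1L)
    } else if (as.character(ans) %in% p$choices) {
      value <- as.character(ans)
    } else {
      stop(sprintf(
        "answer %s for %s is not one of the choices (%s); use 'other:<text>' for a free answer",
        sQuote(as.character(ans)), sQuote(p$key),
        paste(p$choices, collapse = "/")), call. = FALSE)
    }
    keys <- c(keys, p$key)
    values <- c(values, value)
  }
  if (!is.null(common) && length(common$keys)) {
    add <- !(trimws(common$keys) %in% trimws(keys))
    keys <- c(keys, common$keys[add])
    values <- c(values, common$values[add])
  }
  new_metadata_record(keys, values, level = level)
}

#' Mandatory keys of a prompt set
#'
#' @param prompts List of `isatree_prompt` objects.
#' @return Character vector of keys marked mandatory.
#' @export
mandatory_keys <- function(prompts) {
  unlist(lapply(prompts, function(p) if (p$mandatory) p$key else NULL)) %||%
    character()
}
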