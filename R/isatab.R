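# ISA-Tab export of one investigation: an i_Investigation.txt with
# the standard sections, one s_<study>.txt sample file per study and
# one a_<assay>.txt per assay.  The conversion is driven by a flat
# mapping file (tree metadata key -> investigation-file section and
# field); pairs without a mapping entry are carried into
# Comment[...] fields so no metadata is silently dropped.

ISATAB_TOP_SECTIONS <- c("ONTOLOGY SOURCE REFERENCE", "INVESTIGATION",
                         "INVESTIGATION PUBLICATIONS",
                         "INVESTIGATION CONTACTS")
ISATAB_STUDY_SECTIONS <- c("STUDY", "STUDY DESIGN DESCRIPTORS",
                           "STUDY PUBLICATIONS", "STUDY FACTORS",
                           "STUDY ASSAYS", "STUDY PROTOCOLS",
                           "STUDY CONTACTS")

#' Load an ISA-Tab mapping specification
#'
#' The mapping file is tab-separated, one directive per line:
#' `map <key> <section> <field>` routes a metadata key into an
#' investigation-file field, and `assay <type> <measurement>
#' <technology>` declares the measurement and technology types
#' announced for an assay type.  `#` comments and blank lines are
#' skipped.  A bundled default ships with the package.
#'
#' @param path Mapping file; the bundled default when `NULL`.
#' @return An `isatree_mapping`: `entries` (data.frame key/section/
#'   field) and `assay_config` (data.frame type/measurement/
#'   technology).
#' @export
load_mapping <- function(path = NULL) {
  path <- path %||% system.file("extdata", "isatab_mapping.txt",
                                package = "isatree", mustWork = TRUE)
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  entries <- data.frame(key = character(), section = character(),
                        field = character(), stringsAsFactors = FALSE)
  assay_config <- data.frame(type = character(), measurement = character(),
                             technology = character(),
                             stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    ln <- sub("\r$", "", lines[[i]])
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) == 4L && parts[[1L]] == "map") {
      ok <- parts[[3L]] %in% c(ISATAB_TOP_SECTIONS, ISATAB_STUDY_SECTIONS)
      if (!ok) {
        stop(sprintf("%s line %d: unknown ISA-Tab section %s",
                     path, i, sQuote(parts[[3L]])), call. = FALSE)
      }
      entries <- rbind(entries,
                       data.frame(key = parts[[2L]], section = parts[[3L]],
                                  field = parts[[4L]],
                                  stringsAsFactors = FALSE))
    } else if (length(parts) == 4L && parts[[1L]] == "assay") {
      assay_config <- rbind(assay_config,
                            data.frame(type = parts[[2L]],
                                       measurement = parts[[3L]],
                                       technology = parts[[4L]],
                                       stringsAsFactors = FALSE))
    } else {
      stop(sprintf("%s line %d: malformed mapping line: %s", path, i, ln),
           call. = FALSE)
    }
  }
  structure(list(entries = entries, assay_config = assay_config,
                 path = path),
            class = "isatree_mapping")
}

assay_types_for <- function(mapping, type_name, class_name) {
  hit <- if (is.na(type_name)) {
    mapping$assay_config[0L, , drop = FALSE]
  } else {
    mapping$assay_config[mapping$assay_config$type == type_name, ,
                         drop = FALSE]
  }
  if (nrow(hit) >= 1L) {
    return(c(hit$measurement[[1L]], hit$technology[[1L]]))
  }
  warning(sprintf(
    "assay type %s has no mapping entry; using class-based defaults",
    sQuote(type_name)), call. = FALSE)
  default <- if (identical(class_name, "wet")) "laboratory measurement"
             else "data analysis"
  c(default, "unknown technology")
}

empty_sections <- function(names) {
  s <- lapply(names, function(x) list())
  names(s) <- names
  s
}

set_field <- function(sections, section, field, value) {
  cur <- sections[[section]][[field]]
  sections[[section]][[field]] <- c(cur, value)
  sections
}

# Route one metadata record into investigation-file sections.
# `allowed` restricts the sections mapped into (investigation-level
# pairs go to top sections, study pairs to STUDY sections);
# unmapped pairs become Comment[<comment_tag><key>] fields in
# `comment_section`.
route_pairs <- function(sections, record, mapping, allowed,
                        comment_section, comment_tag = "pISA:") {
  for (i in seq_along(record$keys)) {
    key <- record$keys[[i]]; value <- record$values[[i]]
    hit <- mapping$entries[mapping$entries$key == trimws(key) &
                             mapping$entries$section %in% allowed, ,
                           drop = FALSE]
    if (nrow(hit) >= 1L &&
        is.null(sections[[hit$section[[1L]]]][[hit$field[[1L]]]])) {
      sections <- set_field(sections, hit$section[[1L]], hit$field[[1L]],
                            value)
    } else {
      label <- paste0("Comment[", comment_tag, key, "]")
      sections <- set_field(sections, comment_section, label, value)
    }
  }
  sections
}

#' Build an ISA-Tab document from an investigation
#'
#' Populates the investigation file from the project and investigation
#' metadata via the mapping, emits one STUDY block and one sample file
#' per study (samples drawn from the investigation's phenodata table;
#' when phenodata has a `Study` column, rows are attributed to the
#' matching study, otherwise every sample is attached to every study
#' with a warning), and one assay file per assay listing `Sample Name`
#' plus `Raw Data File` entries for files under `output/raw` (wet
#' assays) or `Derived Data File` entries for files under `output`
#' (dry assays).  Assay metadata pairs are carried as Comment fields
#' of the owning STUDY block.
#'
#' @param inv Path of an investigation directory, or a loaded
#'   `isatree_node` of kind investigation.
#' @param phenodata An `isatree_table`; the latest
#'   `phenodata_yyyymmdd.txt` of the investigation when `NULL`.
#'   An investigation without any phenodata is an error.
#' @param mapping An `isatree_mapping`; the bundled default when
#'   `NULL`.
#' @return An `isatree_isatab` document: `sections` (top
#'   investigation-file sections), `studies` (per-study section
#'   blocks), `study_files` and `assay_files` (named lists of data
#'   frames keyed by output filename).
#' @export
build_isatab <- function(inv, phenodata = NULL, mapping = NULL) {
  if (is.character(inv)) inv <- load_tree(inv)
  stopifnot(inherits(inv, "isatree_node"))
  if (inv$kind != "investigation") {
    stop("ISA-Tab export starts from an investigation, got: ", inv$kind,
         call. = FALSE)
  }
  mapping <- mapping %||% load_mapping()
  if (is.null(phenodata)) {
    phenodata <- latest_table(inv$path, "phenodata")
    if (is.null(phenodata)) {
      stop("investigation has no phenodata table; cannot derive study samples",
           call. = FALSE)
    }
  }
  chain <- resolve_chain(inv$path)
  project_meta <- chain[[1L]]$metadata

  sections <- empty_sections(ISATAB_TOP_SECTIONS)
  # required skeleton fields so the document validates structurally
  sections <- set_field(sections, "ONTOLOGY SOURCE REFERENCE",
                        "Term Source Name", "")
  sections <- set_field(sections, "INVESTIGATION",
                        "Investigation Identifier", inv$name)
  sections <- route_pairs(sections, inv$metadata, mapping,
                          allowed = ISATAB_TOP_SECTIONS,
                          comment_section = "INVESTIGATION")
  sections <- route_pairs(sections, project_meta, mapping,
                          allowed = ISATAB_TOP_SECTIONS,
                          comment_section = "INVESTIGATION",
                          comment_tag = "pISA project:")

  study_col <- which(tolower(names(phenodata$data)) == "study")[1]
  if (is.na(study_col) && length(inv$children) > 1L) {
    warning("phenodata has no 'Study' column; attaching every sample ",
            "to every study", call. = FALSE)
  }

  studies <- list(); study_files <- list(); assay_files <- list()
  for (st in inv$children) {
    blk <- empty_sections(ISATAB_STUDY_SECTIONS)
    s_file <- paste0("s_", st$dirname, ".txt")
    blk <- set_field(blk, "STUDY", "Study Identifier", st$name)
    blk <- route_pairs(blk, st$metadata, mapping,
                       allowed = ISATAB_STUDY_SECTIONS,
                       comment_section = "STUDY")
    blk <- set_field(blk, "STUDY", "Study File Name", s_file)

    # sample attribution
    if (!is.na(study_col)) {
      match_rows <- tolower(phenodata$data[[study_col]]) %in%
        tolower(c(st$name, st$dirname))
      rows <- phenodata$data[match_rows, , drop = FALSE]
    } else {
      rows <- phenodata$data
    }
    samp <- data.frame(`Source Name` = if (nrow(rows)) rows[[1L]] else character(),
                       check.names = FALSE, stringsAsFactors = FALSE)
    extra <- setdiff(seq_along(rows), c(1L, study_col))
    for (j in extra) {
      samp[[paste0("Characteristics[", names(rows)[[j]], "]")]] <- rows[[j]]
    }
    samp[["Sample Name"]] <- samp[["Source Name"]]
    rownames(samp) <- NULL
    study_files[[s_file]] <- samp

    a_names <- character(); a_meas <- character(); a_tech <- character()
    for (as in st$children) {
      # assay dirnames are only unique within a study; qualify with it
      a_file <- paste0("a_", st$dirname, ".", as$dirname, ".txt")
      cls <- tryCatch(get_meta(as$metadata, "Assay class"),
                      error = function(e) NA_character_)
      mt <- assay_types_for(mapping, as$assay_type %||% NA_character_, cls)
      a_names <- c(a_names, a_file)
      a_meas <- c(a_meas, mt[[1L]]); a_tech <- c(a_tech, mt[[2L]])

      data_dir <- if (identical(cls, "wet")) "output/raw" else "output"
      data_col <- if (identical(cls, "wet")) "Raw Data File"
                  else "Derived Data File"
      files <- sort(list.files(file.path(as$path, data_dir),
                               recursive = TRUE))
      files <- file.path(data_dir, files)
      if (length(files) == 0L) files <- character()
      smp <- samp[["Sample Name"]]
      n <- max(length(smp), length(files), 1L)
      tab <- data.frame(
        `Sample Name` = if (length(smp)) smp[pmin(seq_len(n), length(smp))]
                        else rep("", n),
        check.names = FALSE, stringsAsFactors = FALSE)
      tab[[data_col]] <- if (length(files))
        c(files, rep("", n - length(files)))[seq_len(n)] else rep("", n)
      assay_files[[a_file]] <- tab

      # assay metadata carried losslessly on the owning study block
      for (k in seq_along(as$metadata$keys)) {
        blk <- set_field(
          blk, "STUDY",
          paste0("Comment[pISA assay ", as$dirname, ":",
                 as$metadata$keys[[k]], "]"),
          as$metadata$values[[k]])
      }
    }
    blk <- set_field(blk, "STUDY ASSAYS", "Study Assay File Name", a_names)
    blk <- set_field(blk, "STUDY ASSAYS", "Study Assay Measurement Type",
                     a_meas)
    blk <- set_field(blk, "STUDY ASSAYS", "Study Assay Technology Type",
                     a_tech)
    studies[[st$dirname]] <- blk
  }

  structure(list(sections = sections, studies = studies,
                 study_files = study_files, assay_files = assay_files),
            class = "isatree_isatab")
}

#' @export
print.isatree_isatab <- function(x, ...) {
  cat(sprintf("<ISA-Tab document: %d studies, %d assay files>\n",
              length(x$studies), length(x$assay_files)))
  invisible(x)
}

serialise_sections <- function(sections) {
  out <- character()
  for (sec in names(sections)) {
    out <- c(out, sec)
    flds <- sections[[sec]]
    for (f in names(flds)) {
      out <- c(out, paste(c(f, flds[[f]]), collapse = "\t"))
    }
  }
  out
}

#' Write an ISA-Tab document to a directory
#'
#' Emits `i_Investigation.txt`, one `s_<study>.txt` and one
#' `a_<assay>.txt`, all tab-separated.
#'
#' @param doc An `isatree_isatab` document.
#' @param outdir Target directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_isatab <- function(doc, outdir) {
  stopifnot(inherits(doc, "isatree_isatab"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  inv_lines <- serialise_sections(doc$sections)
  for (st in names(doc$studies)) {
    inv_lines <- c(inv_lines, serialise_sections(doc$studies[[st]]))
  }
  ipath <- file.path(outdir, "i_Investigation.txt")
  writeLines(inv_lines, ipath)
  written <- c(written, ipath)
  for (fn in names(doc$study_files)) {
    p <- file.path(outdir, fn)
    utils::write.table(doc$study_files[[fn]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    written <- c(written, p)
  }
  for (fn in names(doc$assay_files)) {
    p <- file.path(outdir, fn)
    utils::write.table(doc$assay_files[[fn]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    written <- c(written, p)
  }
  invisible(written)
}

#' Re-parse an exported ISA-Tab directory
#'
#' Inverse of [write_isatab()]; used to verify that exports round-trip.
#'
#' @param dir Directory containing `i_Investigation.txt` and the
#'   study/assay files.
#' @return An `isatree_isatab` document.
#' @export
read_isatab <- function(dir) {
  ipath <- file.path(dir, "i_Investigation.txt")
  if (!file.exists(ipath)) {
    stop("no i_Investigation.txt in ", dir, call. = FALSE)
  }
  lines <- readLines(ipath, encoding = "UTF-8", warn = FALSE)
  all_sections <- c(ISATAB_TOP_SECTIONS, ISATAB_STUDY_SECTIONS)
  sections <- list(); studies <- list()
  cur <- NULL; block <- NULL; study_idx <- 0L
  flush_block <- function() {
    if (!is.null(block)) {
      sf <- block[["STUDY"]][["Study File Name"]]
      key <- if (!is.null(sf)) sub("^s_(.*)\\.txt$", "\\1", sf[[1L]])
             else paste0("study", study_idx)
      studies[[key]] <<- block
      block <<- NULL
    }
  }
  for (ln in lines) {
    if (ln %in% all_sections) {
      if (ln == "STUDY") {
        flush_block()
        study_idx <- study_idx + 1L
        block <- list()
      }
      cur <- ln
      if (is.null(block)) sections[[cur]] <- list()
      else block[[cur]] <- list()
      next
    }
    # keep trailing empty fields (strsplit drops them)
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    nf <- lengths(gregexpr("\t", ln, fixed = TRUE))
    nf <- if (attr(regexpr("\t", ln, fixed = TRUE), "match.length") < 0) 1L
          else nf + 1L
    length(parts) <- nf
    parts[is.na(parts)] <- ""
    if (length(parts) == 0L || is.null(cur)) next
    field <- parts[[1L]]
    value <- if (length(parts) > 1L) parts[-1L] else character()
    if (is.null(block)) sections[[cur]][[field]] <- value
    else block[[cur]][[field]] <- value
  }
  flush_block()
  read_tab <- function(p) {
    utils::read.delim(p, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE,
                      quote = "", comment.char = "")
  }
  # order the table lists as the investigation file references them,
  # so write -> read round-trips to an identical document
  s_ref <- unlist(lapply(studies, function(b)
    b[["STUDY"]][["Study File Name"]])) %||% character()
  a_ref <- unlist(lapply(studies, function(b)
    b[["STUDY ASSAYS"]][["Study Assay File Name"]])) %||% character()
  s_found <- sort(list.files(dir, pattern = "^s_.*\\.txt$"))
  a_found <- sort(list.files(dir, pattern = "^a_.*\\.txt$"))
  study_files <- list(); assay_files <- list()
  for (f in unique(c(intersect(s_ref, s_found), s_found))) {
    study_files[[f]] <- read_tab(file.path(dir, f))
  }
  for (f in unique(c(intersect(a_ref, a_found), a_found))) {
    assay_files[[f]] <- read_tab(file.path(dir, f))
  }
  structure(list(sections = sections, studies = studies,
                 study_files = study_files, assay_files = assay_files),
            class = "isatree_isatab")
}

#' Structural validation of an ISA-Tab document
#'
#' Checks that the required investigation and study sections are
#' present, that every `Study File Name` / `Study Assay File Name`
#' referenced in the investigation file exists in the document, that
#' every `Sample Name` used in an assay file appears in the sample
#' file of its study, and (when `phenodata` is given) that every
#' study sample is a known phenodata identifier.
#'
#' @param doc An `isatree_isatab` document.
#' @param phenodata Optional `isatree_table` to check sample
#'   provenance against.
#' @return Finding table (`path`, `key`, `problem`); zero rows when
#'   the document is structurally valid.
#' @export
validate_isatab_structure <- function(doc, phenodata = NULL) {
  stopifnot(inherits(doc, "isatree_isatab"))
  findings <- no_findings()
  for (sec in ISATAB_TOP_SECTIONS) {
    if (is.null(doc$sections[[sec]])) {
      findings <- rbind(findings,
                        new_finding("i_Investigation.txt", sec,
                                    "missing_file"))
    }
  }
  for (st in names(doc$studies)) {
    blk <- doc$studies[[st]]
    for (sec in ISATAB_STUDY_SECTIONS) {
      if (is.null(blk[[sec]])) {
        findings <- rbind(findings, new_finding(st, sec, "missing_file"))
      }
    }
    sf <- blk[["STUDY"]][["Study File Name"]]
    s_tab <- NULL
    if (is.null(sf) || length(sf) == 0L) {
      findings <- rbind(findings,
                        new_finding(st, "Study File Name", "missing_value"))
    } else if (is.null(doc$study_files[[sf[[1L]]]])) {
      findings <- rbind(findings, new_finding(st, sf[[1L]], "missing_file"))
    } else {
      s_tab <- doc$study_files[[sf[[1L]]]]
    }
    s_samples <- if (!is.null(s_tab)) s_tab[["Sample Name"]] else character()
    if (!is.null(phenodata) && length(s_samples)) {
      ids <- phenodata$data[[1L]]
      dangling <- setdiff(s_samples, ids)
      for (d in dangling) {
        findings <- rbind(findings,
                          new_finding(sf[[1L]], d, "missing_value"))
      }
    }
    for (af in blk[["STUDY ASSAYS"]][["Study Assay File Name"]] %||%
           character()) {
      a_tab <- doc$assay_files[[af]]
      if (is.null(a_tab)) {
        findings <- rbind(findings, new_finding(st, af, "missing_file"))
        next
      }
      used <- setdiff(a_tab[["Sample Name"]], "")
      for (d in setdiff(used, s_samples)) {
        findings <- rbind(findings, new_finding(af, d, "missing_value"))
      }
    }
  }
  sort_findings(findings)
}
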