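# Inspection and validation: render the tree (TREE.TXT), aggregate
# all metadata (plain text or markdown), cross-check mandatory keys
# against the templates, and flag paths that would exceed the Windows
# path-length limit.  All reports are deterministic: siblings are
# ordered case-insensitively, findings are sorted by path then key.

new_finding <- function(path, key, problem) {
  data.frame(path = path, key = key, problem = problem,
             stringsAsFactors = FALSE)
}

no_findings <- function() new_finding(character(), character(), character())

sort_findings <- function(f) {
  if (nrow(f) == 0L) return(f)
  f <- f[order(f$path, f$key), , drop = FALSE]
  rownames(f) <- NULL
  f
}

#' Render the directory tree
#'
#' Produces an indented depth-first listing of the tree below `start`
#' (siblings in case-insensitive lexicographic order) and writes it to
#' `TREE.TXT` in `start`.  With `levels_only = TRUE` only the prefixed
#' level directories are listed, which is the compact overview used to
#' summarise large projects.
#'
#' @param start A path inside a tree; rendering begins at the level
#'   containing it.
#' @param levels_only List only level directories.
#' @param write Write `TREE.TXT` (default `TRUE`).
#' @return An `isatree_treereport`: `root` (the loaded subtree),
#'   `rendered` (the report text), `counts` (named integer vector of
#'   level counts), `path` (report file or `NA`).
#' @export
show_tree <- function(start, levels_only = FALSE, write = TRUE) {
  chain <- resolve_chain(start)
  top <- chain[[length(chain)]]
  node <- load_tree(top$path)
  lines <- render_tree_lines(node$path, depth = 0L,
                             levels_only = levels_only)
  rendered <- paste0(paste(lines, collapse = "\n"), "\n")
  counts <- count_levels(node)
  out_path <- NA_character_
  if (write) {
    out_path <- file.path(node$path, "TREE.TXT")
    writeLines(sub("\n$", "", rendered), out_path)
  }
  structure(list(root = node, rendered = rendered, counts = counts,
                 path = out_path),
            class = "isatree_treereport")
}

render_tree_lines <- function(dir, depth, levels_only) {
  indent <- strrep("    ", depth)
  lines <- paste0(indent, basename(dir))
  entries <- list.files(dir, full.names = TRUE)
  entries <- entries[order(tolower(basename(entries)), basename(entries))]
  for (e in entries) {
    b <- basename(e)
    if (dir.exists(e)) {
      is_level <- !is.null(suppressWarnings(classify_dirname(b)))
      if (levels_only && !is_level) next
      lines <- c(lines, render_tree_lines(e, depth + 1L, levels_only))
    } else if (!levels_only && b != "TREE.TXT") {
      lines <- c(lines, paste0(indent, "    ", b))
    }
  }
  lines
}

#' @export
print.isatree_treereport <- function(x, ...) {
  cat(x$rendered)
  invisible(x)
}

#' Aggregate all metadata of a subtree
#'
#' Concatenates every level's metadata in tree order, each under a
#' heading carrying the level's path relative to the project root.
#' In markdown mode the heading depth equals the level depth
#' (project `#`, investigation `##`, ...).  The document is also
#' written to `METADATA.TXT` / `METADATA.md` in `start` unless
#' `write = FALSE`.
#'
#' @param start A path inside a tree.
#' @param format `"plain"` or `"markdown"`.
#' @param write Write the report file.
#' @return The document as a single string, invisibly when written.
#' @export
show_metadata <- function(start, format = c("plain", "markdown"),
                          write = TRUE) {
  format <- match.arg(format)
  chain <- resolve_chain(start)
  top <- chain[[length(chain)]]
  node <- load_tree(top$path)
  blocks <- character()
  for (n in flatten_tree(node)) {
    depth <- level_index(n$kind)
    heading <- if (format == "markdown") {
      paste0(strrep("#", depth), " ", n$rel_path)
    } else {
      paste0(n$rel_path, "\n", strrep("=", nchar(n$rel_path)))
    }
    body <- if (length(n$metadata$keys)) {
      if (format == "markdown") {
        paste0("- ", n$metadata$keys, ": ", n$metadata$values,
               collapse = "\n")
      } else {
        paste0(n$metadata$keys, ":\t", n$metadata$values, collapse = "\n")
      }
    } else {
      "(no metadata)"
    }
    blocks <- c(blocks, paste0(heading, "\n", body))
  }
  doc <- paste0(paste(blocks, collapse = "\n\n"), "\n")
  if (write) {
    fn <- if (format == "markdown") "METADATA.md" else "METADATA.TXT"
    writeLines(sub("\n$", "", doc), file.path(node$path, fn))
    return(invisible(doc))
  }
  doc
}

#' Cross-check metadata completeness
#'
#' For every level below `start`, keys marked mandatory in the
#' governing templates that are absent or empty in the level's
#' metadata yield `missing_value` findings; a level directory without
#' a metadata file yields a `missing_file` finding.  Problems are
#' findings, not errors: the return value is a (possibly empty)
#' sorted finding table.
#'
#' @param start A path inside a tree.
#' @param templates Templates repository; located automatically when
#'   `NULL`.
#' @return Data frame with columns `path`, `key`, `problem`, sorted
#'   by path then key.
#' @export
xcheck_metadata <- function(start, templates = NULL) {
  chain <- resolve_chain(start)
  top <- chain[[length(chain)]]
  templates <- templates %||% locate_templates(top$path)
  node <- load_tree(top$path)
  findings <- no_findings()
  for (n in flatten_tree(node)) {
    meta_path <- find_metadata_file(n$path, n$kind)
    if (is.na(meta_path)) {
      findings <- rbind(findings,
                        new_finding(n$rel_path, metadata_filename(n$kind),
                                    "missing_file"))
      next
    }
    prompts <- templates$level_prompts[[n$kind]]
    if (n$kind == "assay" && !is.na(n$assay_type)) {
      for (cls in c("wet", "dry")) {
        spec <- templates$classes[[cls]][[n$assay_type]]
        if (!is.null(spec)) prompts <- c(prompts, spec$prompts)
      }
    }
    for (key in mandatory_keys(prompts)) {
      val <- tryCatch(get_meta(n$metadata, key), error = function(e) NULL)
      if (is.null(val) || !nzchar(trimws(val))) {
        findings <- rbind(findings,
                          new_finding(n$rel_path, key, "missing_value"))
      }
    }
    for (w in n$metadata$warnings) {
      if (grepl("no tab separator", w, fixed = TRUE)) {
        findings <- rbind(findings,
                          new_finding(n$rel_path, w, "malformed_line"))
      }
    }
  }
  sort_findings(findings)
}

#' Flag paths exceeding a length limit
#'
#' Windows caps paths at 247 characters unless the registry is
#' altered; trees meant to be shared across platforms should stay
#' below it.  Each file's length is measured as the absolute path it
#' would have under `mount_prefix` (by default the tree's real
#' location); files and directories whose full path exceeds `limit`
#' yield `path_too_long` findings.
#'
#' @param root Tree (or subtree) root directory.
#' @param limit Maximum allowed path length in characters.
#' @param mount_prefix Prefix the tree is assumed to be mounted at;
#'   defaults to the absolute path of `root`'s parent.
#' @return Finding table (columns `path`, `key`, `problem`), `key`
#'   holding the measured length.
#' @export
check_path_lengths <- function(root, limit = 247L, mount_prefix = NULL) {
  if (!dir.exists(root)) return(sort_findings(no_findings()))
  rootn <- norm_path(root)
  prefix <- mount_prefix %||% dirname(rootn)
  prefix <- sub("/$", "", prefix)
  rels <- list.files(rootn, recursive = TRUE, all.files = TRUE,
                     include.dirs = TRUE, no.. = TRUE)
  rels <- c(".", rels)
  findings <- no_findings()
  for (r in rels) {
    full <- if (r == ".") {
      paste0(prefix, "/", basename(rootn))
    } else {
      paste0(prefix, "/", basename(rootn), "/", r)
    }
    len <- nchar(full)
    if (len > limit) {
      findings <- rbind(findings,
                        new_finding(if (r == ".") basename(rootn) else r,
                                    sprintf("length %d > %d", len, limit),
                                    "path_too_long"))
    }
  }
  sort_findings(findings)
}
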