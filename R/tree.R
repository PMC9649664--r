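# In-memory model of the directory tree: level nodes, chain
# resolution from any path up to the project root, and recursive
# loading.  All reported paths are relative to the project root and
# use "/" regardless of platform, so reports are identical when the
# tree is relocated.

new_level_node <- function(kind, name, assay_type, dirname, path, rel_path,
                           metadata, children = list()) {
  structure(
    list(kind = kind, name = name, assay_type = assay_type,
         dirname = dirname, path = path, rel_path = rel_path,
         metadata = metadata, children = children),
    class = "isatree_node"
  )
}

#' @export
print.isatree_node <- function(x, ...) {
  cat(sprintf("<%s %s (%s), %d children>\n",
              x$kind, sQuote(x$name), x$rel_path, length(x$children)))
  invisible(x)
}

norm_path <- function(path) {
  normalizePath(path, winslash = "/", mustWork = FALSE)
}

rel_to <- function(path, root) {
  p <- norm_path(path); r <- norm_path(root)
  if (p == r) return(".")
  prefix <- paste0(r, "/")
  if (!startsWith(p, prefix)) {
    stop(sprintf("%s is not under %s", path, root), call. = FALSE)
  }
  substring(p, nchar(prefix) + 1L)
}

load_node_shallow <- function(dir, project_root) {
  cls <- classify_dirname(basename(dir))
  if (is.null(cls)) {
    stop(sprintf("not a level directory: %s", dir), call. = FALSE)
  }
  meta_path <- find_metadata_file(dir, cls$kind)
  meta <- if (is.na(meta_path)) {
    new_metadata_record(level = cls$kind)
  } else {
    read_metadata(meta_path, level = cls$kind)
  }
  new_level_node(cls$kind, cls$name, cls$assay_type, basename(dir),
                 norm_path(dir), rel_to(dir, project_root), meta)
}

level_subdirs <- function(dir) {
  kids <- list.dirs(dir, recursive = FALSE, full.names = TRUE)
  is_level <- vapply(basename(kids),
                     function(b) !is.null(suppressWarnings(classify_dirname(b))),
                     logical(1))
  kids <- kids[is_level]
  # case-insensitive lexicographic sibling order, stable
  kids[order(tolower(basename(kids)), basename(kids))]
}

#' Locate the project root above a path
#'
#' Walks up the directory ancestry until a `_p_` directory is found.
#'
#' @param start A path inside a tree (file or directory).
#' @return Absolute path of the project root directory.
#' @export
find_project_root <- function(start) {
  p <- norm_path(start)
  if (file.exists(p) && !dir.exists(p)) p <- dirname(p)
  while (TRUE) {
    cls <- classify_dirname(basename(p))
    if (!is.null(cls) && cls$kind == "project") return(p)
    parent <- dirname(p)
    if (parent == p) {
      stop(sprintf("%s is not inside a project tree (no '_p_' ancestor)",
                   start), call. = FALSE)
    }
    p <- parent
  }
}

#' Resolve the chain of levels from the project down to a path
#'
#' Given any path inside a tree, returns the project, investigation,
#' study and assay nodes on the way down to (and including) the level
#' containing `start`, each with its metadata loaded and its path
#' relative to the project root.  The result does not depend on where
#' the project root itself sits on disk.
#'
#' @param start A path inside a tree.
#' @return List of `isatree_node` objects, project first.
#' @export
resolve_chain <- function(start) {
  root <- find_project_root(start)
  p <- norm_path(start)
  if (file.exists(p) && !dir.exists(p)) p <- dirname(p)
  chain_dirs <- character()
  q <- p
  while (TRUE) {
    if (!is.null(classify_dirname(basename(q)))) {
      chain_dirs <- c(q, chain_dirs)
    }
    if (q == root) break
    q <- dirname(q)
  }
  nodes <- lapply(chain_dirs, load_node_shallow, project_root = root)
  kinds <- vapply(nodes, `[[`, character(1), "kind")
  expect <- LEVEL_KINDS[seq_along(nodes)]
  if (!identical(kinds, expect)) {
    stop("malformed tree: level order along ", start, " is ",
         paste(kinds, collapse = " > "), call. = FALSE)
  }
  nodes
}

#' Load a tree (or subtree) into memory
#'
#' Recursively loads a level directory and its nested levels, checking
#' that every child is of the successor kind.
#'
#' @param dir Path of a level directory (defaults interpret `dir`
#'   itself as the subtree root).
#' @return An `isatree_node` with `children` populated, siblings in
#'   case-insensitive lexicographic order.
#' @export
load_tree <- function(dir) {
  root <- find_project_root(dir)
  load_tree_rec(norm_path(dir), root)
}

load_tree_rec <- function(dir, project_root) {
  node <- load_node_shallow(dir, project_root)
  succ <- level_successor(node$kind)
  kids <- level_subdirs(dir)
  if (length(kids) && is.na(succ)) {
    stop(sprintf("assay %s must not contain nested levels", dir),
         call. = FALSE)
  }
  children <- list()
  for (k in kids) {
    cls <- classify_dirname(basename(k))
    if (!identical(cls$kind, succ)) {
      stop(sprintf(
        "hierarchy violation: %s (%s) directly under %s (%s); expected %s",
        basename(k), cls$kind, basename(dir), node$kind, succ),
        call. = FALSE)
    }
    children <- c(children, list(load_tree_rec(k, project_root)))
  }
  node$children <- children
  node
}

#' Flatten a loaded tree into a list of nodes
#'
#' Depth-first, parents before children.
#'
#' @param node An `isatree_node`.
#' @return List of nodes.
#' @export
flatten_tree <- function(node) {
  out <- list(node)
  for (ch in node$children) out <- c(out, flatten_tree(ch))
  out
}

count_levels <- function(node) {
  nodes <- flatten_tree(node)
  kinds <- vapply(nodes, `[[`, character(1), "kind")
  counts <- table(factor(kinds, levels = LEVEL_KINDS))
  stats::setNames(as.integer(counts), LEVEL_KINDS)
}
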