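# Upload planning and execution against a SEEK/FAIRDOMHub-style
# repository.  Planning is pure (no network): it walks one
# investigation, applies seekignore patterns and per-level "Upload to
# FAIRDOMHub" gates, and emits a topologically ordered plan of
# containers and file attachments.  The remote model only allows
# files at the assay level, so investigation-level files go into a
# synthetic "Investigation files" study holding an assay named after
# the investigation, and study-level files into a synthetic assay
# named after the study.  Execution talks to an endpoint object; an
# in-memory mock endpoint is provided so the whole flow is testable
# offline.

#' Parse a seekignore pattern file
#'
#' One glob pattern per line, `#` comments and blank lines skipped;
#' there is no negation.  Patterns are matched against project-root-
#' relative paths, at any directory depth: a pattern that matches a
#' directory excludes its entire subtree.
#'
#' @param path Pattern file; an absent file yields empty rules.
#' @return An `isatree_ignore` object.
#' @export
parse_seekignore <- function(path = NULL) {
  patterns <- character()
  if (!is.null(path) && file.exists(path)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- trimws(sub("\r$", "", lines))
    patterns <- lines[nzchar(lines) & !startsWith(lines, "#")]
  }
  structure(list(patterns = patterns), class = "isatree_ignore")
}

#' Build ignore rules from patterns
#'
#' @param patterns Character vector of glob patterns.
#' @return An `isatree_ignore` object.
#' @export
ignore_rules <- function(patterns = character()) {
  structure(list(patterns = as.character(patterns)),
            class = "isatree_ignore")
}

glob_match_segments <- function(pattern_segs, path_segs) {
  np <- length(pattern_segs); ns <- length(path_segs)
  if (np == 0L || np > ns) return(FALSE)
  regs <- vapply(pattern_segs, utils::glob2rx, character(1))
  for (start in seq_len(ns - np + 1L)) {
    ok <- TRUE
    for (k in seq_len(np)) {
      if (!grepl(regs[[k]], path_segs[[start + k - 1L]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Test paths against ignore rules
#'
#' @param rules An `isatree_ignore` object.
#' @param paths Relative paths (`/`-separated).
#' @return Logical vector: `TRUE` where the path is excluded.
#' @export
is_ignored <- function(rules, paths) {
  stopifnot(inherits(rules, "isatree_ignore"))
  if (length(rules$patterns) == 0L) return(rep(FALSE, length(paths)))
  pat_segs <- strsplit(rules$patterns, "/", fixed = TRUE)
  vapply(paths, function(p) {
    segs <- strsplit(p, "/", fixed = TRUE)[[1L]]
    any(vapply(pat_segs, glob_match_segments, logical(1),
               path_segs = segs))
  }, logical(1), USE.NAMES = FALSE)
}

upload_gate_open <- function(record) {
  val <- tryCatch(get_meta(record, "Upload to FAIRDOMHub"),
                  error = function(e) "Yes")
  !identical(trimws(val), "No")
}

#' List the files of an investigation selected for upload
#'
#' Walks every file under the investigation (metadata files
#' included), drops seekignore matches, and drops the whole subtree
#' of any level whose metadata gate `Upload to FAIRDOMHub` is set to
#' `No` (the gate is inherited by sublevels).
#'
#' @param inv Investigation directory path or loaded `isatree_node`.
#' @param rules An `isatree_ignore` object (empty rules when `NULL`).
#' @return Character vector of project-root-relative paths, sorted.
#' @export
files_to_upload <- function(inv, rules = NULL) {
  if (is.character(inv)) inv <- load_tree(inv)
  stopifnot(inherits(inv, "isatree_node"), inv$kind == "investigation")
  rules <- rules %||% ignore_rules()
  if (!upload_gate_open(inv$metadata)) return(character())

  closed <- character()
  for (n in flatten_tree(inv)) {
    if (!upload_gate_open(n$metadata)) closed <- c(closed, n$rel_path)
  }
  files <- list.files(inv$path, recursive = TRUE, all.files = TRUE,
                      no.. = TRUE)
  rel <- paste0(inv$rel_path, "/", files)
  keep <- !is_ignored(rules, rel)
  for (cl in closed) {
    keep <- keep & !startsWith(rel, paste0(cl, "/"))
  }
  sort(rel[keep])
}

#' Build an upload plan for an investigation
#'
#' Containers: one remote investigation; one remote study per local
#' study plus the synthetic `Investigation files` study; one remote
#' assay per local assay, plus an assay named after the investigation
#' (inside `Investigation files`) for investigation-level files and
#' one assay named after each study for its study-level files.  Every
#' selected file becomes a `data_file` item attached to an assay
#' container — never directly to a study or investigation — with
#' sharing policy from the owning level's `Sharing permission` key
#' (default `Private`) and license from its `License` key.
#' Containers precede their contents in the plan (topological order).
#'
#' @param inv Investigation directory path or loaded node.
#' @param rules Ignore rules (see [parse_seekignore()]).
#' @param project_id Identifier of the pre-existing remote project.
#' @return An `isatree_uploadplan`: `project_id`; `containers`
#'   (data.frame `key`, `kind`, `title`, `parent_key`, `synthetic`);
#'   `items` (data.frame `local_path`, `attach_key`, `attach_to`,
#'   `policy`, `license`).
#' @export
build_upload_plan <- function(inv, rules = NULL, project_id = NULL) {
  if (is.null(project_id)) {
    stop("project_id is required: the remote project page must exist ",
         "before upload", call. = FALSE)
  }
  if (is.character(inv)) inv <- load_tree(inv)
  stopifnot(inherits(inv, "isatree_node"), inv$kind == "investigation")
  rules <- rules %||% ignore_rules()
  files <- files_to_upload(inv, rules)

  containers <- data.frame(key = character(), kind = character(),
                           title = character(), parent_key = character(),
                           synthetic = logical(), stringsAsFactors = FALSE)
  add_container <- function(key, kind, title, parent_key,
                            synthetic = FALSE) {
    containers <<- rbind(containers,
                         data.frame(key = key, kind = kind, title = title,
                                    parent_key = parent_key,
                                    synthetic = synthetic,
                                    stringsAsFactors = FALSE))
  }
  items <- data.frame(local_path = character(), attach_key = character(),
                      attach_to = character(), policy = character(),
                      license = character(), stringsAsFactors = FALSE)

  level_policy <- function(record) {
    pol <- tryCatch(get_meta(record, "Sharing permission"),
                    error = function(e) "")
    if (identical(trimws(pol), "Public")) "Public" else "Private"
  }
  level_license <- function(record) {
    tryCatch(get_meta(record, "License"), error = function(e) "")
  }

  plan <- function() {
    structure(list(project_id = project_id, containers = containers,
                   items = items),
              class = "isatree_uploadplan")
  }
  if (!upload_gate_open(inv$metadata)) return(plan())

  add_container("inv", "investigation", inv$name, "")
  add_container("s:__invfiles__", "study", "Investigation files", "inv",
                synthetic = TRUE)
  add_container("a:__invfiles__", "assay", inv$name, "s:__invfiles__",
                synthetic = TRUE)

  # attach-key lookup: level rel_path -> assay container key
  attach_map <- list()
  attach_map[[inv$rel_path]] <- "a:__invfiles__"
  for (st in Filter(function(s) upload_gate_open(s$metadata),
                    inv$children)) {
    skey <- paste0("s:", st$dirname)
    add_container(skey, "study", st$name, "inv")
    add_container(paste0("a:", st$dirname, ":self"), "assay", st$name,
                  skey, synthetic = TRUE)
    attach_map[[st$rel_path]] <- paste0("a:", st$dirname, ":self")
    for (as in Filter(function(a) upload_gate_open(a$metadata),
                      st$children)) {
      akey <- paste0("a:", st$dirname, "/", as$dirname)
      add_container(akey, "assay", as$name, skey)
      attach_map[[as$rel_path]] <- akey
    }
  }

  node_index <- flatten_tree(inv)
  titles <- stats::setNames(containers$title, containers$key)
  for (f in files) {
    owner <- NULL
    for (n in node_index) {
      if (startsWith(f, paste0(n$rel_path, "/")) &&
          (is.null(owner) || nchar(n$rel_path) > nchar(owner$rel_path))) {
        owner <- n
      }
    }
    akey <- attach_map[[owner$rel_path]]
    items <- rbind(items,
                   data.frame(local_path = f, attach_key = akey,
                              attach_to = unname(titles[[akey]]),
                              policy = level_policy(owner$metadata),
                              license = level_license(owner$metadata),
                              stringsAsFactors = FALSE))
  }
  plan()
}

#' @export
print.isatree_uploadplan <- function(x, ...) {
  cat(sprintf("<upload plan: project %s, %d containers, %d files>\n",
              x$project_id, nrow(x$containers), nrow(x$items)))
  invisible(x)
}

#' In-memory mock SEEK endpoint
#'
#' Implements the subset of a SEEK-style JSON API needed for bulk
#' upload — create investigation/study/assay/data_file objects and
#' attach file blobs — entirely in memory, recording every call, so
#' upload execution can be exercised offline.
#'
#' @return An `isatree_seek_mock` environment with fields `objects`
#'   (data.frame id/kind/title/parent_id/policy/license), `calls`
#'   (character log) and `blobs` (named list).  Setting `fail_after`
#'   to an integer makes the endpoint fail after that many create
#'   calls (for testing resumability).
#' @export
seek_mock_endpoint <- function() {
  e <- new.env(parent = emptyenv())
  e$objects <- data.frame(id = integer(), kind = character(),
                          title = character(), parent_id = integer(),
                          policy = character(), license = character(),
                          stringsAsFactors = FALSE)
  e$calls <- character()
  e$blobs <- list()
  e$next_id <- 1L
  e$fail_after <- NA_integer_
  class(e) <- "isatree_seek_mock"
  e
}

seek_find <- function(endpoint, kind, title, parent_id) {
  o <- endpoint$objects
  pid <- if (is.null(parent_id) || is.na(parent_id)) NA_integer_
         else parent_id
  same_parent <- if (is.na(pid)) is.na(o$parent_id)
                 else !is.na(o$parent_id) & o$parent_id == pid
  hit <- which(o$kind == kind & o$title == title & same_parent)
  if (length(hit)) o$id[[hit[[1L]]]] else NA_integer_
}

seek_create <- function(endpoint, kind, title, parent_id,
                        policy = "Private", license = "") {
  n_create <- sum(startsWith(endpoint$calls, "create"))
  if (!is.na(endpoint$fail_after) && n_create >= endpoint$fail_after) {
    stop("mock endpoint: simulated HTTP failure", call. = FALSE)
  }
  id <- endpoint$next_id
  endpoint$next_id <- id + 1L
  endpoint$objects <- rbind(
    endpoint$objects,
    data.frame(id = id, kind = kind, title = title,
               parent_id = if (is.null(parent_id)) NA_integer_
                           else as.integer(parent_id),
               policy = policy, license = license,
               stringsAsFactors = FALSE))
  endpoint$calls <- c(endpoint$calls,
                      sprintf("create %s %s (parent %s)", kind, title,
                              parent_id %||% NA))
  id
}

#' JSON payload for one planned object
#'
#' Renders the creation request body that would be POSTed to a
#' SEEK-style API for a container or data file.
#'
#' @param kind Object kind.
#' @param title Title.
#' @param parent_id Remote id of the parent container.
#' @param policy,license Sharing policy and license.
#' @return JSON string.
#' @export
seek_payload <- function(kind, title, parent_id = NULL,
                         policy = "Private", license = "") {
  body <- list(data = list(
    type = paste0(kind, "s"),
    attributes = list(
      title = title,
      policy = list(access = if (identical(policy, "Public")) "download"
                             else "no_access")
    )
  ))
  if (nzchar(license)) body$data$attributes$license <- license
  if (!is.null(parent_id)) {
    body$data$relationships <- list(parent = list(
      data = list(id = parent_id)))
  }
  jsonlite::toJSON(body, auto_unbox = TRUE)
}

#' Execute an upload plan against an endpoint
#'
#' Creates containers and data files in plan order.  Re-running with
#' an unchanged tree is a no-op: objects are matched by title within
#' their parent container and reused instead of recreated.  On
#' failure the transcript of completed steps is attached to the error
#' condition (field `transcript`) so the run can be resumed.
#'
#' @param plan An `isatree_uploadplan`.
#' @param endpoint An endpoint object (see [seek_mock_endpoint()]).
#' @param project_root Project root directory; needed to read file
#'   blobs (optional — paths are recorded unread when absent).
#' @return Transcript data.frame: `step`, `kind`, `title`,
#'   `local_path`, `remote_id`, `created`.
#' @export
execute_plan <- function(plan, endpoint, project_root = NULL) {
  stopifnot(inherits(plan, "isatree_uploadplan"))
  if (!inherits(endpoint, "isatree_seek_mock")) {
    stop("unsupported endpoint object", call. = FALSE)
  }
  transcript <- data.frame(step = integer(), kind = character(),
                           title = character(), local_path = character(),
                           remote_id = integer(), created = logical(),
                           stringsAsFactors = FALSE)
  step <- 0L
  note <- function(kind, title, local_path, id, created) {
    step <<- step + 1L
    transcript <<- rbind(transcript,
                         data.frame(step = step, kind = kind, title = title,
                                    local_path = local_path, remote_id = id,
                                    created = created,
                                    stringsAsFactors = FALSE))
  }
  ids <- list()  # container key -> remote id
  run <- function() {
    for (i in seq_len(nrow(plan$containers))) {
      co <- plan$containers[i, ]
      parent_id <- if (co$kind == "investigation") {
        suppressWarnings(as.integer(plan$project_id))
      } else {
        pid <- ids[[co$parent_key]]
        if (is.null(pid)) {
          stop("plan is not topologically ordered: parent ",
               sQuote(co$parent_key), " not yet created", call. = FALSE)
        }
        pid
      }
      existing <- seek_find(endpoint, co$kind, co$title, parent_id)
      id <- if (!is.na(existing)) existing
            else seek_create(endpoint, co$kind, co$title, parent_id)
      ids[[co$key]] <<- id
      note(co$kind, co$title, NA_character_, id, is.na(existing))
    }
    for (i in seq_len(nrow(plan$items))) {
      it <- plan$items[i, ]
      parent_id <- ids[[it$attach_key]]
      existing <- seek_find(endpoint, "data_file", it$local_path, parent_id)
      if (!is.na(existing)) {
        note("data_file", basename(it$local_path), it$local_path,
             existing, FALSE)
        next
      }
      id <- seek_create(endpoint, "data_file", it$local_path, parent_id,
                        policy = it$policy, license = it$license)
      blob <- if (!is.null(project_root)) {
        p <- file.path(project_root, it$local_path)
        if (file.exists(p)) readBin(p, "raw", n = file.size(p)) else raw()
      } else raw()
      endpoint$blobs[[it$local_path]] <- blob
      endpoint$calls <- c(endpoint$calls,
                          sprintf("attach blob %s", it$local_path))
      note("data_file", basename(it$local_path), it$local_path, id, TRUE)
    }
  }
  tryCatch(run(), error = function(e) {
    stop(structure(
      class = c("isatree_upload_error", "error", "condition"),
      list(message = paste0("upload aborted: ", conditionMessage(e)),
           call = NULL, transcript = transcript)))
  })
  transcript
}
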