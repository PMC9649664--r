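# The tab-delimited key-value metadata dialect.
#
# One pair per line, serialised as "<key>:\t<value>".  The trailing
# colon belongs to the serialisation, not to the key.  Files are
# hand-editable, so reading is forgiving: malformed lines are kept
# verbatim in a raw-lines annex (write-back is lossless), duplicate
# keys are preserved and flagged, a UTF-8 BOM is stripped.

new_metadata_record <- function(keys = character(), values = character(),
                                level = NA_character_,
                                source_path = NA_character_,
                                raw_lines = NULL, warnings = character()) {
  stopifnot(length(keys) == length(values))
  structure(
    list(
      keys = as.character(keys),
      values = as.character(values),
      level = level,
      source_path = source_path,
      # raw_lines: data.frame(after = index of preceding pair, line = text)
      raw_lines = raw_lines %||%
        data.frame(after = integer(), line = character(),
                   stringsAsFactors = FALSE),
      warnings = warnings
    ),
    class = "isatree_metadata"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.isatree_metadata <- function(x, ...) {
  src <- if (is.na(x$source_path)) "(in memory)" else x$source_path
  cat(sprintf("<metadata record: %d pairs, level %s, %s>\n",
              length(x$keys), x$level %||% NA, src))
  if (length(x$keys)) {
    cat(paste0("  ", format(x$keys), " : ", x$values, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
length.isatree_metadata <- function(x) length(x$keys)

strip_bom <- function(x) sub("^\ufeff", "", x)

#' Parse metadata text into a record
#'
#' Accepts LF and CRLF line endings and a leading UTF-8 BOM.  Each
#' non-blank line with a tab becomes one key-value pair; a trailing
#' colon on the key token is stripped (it is part of the on-disk form,
#' not of the key).  Lines without a tab are recorded as warnings and
#' kept verbatim so that [write_metadata()] reproduces the file.
#' Duplicate keys are preserved and flagged.
#'
#' @param text Character vector of lines, or a single string containing
#'   newlines.
#' @param level Level kind the record belongs to (optional, for
#'   reporting).
#' @param source_path Path recorded on the record (optional).
#' @return An `isatree_metadata` record.
#' @export
#' @examples
#' r <- parse_metadata("Upload to FAIRDOMHub:\tYes")
#' get_meta(r, "Upload to FAIRDOMHub")
parse_metadata <- function(text, level = NA_character_,
                           source_path = NA_character_) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  lines <- sub("\r$", "", as.character(text))
  if (length(lines)) lines[1L] <- strip_bom(lines[1L])

  keys <- character(); values <- character()
  raw_after <- integer(); raw_line <- character()
  warns <- character()

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    tab <- regexpr("\t", ln, fixed = TRUE)
    if (tab < 0L) {
      warns <- c(warns, sprintf("line %d: no tab separator: %s", i, ln))
      raw_after <- c(raw_after, length(keys))
      raw_line <- c(raw_line, ln)
      next
    }
    key <- substring(ln, 1L, tab - 1L)
    value <- substring(ln, tab + 1L)
    key <- sub(":$", "", key)
    if (!nzchar(key)) {
      warns <- c(warns, sprintf("line %d: empty key: %s", i, ln))
      raw_after <- c(raw_after, length(keys))
      raw_line <- c(raw_line, ln)
      next
    }
    if (key %in% keys) {
      warns <- c(warns, sprintf("line %d: duplicate key %s", i, sQuote(key)))
    }
    keys <- c(keys, key)
    values <- c(values, value)
  }

  new_metadata_record(
    keys, values, level = level, source_path = source_path,
    raw_lines = data.frame(after = raw_after, line = raw_line,
                           stringsAsFactors = FALSE),
    warnings = warns
  )
}

#' Read a metadata file
#'
#' @param path Path to a metadata file in the key-value dialect.
#' @param level Level kind (optional, recorded on the result).
#' @return An `isatree_metadata` record with `source_path` set.
#' @export
read_metadata <- function(path, level = NA_character_) {
  if (!file.exists(path)) {
    stop("metadata file not found: ", path, call. = FALSE)
  }
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) {
    lines <- strsplit(rawToChar(raw), "\n", fixed = TRUE)[[1L]]
    bad <- which(!validUTF8(lines))[1L]
    stop(sprintf("metadata file %s is not valid UTF-8 (line %d)",
                 path, bad), call. = FALSE)
  }
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  parse_metadata(lines, level = level, source_path = path)
}

#' Serialise a metadata record
#'
#' Each pair is emitted as `key + ":" + TAB + value` followed by the
#' line terminator (LF by default).  Pair order is preserved, and any
#' malformed raw lines captured at parse time are re-emitted at their
#' original positions, so `write(parse(f))` reproduces `f` up to the
#' configured terminator.
#'
#' @param record An `isatree_metadata` record.
#' @param eol Line terminator, default `"\n"`.
#' @return A single string.
#' @export
write_metadata <- function(record, eol = "\n") {
  stopifnot(inherits(record, "isatree_metadata"))
  bad <- grepl("\t", record$keys, fixed = TRUE)
  if (any(bad)) {
    stop("metadata keys must not contain tabs: ",
         paste(sQuote(record$keys[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(grepl("[\r\n]", record$keys)) || any(grepl("[\r\n]", record$values))) {
    stop("metadata keys and values must not contain newlines", call. = FALSE)
  }
  if (any(grepl("\t", record$values, fixed = TRUE))) {
    stop("metadata values must not contain tabs (they would break the dialect)",
         call. = FALSE)
  }
  n <- length(record$keys)
  out <- character(0)
  raws <- record$raw_lines
  emit_raw <- function(pos) raws$line[raws$after == pos]
  out <- c(out, emit_raw(0L))
  for (i in seq_len(n)) {
    out <- c(out, paste0(record$keys[i], ":\t", record$values[i]))
    out <- c(out, emit_raw(i))
  }
  if (length(out) == 0L) return("")
  paste0(paste(out, collapse = eol), eol)
}

#' Write a metadata record to a file
#'
#' UTF-8, no BOM.
#'
#' @param record An `isatree_metadata` record.
#' @param path Target file path.
#' @param eol Line terminator.
#' @return `path`, invisibly.
#' @export
save_metadata <- function(record, path, eol = "\n") {
  txt <- write_metadata(record, eol = eol)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(txt)), con)
  invisible(path)
}

#' Retrieve a metadata value by key
#'
#' Key matching trims surrounding whitespace on both sides (files are
#' hand-edited); values are returned verbatim.  With duplicate keys the
#' first value is returned with a warning.
#'
#' @param record An `isatree_metadata` record.
#' @param key Key to look up.
#' @param default If supplied, returned instead of erroring when the
#'   key is absent.
#' @return The value string.
#' @export
get_meta <- function(record, key, default = NULL) {
  stopifnot(inherits(record, "isatree_metadata"))
  hits <- which(trimws(record$keys) == trimws(key))
  if (length(hits) == 0L) {
    if (!is.null(default)) return(default)
    src <- if (is.na(record$source_path)) "in-memory record" else record$source_path
    stop(sprintf("key %s not found in %s", sQuote(key), src), call. = FALSE)
  }
  if (length(hits) > 1L) {
    warning(sprintf("key %s occurs %d times; returning the first value",
                    sQuote(key), length(hits)), call. = FALSE)
  }
  record$values[hits[[1L]]]
}

#' Set or append a metadata pair
#'
#' Replaces the value of the first matching key, or appends a new pair.
#'
#' @param record An `isatree_metadata` record.
#' @param key,value Pair to set.
#' @return The modified record.
#' @export
set_meta <- function(record, key, value) {
  stopifnot(inherits(record, "isatree_metadata"))
  hits <- which(trimws(record$keys) == trimws(key))
  if (length(hits)) {
    record$values[hits[[1L]]] <- value
  } else {
    record$keys <- c(record$keys, key)
    record$values <- c(record$values, value)
  }
  record
}

#' Build a metadata record from key-value vectors
#'
#' @param keys,values Equal-length character vectors.
#' @param level Level kind (optional).
#' @return An `isatree_metadata` record.
#' @export
metadata_record <- function(keys, values, level = NA_character_) {
  new_metadata_record(keys, values, level = level)
}
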