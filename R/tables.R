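# Sample-description tables: phenodata (master sample table, one row
# per sample), featuredata (measured-variable descriptions) and the
# per-assay analyte table.  phenodata/featuredata filenames carry a
# yyyymmdd version stamp; the stamp is treated as an opaque version
# ordinal, and the greatest stamp wins.

TABLE_ROLES <- c("phenodata", "featuredata", "analytes")

table_pattern <- function(role) {
  switch(role,
         phenodata   = "^phenodata_([0-9]{8})\\.txt$",
         featuredata = "^featuredata_([0-9]{8})\\.txt$",
         analytes    = "^analytes\\.txt$")
}

#' Load a sample/feature/analyte table
#'
#' Tables are plain TSV with a header row; the first column holds
#' identifiers.  For phenodata the identifiers must be unique.
#'
#' @param path Path to the table file.
#' @param role One of `"phenodata"`, `"featuredata"`, `"analytes"`;
#'   guessed from the filename when omitted.
#' @return An `isatree_table`: list with `role`, `data` (data.frame,
#'   character columns), `date_stamp` (`Date` or `NA`) and `path`.
#' @export
load_table <- function(path, role = NULL) {
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  base <- basename(path)
  if (is.null(role)) {
    role <- TABLE_ROLES[vapply(TABLE_ROLES,
                               function(r) grepl(table_pattern(r), base),
                               logical(1))]
    if (length(role) != 1L) {
      stop("cannot infer table role from filename: ", base, call. = FALSE)
    }
  }
  role <- match.arg(role, TABLE_ROLES)
  stamp <- NA
  m <- regmatches(base, regexec(table_pattern(role), base))[[1L]]
  if (length(m) == 2L) stamp <- as.Date(m[[2L]], format = "%Y%m%d")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "",
                          blank.lines.skip = TRUE, fileEncoding = "UTF-8")
  if (role == "phenodata" && nrow(df) > 0L) {
    ids <- df[[1L]]
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) {
      stop("duplicate sample identifiers in ", base, ": ",
           paste(sQuote(dup), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(role = role, data = df, date_stamp = stamp, path = path),
            class = "isatree_table")
}

#' Write a table back to TSV
#'
#' Cell values and column order are preserved.
#'
#' @param table An `isatree_table`.
#' @param path Target path.
#' @return `path`, invisibly.
#' @export
save_table <- function(table, path) {
  stopifnot(inherits(table, "isatree_table"))
  utils::write.table(table$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Pick the latest versioned table in a directory
#'
#' Among files matching the role's filename pattern
#' (`phenodata_yyyymmdd.txt`, `featuredata_yyyymmdd.txt`,
#' `analytes.txt`), returns the one with the lexicographically
#' greatest date stamp.
#'
#' @param dir Directory to search.
#' @param role Table role.
#' @return An `isatree_table`, or `NULL` when no file matches.
#' @export
latest_table <- function(dir, role = "phenodata") {
  role <- match.arg(role, TABLE_ROLES)
  files <- list.files(dir, pattern = table_pattern(role))
  if (length(files) == 0L) return(NULL)
  files <- sort(files)                      # yyyymmdd sorts lexicographically
  load_table(file.path(dir, files[[length(files)]]), role = role)
}

#' @export
print.isatree_table <- function(x, ...) {
  cat(sprintf("<%s table: %d rows x %d cols%s>\n", x$role,
              nrow(x$data), ncol(x$data),
              if (!is.na(x$date_stamp)) paste0(", stamp ", x$date_stamp) else ""))
  invisible(x)
}
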