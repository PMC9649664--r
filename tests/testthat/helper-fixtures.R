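# Shared helpers: tiny trees built in code under tempdirs.

tmp_root <- function() {
  d <- tempfile("tree")
  dir.create(d)
  d
}

# Minimal fully answered project > investigation > study > assay tree.
make_mini_tree <- function(root = tmp_root(), name = "Demo") {
  withr_opts <- options(isatree.date = as.Date("2020-01-01"))
  on.exit(options(withr_opts))
  tpl <- load_repository(bundled_templates_path())
  ans <- function(title) list(Title = title, Description = title,
                              `Principal investigator` = "J. Doe")
  p <- make_level(root, "project", name, answers = ans(name),
                  templates = tpl)
  i <- make_level(p$path, "investigation", "01_Inv",
                  answers = ans("01_Inv"), templates = tpl)
  s <- make_level(i$path, "study", "01_Study", answers = ans("01_Study"),
                  templates = tpl)
  a <- make_level(s$path, "assay", "Trial1", assay_class = "wet",
                  assay_type = "RNAisol",
                  answers = list(Description = "d", Protocol = "p"),
                  templates = tpl)
  list(root = root, project = p, investigation = i, study = s, assay = a,
       templates = tpl)
}

random_printable <- function(n, min_len = 1, max_len = 12) {
  pool <- c(LETTERS, letters, 0:9, " ", ".", "-", "_", ",", ";", "(", ")")
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    paste(sample(pool, len, replace = TRUE), collapse = "")
  }, character(1))
}

random_record <- function(n_pairs) {
  keys <- random_printable(n_pairs)
  keys <- trimws(keys)
  keys <- keys[nzchar(keys)]
  keys <- make.unique(keys)
  # keys must not end in ":" (serialisation ambiguity) nor start "!"
  keys <- paste0("K", keys)
  keys <- sub(":+$", "", keys)
  values <- random_printable(length(keys), 0, 20)
  metadata_record(keys, values)
}
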