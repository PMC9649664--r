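test_that("show_tree renders, writes TREE.TXT and counts levels", {
  tr <- make_mini_tree()
  rep <- show_tree(tr$project$path, levels_only = TRUE)
  expect_true(file.exists(file.path(tr$project$path, "TREE.TXT")))
  expect_equal(unname(rep$counts),
               c(1L, 1L, 1L, 1L))
  # counts equal an independent walk over prefixed directories
  walk <- list.files(tr$project$path, recursive = TRUE,
                     include.dirs = TRUE)
  tally <- vapply(c("_I_", "_S_", "_A_"), function(pre)
    sum(startsWith(basename(walk), pre)), integer(1))
  expect_equal(unname(rep$counts[c("investigation", "study", "assay")]),
               unname(tally))
  # levels-only rendering carries no plain subdirectories
  expect_false(grepl("reports", rep$rendered))
  # two runs are byte-identical
  rep2 <- show_tree(tr$project$path, levels_only = TRUE)
  expect_identical(rep$rendered, rep2$rendered)
})

test_that("an empty project renders as a single line", {
  d <- tmp_root()
  tpl <- load_repository(bundled_templates_path())
  p <- make_level(d, "project", "Empty", answers = list(Title = "t"),
                  templates = tpl)
  rep <- show_tree(p$path, levels_only = TRUE, write = FALSE)
  expect_equal(rep$rendered, paste0(p$dirname, "\n"))
})

test_that("show_metadata aggregates every pair exactly once", {
  tr <- make_mini_tree()
  doc <- show_metadata(tr$project$path, format = "plain", write = FALSE)
  nodes <- flatten_tree(load_tree(tr$project$path))
  for (n in nodes) {
    expect_true(grepl(n$rel_path, doc, fixed = TRUE))
  }
  # multiset of pairs in the document equals the per-file parses
  doc_pairs <- regmatches(doc, gregexpr("[^\n]+:\t[^\n]*", doc))[[1]]
  file_pairs <- unlist(lapply(nodes, function(n)
    paste0(n$metadata$keys, ":\t", n$metadata$values)))
  expect_equal(sort(doc_pairs), sort(file_pairs))
  md <- show_metadata(tr$project$path, format = "markdown", write = FALSE)
  expect_true(grepl("^# \\.", md))
  expect_true(grepl("\n#### ", md))  # assay heading depth = 4
})

test_that("xcheck reports missing mandatory values and missing files", {
  tr <- make_mini_tree()
  expect_equal(nrow(xcheck_metadata(tr$project$path)), 0L)

  # unanswered mandatory prompt on a fresh assay -> exactly that finding
  a2 <- make_level(tr$study$path, "assay", "Blank", assay_class = "dry",
                   assay_type = "NGS", answers = list(),
                   templates = tr$templates)
  f <- xcheck_metadata(tr$project$path)
  expect_true(all(f$path == a2$rel_path))
  expect_setequal(f$key, c("Description", "Protocol"))
  expect_true(all(f$problem == "missing_value"))

  # deleting one metadata file adds exactly one missing_file finding
  before <- f
  unlink(file.path(tr$study$path, "_STUDY_METADATA.TXT"))
  after <- xcheck_metadata(tr$project$path)
  added <- setdiff(
    paste(after$path, after$key, after$problem),
    paste(before$path, before$key, before$problem))
  expect_length(added, 1L)
  expect_true(grepl("missing_file", added))
})

test_that("xcheck findings are monotone under answering and blanking", {
  tr <- make_mini_tree()
  a2 <- make_level(tr$study$path, "assay", "Mono", assay_class = "dry",
                   assay_type = "NGS", answers = list(),
                   templates = tr$templates)
  n0 <- nrow(xcheck_metadata(tr$project$path))
  # answering a mandatory key never adds findings
  mp <- file.path(a2$path, "_ASSAY_METADATA.TXT")
  rec <- read_metadata(mp)
  rec <- set_meta(rec, "Description", "now described")
  save_metadata(rec, mp)
  n1 <- nrow(xcheck_metadata(tr$project$path))
  expect_equal(n1, n0 - 1L)
  # blanking a mandatory value adds exactly one
  rec <- set_meta(rec, "Protocol", "")
  save_metadata(rec, mp)
  expect_equal(nrow(xcheck_metadata(tr$project$path)), n1)
  rec <- set_meta(rec, "Description", "")
  save_metadata(rec, mp)
  expect_equal(nrow(xcheck_metadata(tr$project$path)), n1 + 1L)
})

test_that("path length findings start exactly one past the limit", {
  d <- tmp_root()
  tpl <- load_repository(bundled_templates_path())
  p <- make_level(d, "project", "PL", answers = list(Title = "t"),
                  templates = tpl)
  # construct a file whose simulated absolute path length is exact
  prefix <- "C:/mnt"
  dir.create(file.path(p$path, "reports"), showWarnings = FALSE)
  # length(prefix)+1+length(_p_PL)+1+... build a name to land on 247
  base_len <- nchar(paste0(prefix, "/", basename(p$path), "/"))
  fname <- strrep("x", 247L - base_len)
  file.create(file.path(p$path, fname))
  f247 <- check_path_lengths(p$path, limit = 247, mount_prefix = prefix)
  expect_equal(nrow(f247[f247$path == fname, ]), 0L)
  fname2 <- strrep("y", 248L - base_len)
  file.create(file.path(p$path, fname2))
  f248 <- check_path_lengths(p$path, limit = 247, mount_prefix = prefix)
  expect_equal(f248$path, fname2)
  expect_equal(f248$problem, "path_too_long")
  # threshold probe: smallest flagged length is limit + 1
  expect_true(grepl("length 248", f248$key))
  # an empty tree yields nothing
  expect_equal(nrow(check_path_lengths(tempfile(), limit = 247)), 0L)
})
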