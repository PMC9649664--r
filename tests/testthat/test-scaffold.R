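test_that("name sanitisation is idempotent and rejects degenerate names", {
  expect_equal(sanitise_name("Lab Trials 2020"), "Lab-Trials-2020")
  expect_equal(sanitise_name("qPCR"), "qPCR")
  expect_error(sanitise_name("///"), "empty")
  expect_error(sanitise_name("NUL"), "reserved")
  set.seed(7)
  pool <- c(LETTERS, letters, 0:9, " ", ".", "-", "_", "/", "\\", "*", "?")
  for (i in 1:1000) {
    raw <- paste(sample(pool, sample(1:15, 1), replace = TRUE),
                 collapse = "")
    s <- tryCatch(sanitise_name(raw), error = function(e) NULL)
    if (!is.null(s)) expect_equal(sanitise_name(s), s)
  }
})

test_that("levels scaffold with prefixes, metadata and subdirectories", {
  tr <- make_mini_tree()
  i <- tr$investigation
  expect_true(startsWith(basename(i$path), "_I_"))
  expect_true(file.exists(file.path(i$path, "_INVESTIGATION_METADATA.TXT")))
  expect_true(file.exists(file.path(i$path, "phenodata_20200101.txt")))
  expect_true(file.exists(file.path(i$path, "featuredata_20200101.txt")))
  expect_true(all(dir.exists(file.path(i$path,
                                       c("reports", "presentations",
                                         "other")))))
  expect_true(dir.exists(file.path(tr$study$path, "reports")))
  # wet assay: output/raw present, scripts absent, analytes seeded
  a <- tr$assay
  expect_true(dir.exists(file.path(a$path, "output", "raw")))
  expect_false(dir.exists(file.path(a$path, "scripts")))
  expect_true(file.exists(file.path(a$path, "analytes.txt")))
  expect_true(file.exists(file.path(a$path, "_ASSAY_METADATA.TXT")))
})

test_that("dry assays get input, scripts and output", {
  tr <- make_mini_tree()
  a <- make_level(tr$study$path, "assay", "Pipe", assay_class = "dry",
                  assay_type = "NGS",
                  answers = list(Description = "d", Protocol = "p"),
                  templates = tr$templates)
  expect_true(all(dir.exists(file.path(a$path,
                                       c("input", "scripts", "output")))))
  expect_false(dir.exists(file.path(a$path, "output", "raw")))
})

test_that("creation never overwrites and enforces strict nesting", {
  tr <- make_mini_tree()
  expect_error(make_level(tr$root, "project", "Demo",
                          templates = tr$templates), "exists")
  expect_error(make_level(tr$investigation$path, "study", "01_Study",
                          templates = tr$templates), "exists")
  # assay directly under an investigation is rejected
  expect_error(make_level(tr$investigation$path, "assay", "X",
                          assay_class = "dry", assay_type = "NGS",
                          templates = tr$templates), "study")
  # study under a study likewise
  expect_error(make_level(tr$study$path, "study", "Nested",
                          templates = tr$templates), "investigation")
  # unknown assay type
  expect_error(make_level(tr$study$path, "assay", "Y",
                          assay_class = "wet", assay_type = "Nope",
                          templates = tr$templates), "unknown assay type")
})

test_that("failed creation leaves no partial directory behind", {
  tr <- make_mini_tree()
  tpl <- tr$templates
  tpl$classes$wet$Broken <- tpl$classes$wet$RNAisol
  tpl$classes$wet$Broken$type_name <- "Broken"
  tpl$classes$wet$Broken$extra_files <- list()
  tpl$classes$wet$Broken$subdirs <- character()
  # force a failure mid-creation: metadata with an illegal tab value
  expect_error(
    make_level(tr$study$path, "assay", "Z", assay_class = "wet",
               assay_type = "Broken",
               answers = list(Description = "a\tb"),
               templates = tpl),
    "tab")
  expect_false(any(grepl("^_A_Z-", list.files(tr$study$path))))
})

test_that("scaffolded dirnames classify back to their creation request", {
  tr <- make_mini_tree()
  set.seed(11)
  for (i in 1:10) {
    nm <- sanitise_name(paste0("S", paste(sample(letters, 5), collapse = "")))
    st <- make_level(tr$investigation$path, "study", nm,
                     answers = list(Title = nm, Description = nm),
                     templates = tr$templates)
    cls <- classify_dirname(st$dirname)
    expect_equal(cls$kind, "study")
    expect_equal(cls$name, nm)
    an <- paste0(nm, "-x")  # hyphenated assay name
    a <- make_level(st$path, "assay", an, assay_class = "dry",
                    assay_type = "Statistics",
                    answers = list(Description = "d", Protocol = "p"),
                    templates = tr$templates)
    acl <- classify_dirname(a$dirname)
    expect_equal(acl$kind, "assay")
    expect_equal(acl$name, an)
    expect_equal(acl$assay_type, "Statistics")
  }
})

test_that("init_tree_root installs Templates once and relocatably", {
  d <- tmp_root()
  init_tree_root(d)
  expect_true(dir.exists(file.path(d, "Templates", "DRY")))
  expect_true(dir.exists(file.path(d, "Templates", "WET")))
  expect_message(init_tree_root(d), "already present")
  # a project made under the root uses the local repository
  p <- make_level(d, "project", "Rel", answers = list(Title = "t"))
  expect_true(file.exists(file.path(p$path, "_PROJECT_METADATA.TXT")))
})
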