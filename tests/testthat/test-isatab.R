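test_that("the bundled mapping loads and covers the bundled wet types", {
  m <- load_mapping()
  hit <- m$entries[m$entries$key == "Title" &
                     m$entries$section == "INVESTIGATION", ]
  expect_equal(hit$field, "Investigation Title")
  tpl <- load_repository(bundled_templates_path())
  for (type in names(tpl$classes$wet)) {
    cfg <- m$assay_config[m$assay_config$type == type, ]
    expect_equal(nrow(cfg), 1L)
    expect_true(nzchar(cfg$technology))
  }
  expect_warning(
    out <- isatree:::assay_types_for(m, "Unheard", "wet"), "defaults")
  expect_equal(out[[2]], "unknown technology")
})

test_that("an investigation converts to one i_ file plus per-study files", {
  root <- tmp_root()
  p <- generate_strt_fixture(root)
  inv <- file.path(p$path, "_I_STRT")
  doc <- build_isatab(inv)
  expect_length(doc$studies, 4L)
  expect_length(doc$study_files, 4L)
  expect_length(doc$assay_files, 8L)
  expect_equal(get_field <- doc$sections$INVESTIGATION[["Investigation Title"]],
               "STRT")
  out <- tempfile("isa")
  files <- write_isatab(doc, out)
  expect_length(files, 1L + 4L + 8L)
  expect_true(file.exists(file.path(out, "i_Investigation.txt")))
})

test_that("metadata pairs land in mapped fields or Comment fields", {
  tr <- make_mini_tree()
  doc <- build_isatab(tr$investigation$path)
  inv_meta <- load_tree(tr$investigation$path)$metadata
  all_fields <- unlist(c(doc$sections,
                         lapply(doc$studies, function(b) b)),
                       use.names = TRUE)
  labels <- names(rapply(doc$sections, function(x) x, how = "unlist"))
  sec_labels <- unlist(lapply(doc$sections, names))
  for (k in inv_meta$keys) {
    mapped <- any(sec_labels == paste0("Comment[pISA:", k, "]")) ||
      k %in% load_mapping()$entries$key
    expect_true(mapped, info = k)
  }
  # project pairs are never dropped either
  proj_meta <- resolve_chain(tr$investigation$path)[[1]]$metadata
  for (k in proj_meta$keys) {
    present <- any(grepl(k, sec_labels, fixed = TRUE)) ||
      k %in% load_mapping()$entries$key
    expect_true(present, info = k)
  }
})

test_that("study samples come from phenodata with Study-column attribution", {
  root <- tmp_root()
  p <- generate_cpb_fixture(root)
  inv <- file.path(p$path, "_I_01_LabTrials")
  doc <- build_isatab(inv)
  pheno <- latest_table(inv, "phenodata")
  # with a Study column each sample lands only in its own study
  s1 <- doc$study_files[["s__S_01_Study.txt"]]
  expect_equal(s1[["Sample Name"]],
               pheno$data[pheno$data$Study == "01_Study", 1])
  # referential closure, checked independently of the validator
  for (st in names(doc$studies)) {
    blk <- doc$studies[[st]]
    s_tab <- doc$study_files[[blk$STUDY[["Study File Name"]]]]
    for (af in blk$`STUDY ASSAYS`[["Study Assay File Name"]]) {
      used <- setdiff(doc$assay_files[[af]][["Sample Name"]], "")
      expect_true(all(used %in% s_tab[["Sample Name"]]))
    }
    expect_true(all(s_tab[["Sample Name"]] %in% pheno$data[[1]]))
  }
  expect_equal(nrow(validate_isatab_structure(doc, pheno)), 0L)
})

test_that("without a Study column every sample goes everywhere, with warning", {
  tr <- make_mini_tree()
  st2 <- make_level(tr$investigation$path, "study", "02_Study",
                    answers = list(Title = "t", Description = "d"),
                    templates = tr$templates)
  writeLines(c("Sample ID\tTreat", "s1\ta", "s2\tb"),
             file.path(tr$investigation$path, "phenodata_20200102.txt"))
  expect_warning(doc <- build_isatab(tr$investigation$path), "every study")
  for (sf in doc$study_files) {
    expect_equal(sf[["Sample Name"]], c("s1", "s2"))
  }
})

test_that("an investigation without studies still exports validly", {
  d <- tmp_root()
  tpl <- load_repository(bundled_templates_path())
  p <- make_level(d, "project", "E", answers = list(Title = "t"),
                  templates = tpl)
  i <- make_level(p$path, "investigation", "01",
                  answers = list(Title = "t", Description = "d"),
                  templates = tpl)
  doc <- build_isatab(i$path)
  expect_length(doc$studies, 0L)
  expect_equal(nrow(validate_isatab_structure(doc)), 0L)
})

test_that("exports re-parse to an equal document, byte-stably", {
  root <- tmp_root()
  p <- generate_strt_fixture(root)
  inv <- file.path(p$path, "_I_STRT")
  doc <- build_isatab(inv)
  out <- tempfile("isa")
  write_isatab(doc, out)
  doc2 <- read_isatab(out)
  expect_equal(unclass(doc2), unclass(doc))
  # re-export after a no-op change is byte-identical
  out2 <- tempfile("isa")
  write_isatab(build_isatab(inv), out2)
  for (f in list.files(out)) {
    expect_identical(readLines(file.path(out2, f)),
                     readLines(file.path(out, f)))
  }
})

test_that("the validator reports dangling sample references", {
  root <- tmp_root()
  p <- generate_strt_fixture(root)
  inv <- file.path(p$path, "_I_STRT")
  doc <- build_isatab(inv)
  pheno <- latest_table(inv, "phenodata")
  expect_equal(nrow(validate_isatab_structure(doc, pheno)), 0L)
  # deleting a sample row leaves assay references dangling
  sf <- names(doc$study_files)[[1]]
  victim <- doc$study_files[[sf]][["Sample Name"]][[1]]
  doc$study_files[[sf]] <-
    doc$study_files[[sf]][doc$study_files[[sf]][["Sample Name"]] != victim, ]
  f <- validate_isatab_structure(doc, pheno)
  expect_gt(nrow(f), 0L)
  expect_true(victim %in% f$key)
  # a missing referenced file is also a finding
  doc2 <- build_isatab(inv)
  doc2$assay_files[[1]] <- NULL
  expect_true(any(validate_isatab_structure(doc2)$problem ==
                    "missing_file"))
})
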