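test_that("seekignore patterns exclude matching subtrees", {
  d <- tmp_root()
  writeLines(c("# comment", "", "output/raw", "*.log"),
             f <- file.path(d, "seekignore.txt"))
  rules <- parse_seekignore(f)
  expect_length(rules$patterns, 2L)
  expect_true(is_ignored(rules, "_p_X/_I_A/_S_B/_A_C-T/output/raw/f.txt"))
  expect_true(is_ignored(rules, "_p_X/_I_A/run.log"))
  expect_false(is_ignored(rules, "_p_X/_I_A/output/final.txt"))
  expect_false(is_ignored(parse_seekignore(NULL), "anything/at/all"))
})

test_that("exclusions equal a brute-force per-file pattern filter", {
  root <- tmp_root()
  p <- generate_random_tree(root, list(seed = 3))
  inv <- load_tree(file.path(p$path, "_I_01_Inv"))
  rules <- ignore_rules(c("output/raw", "reports"))
  got <- files_to_upload(inv, rules)
  all_files <- paste0(inv$rel_path, "/",
                      list.files(inv$path, recursive = TRUE,
                                 all.files = TRUE, no.. = TRUE))
  brute <- sort(all_files[!vapply(all_files, function(f) {
    segs <- strsplit(f, "/")[[1]]
    has <- function(pat) {
      ps <- strsplit(pat, "/")[[1]]
      any(vapply(seq_len(max(0, length(segs) - length(ps) + 1)),
                 function(s) all(segs[s:(s + length(ps) - 1)] == ps),
                 logical(1)))
    }
    has("output/raw") || has("reports")
  }, logical(1))])
  expect_equal(got, brute)
})

test_that("upload gates prune levels and are inherited", {
  root <- tmp_root()
  p <- generate_random_tree(root, list(seed = 4))
  inv_path <- file.path(p$path, "_I_01_Inv")
  all_files <- files_to_upload(inv_path)
  expect_true(any(grepl("_STUDY_METADATA", all_files)))  # metadata included

  # close the gate on one study: its whole subtree vanishes
  st <- file.path(inv_path, "_S_01_Study")
  mp <- file.path(st, "_STUDY_METADATA.TXT")
  rec <- set_meta(read_metadata(mp), "Upload to FAIRDOMHub", "No")
  save_metadata(rec, mp)
  gated <- files_to_upload(inv_path)
  expect_true(length(gated) < length(all_files))
  expect_false(any(startsWith(gated, paste0(p$dirname, "/_I_01_Inv/_S_01_Study/"))))
  # gate monotonicity
  expect_true(all(gated %in% all_files))

  # closing the investigation gate empties the list
  imp <- file.path(inv_path, "_INVESTIGATION_METADATA.TXT")
  save_metadata(set_meta(read_metadata(imp), "Upload to FAIRDOMHub", "No"),
                imp)
  expect_length(files_to_upload(inv_path), 0L)
})

test_that("plans follow the assay-only attachment convention", {
  root <- tmp_root()
  p <- generate_random_tree(root, list(seed = 5,
                                       studies_per_investigation = 2L))
  inv <- file.path(p$path, "_I_01_Inv")
  plan <- build_upload_plan(inv, project_id = 161)
  co <- plan$containers
  # 1 investigation; 2 studies + synthetic "Investigation files";
  # 4 assays (2 per study) + 2 study-named + 1 investigation-named
  expect_equal(sum(co$kind == "investigation"), 1L)
  expect_equal(sum(co$kind == "study"), 3L)
  expect_equal(sum(co$kind == "assay"), 4L + 2L + 1L)
  expect_true("Investigation files" %in% co$title[co$kind == "study"])
  # every file attaches to an assay container
  kind_of <- stats::setNames(co$kind, co$key)
  expect_true(all(kind_of[plan$items$attach_key] == "assay"))
  # containers precede their contents (topological order)
  pos <- stats::setNames(seq_len(nrow(co)), co$key)
  for (i in seq_len(nrow(co))) {
    if (nzchar(co$parent_key[i])) {
      expect_lt(pos[[co$parent_key[i]]], i)
    }
  }
  # investigation-level files sit in the investigation-named assay
  inv_meta <- plan$items[grepl("_INVESTIGATION_METADATA",
                               plan$items$local_path), ]
  expect_equal(inv_meta$attach_key, "a:__invfiles__")
  # study metadata sits in the study-named synthetic assay
  st_meta <- plan$items[grepl("_S_01_Study/_STUDY_METADATA",
                              plan$items$local_path), ]
  expect_equal(st_meta$attach_key, "a:_S_01_Study:self")
  expect_error(build_upload_plan(inv), "project_id")
})

test_that("policy and license flow from level metadata into the plan", {
  tr <- make_mini_tree()
  mp <- file.path(tr$assay$path, "_ASSAY_METADATA.TXT")
  rec <- read_metadata(mp)
  rec <- set_meta(rec, "Sharing permission", "Public")
  rec <- set_meta(rec, "License", "CC-BY-4.0")
  save_metadata(rec, mp)
  plan <- build_upload_plan(tr$investigation$path, project_id = 1)
  assay_items <- plan$items[startsWith(plan$items$local_path,
                                       paste0(tr$assay$rel_path, "/")), ]
  expect_true(all(assay_items$policy == "Public"))
  expect_true(all(assay_items$license == "CC-BY-4.0"))
  other_items <- plan$items[!startsWith(plan$items$local_path,
                                        paste0(tr$assay$rel_path, "/")), ]
  expect_true(all(other_items$policy == "Private"))
})

test_that("execution creates every planned object and is idempotent", {
  root <- tmp_root()
  p <- generate_random_tree(root, list(seed = 6))
  inv <- file.path(p$path, "_I_01_Inv")
  plan <- build_upload_plan(inv, project_id = 9)
  ep <- seek_mock_endpoint()
  tr1 <- execute_plan(plan, ep, project_root = p$path)
  n_create <- sum(startsWith(ep$calls, "create"))
  expect_equal(n_create, nrow(plan$containers) + nrow(plan$items))
  # every listed file has a remote id in the transcript
  files <- tr1[tr1$kind == "data_file", ]
  expect_setequal(files$local_path, plan$items$local_path)
  expect_false(any(is.na(files$remote_id)))
  # sharing policy recorded remotely
  restricted <- ep$objects[ep$objects$kind == "data_file", ]
  expect_true(all(restricted$policy == "Private"))
  # no file object has a non-assay parent
  assay_ids <- ep$objects$id[ep$objects$kind == "assay"]
  expect_true(all(restricted$parent_id %in% assay_ids))
  # second run: nothing new is created
  tr2 <- execute_plan(plan, ep, project_root = p$path)
  expect_false(any(tr2$created))
  expect_equal(sum(startsWith(ep$calls, "create")), n_create)
})

test_that("a mid-run failure aborts with a resumable transcript", {
  root <- tmp_root()
  p <- generate_random_tree(root, list(seed = 8))
  inv <- file.path(p$path, "_I_01_Inv")
  plan <- build_upload_plan(inv, project_id = 2)
  ep <- seek_mock_endpoint()
  ep$fail_after <- 3L
  err <- tryCatch(execute_plan(plan, ep, project_root = p$path),
                  isatree_upload_error = function(e) e)
  expect_s3_class(err, "isatree_upload_error")
  expect_equal(nrow(err$transcript), 3L)
  # resuming against the same endpoint completes without recreating
  ep$fail_after <- NA_integer_
  tr <- execute_plan(plan, ep, project_root = p$path)
  expect_equal(sum(tr$created), nrow(plan$containers) +
                 nrow(plan$items) - 3L)
})
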