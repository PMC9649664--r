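# Deterministic example trees.  Two generators mirror the published
# shapes of real projects managed with this layout — an insect
# pesticide-development project (3 investigations, 16 studies, wet
# and dry assays) and a de novo transcriptome-assembly project (1
# investigation, 4 studies, dry assays only) — and a third builds
# seeded random trees for property tests.  Only tree SHAPE is
# reproduced; all file contents are short deterministic placeholders
# derived from a seed and the path, so regeneration is byte-stable.

placeholder_text <- function(seed, relpath) {
  sprintf("placeholder %s #%d", relpath,
          sum(utf8ToInt(paste0(seed, "/", relpath))) %% 10000L)
}

seed_file <- function(root, relpath, seed) {
  p <- file.path(root, relpath)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  writeLines(placeholder_text(seed, relpath), p)
}

fixture_answers <- function(kind, title, extra = list()) {
  base <- switch(kind,
    project = list(Title = title, "Principal investigator" = "J. Doe"),
    investigation = list(Title = title,
                         Description = paste("Investigation", title)),
    study = list(Title = title, Description = paste("Study", title)),
    assay = list(Description = paste("Assay", title)))
  utils::modifyList(base, extra)
}

check_empty_target <- function(root, dirname) {
  if (file.exists(file.path(root, dirname))) {
    stop("fixture target already exists: ", file.path(root, dirname),
         call. = FALSE)
  }
}

write_phenodata <- function(inv_path, samples, studies, stamp = "20200101") {
  p <- file.path(inv_path, sprintf("phenodata_%s.txt", stamp))
  lines <- c("Sample ID\tStudy\tTreatment\tDescription",
             sprintf("%s\t%s\t%s\tsample %s", samples, studies,
                     rep_len(c("control", "treated"), length(samples)),
                     samples))
  writeLines(lines, p)
}

#' Generate the pesticide-project example tree
#'
#' A project with three investigations and sixteen studies in total.
#' The first investigation, `_I_01_LabTrials`, holds eleven studies:
#' three on dsRNA design and production (dry assays) followed by
#' eight feeding-trial studies whose wet `RNAisol` assays carry an
#' `analytes.txt` table recording isolated-RNA quantity and quality.
#' The remaining five studies are split across the other two
#' investigations.  Each investigation carries a populated phenodata
#' table.
#'
#' @param root Directory in which to create the project; the project
#'   directory itself must not pre-exist.
#' @param seed Integer seed controlling placeholder file contents.
#' @return The loaded project `isatree_node`, invisibly.
#' @export
generate_cpb_fixture <- function(root, seed = 1L) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  check_empty_target(root, "_p_CPB")
  templates <- load_repository(bundled_templates_path())
  old <- options(isatree.date = as.Date("2020-01-01"))
  on.exit(options(old))

  proj <- make_level(root, "project", "CPB",
                     answers = fixture_answers("project",
                                               "dsRNA insecticide validation"),
                     templates = templates)

  inv_specs <- list(
    list(name = "01_LabTrials", n_studies = 11L),
    list(name = "02_FieldTrials", n_studies = 3L),
    list(name = "03_Bioinformatics", n_studies = 2L)
  )
  for (iv in inv_specs) {
    inv <- make_level(proj$path, "investigation", iv$name,
                      answers = fixture_answers("investigation", iv$name),
                      templates = templates)
    study_names <- sprintf("%02d_Study", seq_len(iv$n_studies))
    samples <- sprintf("%s.S%02d", iv$name, seq_len(iv$n_studies))
    write_phenodata(inv$path, samples, study_names)
    for (si in seq_len(iv$n_studies)) {
      st <- make_level(inv$path, "study", study_names[[si]],
                       answers = fixture_answers("study", study_names[[si]]),
                       templates = templates)
      if (iv$name == "01_LabTrials" && si <= 3L) {
        # dsRNA design and production: dry analysis assays
        as <- make_level(st$path, "assay", "dsRNAdesign",
                         assay_class = "dry", assay_type = "Statistics",
                         answers = fixture_answers(
                           "assay", "dsRNAdesign",
                           list(Protocol = "design pipeline")),
                         templates = templates)
        seed_file(as$path, "output/design_table.txt", seed)
      } else if (iv$name == "01_LabTrials") {
        # feeding trials: RNA isolation wet assays with analyte tables
        as <- make_level(st$path, "assay", paste0("Trial", si - 3L),
                         assay_class = "wet", assay_type = "RNAisol",
                         answers = fixture_answers(
                           "assay", "feeding trial",
                           list(Protocol = "RNA isolation",
                                `Isolation kit` = "RNeasy")),
                         templates = templates)
        seed_file(as$path, "output/raw/quantities.txt", seed)
      } else {
        as <- make_level(st$path, "assay", "Analysis",
                         assay_class = "dry", assay_type = "NGS",
                         answers = fixture_answers(
                           "assay", "analysis",
                           list(Protocol = "standard pipeline")),
                         templates = templates)
        seed_file(as$path, "output/result.txt", seed)
      }
    }
  }
  invisible(load_tree(proj$path))
}

#' Generate the transcriptome-assembly example tree
#'
#' A project with a single investigation `_I_STRT` and four studies —
#' the four consecutive bioinformatics procedures (sequencing
#' acquisition and pre-processing, de novo assembly, cultivar
#' transcriptome generation, pan-transcriptome generation) — holding
#' dry assays only, each with small placeholder files in `input`,
#' `scripts` and `output`.
#'
#' @inheritParams generate_cpb_fixture
#' @return The loaded project `isatree_node`, invisibly.
#' @export
generate_strt_fixture <- function(root, seed = 1L) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  check_empty_target(root, "_p_STRT")
  templates <- load_repository(bundled_templates_path())
  old <- options(isatree.date = as.Date("2020-01-01"))
  on.exit(options(old))

  proj <- make_level(root, "project", "STRT",
                     answers = fixture_answers("project",
                                               "Reference transcriptomes"),
                     templates = templates)
  inv <- make_level(proj$path, "investigation", "STRT",
                    answers = fixture_answers("investigation", "STRT"),
                    templates = templates)
  studies <- c("01_Preprocessing", "02_DeNovoAssembly",
               "03_CultivarTranscriptomes", "04_PanTranscriptome")
  write_phenodata(inv$path, sprintf("STRT.S%02d", seq_along(studies)),
                  studies)
  for (si in seq_along(studies)) {
    st <- make_level(inv$path, "study", studies[[si]],
                     answers = fixture_answers("study", studies[[si]]),
                     templates = templates)
    for (ai in 1:2) {
      as <- make_level(st$path, "assay", sprintf("Step%d", ai),
                       assay_class = "dry", assay_type = "NGS",
                       answers = fixture_answers(
                         "assay", sprintf("step %d", ai),
                         list(Protocol = "assembly pipeline")),
                       templates = templates)
      seed_file(as$path, "input/reads_list.txt", seed)
      seed_file(as$path, "scripts/run.sh", seed)
      seed_file(as$path, "output/contigs_summary.txt", seed)
    }
  }
  invisible(load_tree(proj$path))
}

#' Generate a seeded random tree
#'
#' Builds a fully answered tree whose shape is drawn from `spec`:
#' same seed, same spec, byte-identical tree.  Every mandatory key is
#' answered, so the result is clean under [xcheck_metadata()].
#'
#' @param root Directory in which to create the project.
#' @param spec List with `seed`, `n_investigations`,
#'   `studies_per_investigation` (scalar or vector), `assay_mix`
#'   (data.frame-like list of `class`, `type`, `count` recycled over
#'   studies) and `loose_files_per_level`.
#' @return The loaded project `isatree_node`, invisibly.
#' @export
generate_random_tree <- function(root, spec = list()) {
  spec <- utils::modifyList(
    list(seed = 1L, n_investigations = 2L, studies_per_investigation = 2L,
         assay_mix = list(class = c("wet", "dry"),
                          type = c("RNAisol", "NGS"),
                          count = c(1L, 1L)),
         loose_files_per_level = 1L),
    spec)
  seed <- spec$seed
  set.seed(seed %% .Machine$integer.max)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  name <- sprintf("Rand%04d", seed %% 10000L)
  check_empty_target(root, paste0("_p_", name))
  templates <- load_repository(bundled_templates_path())
  old <- options(isatree.date = as.Date("2020-01-01"))
  on.exit(options(old))

  proj <- make_level(root, "project", name,
                     answers = fixture_answers("project", name),
                     templates = templates)
  n_stud <- rep_len(spec$studies_per_investigation, spec$n_investigations)
  for (ii in seq_len(spec$n_investigations)) {
    iname <- sprintf("%02d_Inv", ii)
    inv <- make_level(proj$path, "investigation", iname,
                      answers = fixture_answers("investigation", iname),
                      templates = templates)
    ns <- n_stud[[ii]]
    if (ns > 0L) {
      write_phenodata(inv$path,
                      sprintf("%s.S%02d", iname, seq_len(ns)),
                      sprintf("%02d_Study", seq_len(ns)))
    }
    for (si in seq_len(ns)) {
      sname <- sprintf("%02d_Study", si)
      st <- make_level(inv$path, "study", sname,
                       answers = fixture_answers("study", sname),
                       templates = templates)
      mix <- spec$assay_mix
      for (mi in seq_along(mix$class)) {
        for (ci in seq_len(mix$count[[mi]])) {
          aname <- sprintf("A%d_%d", mi, ci)
          as <- make_level(st$path, "assay", aname,
                           assay_class = mix$class[[mi]],
                           assay_type = mix$type[[mi]],
                           answers = fixture_answers(
                             "assay", aname, list(Protocol = "protocol")),
                           templates = templates)
          data_dir <- if (mix$class[[mi]] == "wet") "output/raw"
                      else "output"
          for (fi in seq_len(spec$loose_files_per_level)) {
            seed_file(as$path, sprintf("%s/data_%d.txt", data_dir, fi),
                      seed)
          }
        }
      }
      for (fi in seq_len(spec$loose_files_per_level)) {
        seed_file(st$path, sprintf("reports/report_%d.txt", fi), seed)
      }
    }
    for (fi in seq_len(spec$loose_files_per_level)) {
      seed_file(inv$path, sprintf("reports/note_%d.txt", fi), seed)
    }
  }
  invisible(load_tree(proj$path))
}
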