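#' Pipeline orchestration
#'
#' Five stages, each re-runnable on its own from the previous stage's files:
#' `generate` (synthetic population), `query` (case phenotype query over the
#' event layer), `screen` (simulated chart review of queried patients),
#' `match` (control-stream generation, demographic matching and sequential
#' review), `report` (attrition tables). [run_pipeline()] executes all five
#' and writes a JSON run manifest.
#'
#' Each stage derives its own seed from the run seed, so a stage re-run in
#' isolation reproduces the files the full pipeline wrote.
#'
#' @name pipeline
NULL

stage_seed <- function(seed, k) if (is.null(seed)) NULL else (seed + 101L * k) %% .Machine$integer.max

#' @rdname pipeline
#' @param config a [generator_config].
#' @param outdir output directory.
#' @param fixed_margins reproduce the configured disposition margins as exact
#'   counts (deterministic largest-remainder allocation for cases and exact
#'   control-review margins) instead of sampling them.
#' @param seed integer seed for the stage.
#' @return each stage returns a named list of record counts, invisibly.
#' @export
stage_generate <- function(config, outdir, fixed_margins = FALSE, seed = NULL) {
  cfg <- config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  pop <- generate_population(cfg, fixed_margins = fixed_margins)
  write_population(pop, outdir)
  invisible(list(n_patients = nrow(pop$records), n_events = nrow(pop$events)))
}

#' @rdname pipeline
#' @param identified write the patient-id list (identified mode) in addition
#'   to the count (de-identified mode).
#' @export
stage_query <- function(outdir, identified = TRUE) {
  pop <- read_population(outdir)
  ids <- evaluate_query(pop$events, case_query())
  writeLines(as.character(length(ids)), file.path(outdir, "query_count.txt"))
  if (identified) {
    writeLines(ids, file.path(outdir, "potential_cases.txt"))
  }
  invisible(list(n_potential_cases = length(ids)))
}

#' @rdname pipeline
#' @export
stage_screen <- function(outdir, config) {
  pop <- read_population(outdir)
  ids <- readLines(file.path(outdir, "potential_cases.txt"))
  rec <- pop$records[match(ids, pop$records$patient_id), , drop = FALSE]
  labels <- assess_case(rec, criteria_from_config(config))
  disp <- tibble::tibble(patient_id = ids, role = "case", label = labels,
                         matched_case_id = NA_character_)
  readr::write_tsv(disp, file.path(outdir, "dispositions.tsv"), na = "",
                   progress = FALSE)
  invisible(list(n_screened = nrow(disp),
                 n_included = sum(labels == "INCLUDED")))
}

# exact control-stream margins for fixed-margins runs: distributes the
# configured ineligible-review totals over the cases that undergo review
# (intended NO_CONTROL cases get an empty stream), interleaving the exclusion
# labels evenly, and shorts the last `n_short_cases` pools to a single
# eligible candidate
fixed_control_plan <- function(case_ids, forced_empty, config) {
  reviewing <- setdiff(case_ids, forced_empty)
  n_rev <- length(reviewing)
  plan <- stats::setNames(rep(list(character(0)), length(case_ids)), case_ids)
  if (n_rev == 0L) return(plan)
  n_inelig <- config$fixed_control_margins$n_ineligible[control_exclusion_order()]
  n_inelig <- n_inelig[!is.na(n_inelig)]
  total <- sum(n_inelig)
  per_case <- allocate_counts(rep(1 / n_rev, n_rev), total)
  # evenly interleaved global label sequence, then chunked per case
  lab <- rep(names(n_inelig), n_inelig)
  pos <- unlist(lapply(n_inelig, function(m) if (m > 0) (seq_len(m) - 0.5) / m else numeric(0)))
  lab <- lab[order(pos)]
  n_short <- min(config$fixed_control_margins$n_short_cases, n_rev)
  n_elig <- rep(config$match_ratio, n_rev)
  if (n_short > 0L) n_elig[seq.int(n_rev - n_short + 1L, n_rev)] <- 1L
  offset <- c(0L, cumsum(per_case))
  for (i in seq_len(n_rev)) {
    chunk <- if (per_case[i] > 0L) lab[seq.int(offset[i] + 1L, offset[i + 1L])] else character(0)
    plan[[reviewing[i]]] <- c(chunk, rep("ELIGIBLE", n_elig[i]))
  }
  plan
}

#' @rdname pipeline
#' @export
stage_match <- function(outdir, config, fixed_margins = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- read_population(outdir)
  disp <- readr::read_tsv(file.path(outdir, "dispositions.tsv"), na = "",
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  included <- sort(disp$patient_id[disp$label == "INCLUDED"])
  cases <- pop$records[match(included, pop$records$patient_id), , drop = FALSE]
  forced_empty <- character(0)
  if (!is.null(pop$intended)) {
    forced_empty <- pop$intended$patient_id[pop$intended$intended_label == "NO_CONTROL"]
  }
  plan <- if (fixed_margins) {
    fixed_control_plan(included, forced_empty, config)
  } else {
    NULL
  }

  store <- new.env(parent = emptyenv())
  store$streams <- list()
  source_fn <- function(case) {
    id <- as.character(case$patient_id)
    stream <- if (id %in% forced_empty) {
      generate_control_stream(case, config, n = 0L)
    } else if (!is.null(plan)) {
      generate_control_stream(case, config, intended = plan[[id]])
    } else {
      generate_control_stream(case, config)
    }
    store$streams[[id]] <- stream
    stream$records
  }
  spec <- match_spec(match_ratio = config$match_ratio,
                     dob_tolerance_days = config$dob_tolerance_days)
  mm <- run_matching(cases, source_fn, criteria_from_config(config), spec,
                     shuffle = !fixed_margins)

  # persist the generated control layer (schema kept even with no streams)
  streams <- store$streams
  if (length(streams) > 0L) streams <- streams[order(names(streams))]
  empty <- realize_cases(character(0), config)
  empty$intended <- tibble::tibble(patient_id = character(0),
                                   intended_label = character(0),
                                   case_id = character(0))
  ctrl_pop <- list(
    records = dplyr::bind_rows(c(list(empty$records),
                                 lapply(streams, `[[`, "records"))),
    events = dplyr::bind_rows(c(list(empty$events),
                                lapply(streams, `[[`, "events"))),
    intended = dplyr::bind_rows(c(list(empty$intended),
                                  lapply(streams, `[[`, "intended"))))
  write_population(ctrl_pop, outdir, prefix = "controls_")

  readr::write_tsv(mm$matches, file.path(outdir, "matches.tsv"), na = "",
                   progress = FALSE)
  stats_tab <- tibble::tibble(case_id = mm$results$case_id,
                              n_reviewed_ineligible = mm$results$n_reviewed_ineligible,
                              n_matched = mm$results$n_matched,
                              exhausted = mm$results$exhausted)
  readr::write_tsv(stats_tab, file.path(outdir, "review_stats.tsv"), na = "",
                   progress = FALSE)

  # relabel unmatched cases and append control dispositions
  unmatched <- mm$results$case_id[mm$results$n_matched == 0L]
  disp$label[disp$patient_id %in% unmatched] <- "NO_CONTROL"
  ctrl_disp <- tibble::tibble(patient_id = mm$reviewed$patient_id,
                              role = "control", label = mm$reviewed$label,
                              matched_case_id = mm$reviewed$case_id)
  readr::write_tsv(dplyr::bind_rows(disp, ctrl_disp),
                   file.path(outdir, "dispositions.tsv"), na = "",
                   progress = FALSE)
  matched <- mm$results$n_matched > 0L
  invisible(list(n_cases_matched = sum(matched),
                 n_controls = nrow(mm$matches),
                 n_reviewed = nrow(mm$reviewed),
                 mean_reviews = if (any(matched)) {
                   round(mean(stats_tab$n_reviewed_ineligible[matched]), 2)
                 } else NA_real_))
}

#' @rdname pipeline
#' @export
stage_report <- function(outdir) {
  disp <- readr::read_tsv(file.path(outdir, "dispositions.tsv"), na = "",
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  tabs <- list(case = tabulate_flow(disp[disp$role == "case", ], "case"),
               control = tabulate_flow(disp[disp$role == "control", ], "control"))
  write_flow_table(tabs$case, file.path(outdir, "flow_cases.tsv"))
  write_flow_table(tabs$control, file.path(outdir, "flow_controls.tsv"))
  writeLines(render_flow(tabs), file.path(outdir, "report.txt"))
  invisible(list(n_cases = tabs$case$n_included,
                 n_controls = tabs$control$n_included))
}

#' Run the full cohort-assembly pipeline
#'
#' Executes generate, query, screen, match and report in order, writing every
#' intermediate TSV plus a JSON run manifest (config snapshot, seed,
#' timestamps, per-stage outputs and record counts) to `outdir`. All
#' randomness flows from `seed` (or `config$seed`), so identical seed and
#' config give byte-identical data files; the manifest alone carries
#' wall-clock timestamps.
#'
#' @param config a [generator_config], or a path to a YAML config file.
#' @param outdir output directory.
#' @param seed integer run seed; overrides `config$seed` when given.
#' @param fixed_margins allocate every disposition margin as exact counts
#'   (cases via largest remainder, control streams via the configured exact
#'   margins) so the configured attrition arithmetic is reproduced
#'   deterministically.
#' @return the run manifest, invisibly.
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "cohortflow-demo")
#' man <- run_pipeline(generator_config(), out, seed = 1, fixed_margins = TRUE)
#' man$stages$report
#' }
#' @export
run_pipeline <- function(config = generator_config(), outdir,
                         seed = NULL, fixed_margins = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) seed <- config$seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  stages <- list()
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] %s", name,
                    paste(names(res), unlist(res), sep = "=", collapse = " ")))
    stages[[name]] <<- res
    res
  }
  run_stage("generate", function()
    stage_generate(config, outdir, fixed_margins, seed = stage_seed(seed, 1L)))
  run_stage("query", function() stage_query(outdir, identified = TRUE))
  run_stage("screen", function() stage_screen(outdir, config))
  run_stage("match", function()
    stage_match(outdir, config, fixed_margins, seed = stage_seed(seed, 2L)))
  run_stage("report", function() stage_report(outdir))

  manifest <- list(
    tool = "cohortflow",
    version = as.character(utils::packageVersion("cohortflow")),
    seed = seed,
    fixed_margins = fixed_margins,
    started = t0,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_snapshot(config),
    outdir = outdir,
    files = list.files(outdir, pattern = "\\.(tsv|txt)$"),
    stages = stages)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$study_period <- format(snap$study_period)
  snap$horizon <- format(snap$horizon)
  snap
}
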