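#' Write and read a synthetic population as delimited text
#'
#' Serializes the three layers as TSV with header rows and ISO-8601 dates:
#' `demographics.tsv` (`patient_id`, `dob`, `sex`), `events.tsv`
#' (`patient_id`, `code_system`, `code`, `date`) and `truth.tsv` (the latent
#' clinical fields, with `feed_months` as comma-separated `YYYY-MM` tokens
#' and absent dates as empty fields). `intended.tsv` records the generator's
#' intended disposition per patient when available. Identical populations
#' produce byte-identical files.
#'
#' @param pop list with `records`, `events` and optionally `intended`, as
#'   returned by [generate_population()].
#' @param dir output directory (created if needed).
#' @param prefix optional file-name prefix (e.g. `"controls_"`).
#' @return invisibly, the vector of files written.
#' @export
write_population <- function(pop, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(dir, paste0(prefix, name))
  rec <- pop$records
  demo <- tibble::tibble(patient_id = rec$patient_id, dob = rec$dob,
                         sex = rec$sex)
  truth <- tibble::tibble(
    patient_id = rec$patient_id,
    has_true_stone = rec$has_true_stone,
    stone_dx_date = rec$stone_dx_date,
    has_true_gtube = rec$has_true_gtube,
    gtube_placement_date = rec$gtube_placement_date,
    feed_months = vapply(rec$feed_months, paste, "", collapse = ","),
    nutrition_data_adequate = rec$nutrition_data_adequate)
  readr::write_tsv(demo, f("demographics.tsv"), na = "", progress = FALSE)
  readr::write_tsv(pop$events, f("events.tsv"), na = "", progress = FALSE)
  readr::write_tsv(truth, f("truth.tsv"), na = "", progress = FALSE)
  files <- c(f("demographics.tsv"), f("events.tsv"), f("truth.tsv"))
  if (!is.null(pop$intended)) {
    readr::write_tsv(pop$intended, f("intended.tsv"), na = "", progress = FALSE)
    files <- c(files, f("intended.tsv"))
  }
  invisible(files)
}

#' @rdname write_population
#' @export
read_population <- function(dir, prefix = "") {
  f <- function(name) file.path(dir, paste0(prefix, name))
  demo <- readr::read_tsv(f("demographics.tsv"), na = "",
                          col_types = readr::cols(
                            patient_id = "c", dob = "D", sex = "c"),
                          progress = FALSE)
  truth <- readr::read_tsv(f("truth.tsv"), na = "",
                           col_types = readr::cols(
                             patient_id = "c", has_true_stone = "l",
                             stone_dx_date = "D", has_true_gtube = "l",
                             gtube_placement_date = "D", feed_months = "c",
                             nutrition_data_adequate = "l"),
                           progress = FALSE)
  events <- readr::read_tsv(f("events.tsv"), na = "",
                            col_types = readr::cols(
                              patient_id = "c", code_system = "c",
                              code = "c", date = "D"),
                            progress = FALSE)
  records <- dplyr::left_join(demo, truth, by = "patient_id")
  fm <- records$feed_months
  fm[is.na(fm)] <- ""
  records$feed_months <- lapply(fm, parse_feed_field)
  out <- list(records = tibble::as_tibble(records), events = events)
  if (file.exists(f("intended.tsv"))) {
    out$intended <- readr::read_tsv(f("intended.tsv"), na = "",
                                    col_types = readr::cols(.default = "c"),
                                    progress = FALSE)
  }
  out
}
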