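#' Write a synthetic survey to plain-text fixture files
#'
#' Writes `households.csv` and `individuals.csv` (UTF-8, header row, "."
#' decimal, full double precision) and the ground truth — latent wealth,
#' per-indicator parameters and a config echo — to a `truth.json` sidecar,
#' never into the microdata tables themselves.  Output is byte-identical for
#' identical surveys.
#'
#' @param survey a [generate_survey()] result.
#' @param path directory to write into (created if missing).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(survey, path) {
  stopifnot(inherits(survey, "synthetic_survey"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    households = file.path(path, "households.csv"),
    individuals = file.path(path, "individuals.csv"),
    truth = file.path(path, "truth.json")
  )
  write_csv_precise(survey$households, paths[["households"]])
  write_csv_precise(survey$individuals, paths[["individuals"]])
  truth <- survey$truth
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

write_csv_precise <- function(df, file) {
  out <- df
  for (nm in names(out)) out[[nm]] <- .fmt_num(out[[nm]])
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Read a synthetic-survey fixture back from disk
#'
#' Reads the tables written by [write_fixture()] and rebuilds the
#' `synthetic_survey` object, validating referential integrity: every
#' individual must reference a household present in the household table, and
#' a violation is reported with its row number.
#'
#' @param path directory holding `households.csv`, `individuals.csv` and
#'   optionally `truth.json`.
#' @return object of class `synthetic_survey` (with `truth = NULL` if no
#'   sidecar is present).
#' @export
read_fixture <- function(path) {
  hh_file <- file.path(path, "households.csv")
  ind_file <- file.path(path, "individuals.csv")
  if (!file.exists(hh_file)) stop(sprintf("missing file: %s", hh_file))
  if (!file.exists(ind_file)) stop(sprintf("missing file: %s", ind_file))
  households <- utils::read.csv(hh_file, stringsAsFactors = FALSE)
  individuals <- utils::read.csv(ind_file, stringsAsFactors = FALSE)
  need_h <- c("household_id", "weight", "stratum", "residence")
  if (!all(need_h %in% names(households))) {
    stop(sprintf("parse error in %s: missing column(s) %s", hh_file,
                 paste(setdiff(need_h, names(households)), collapse = ", ")))
  }
  need_i <- c("unit_id", "household_id", "weight", "residence", "education")
  if (!all(need_i %in% names(individuals))) {
    stop(sprintf("parse error in %s: missing column(s) %s", ind_file,
                 paste(setdiff(need_i, names(individuals)), collapse = ", ")))
  }
  orphan <- which(!individuals$household_id %in% households$household_id)
  if (length(orphan)) {
    stop(sprintf("parse error in %s: row %d references unknown household_id %s",
                 ind_file, orphan[1L], individuals$household_id[orphan[1L]]))
  }
  truth <- NULL
  truth_file <- file.path(path, "truth.json")
  if (file.exists(truth_file)) {
    truth <- jsonlite::read_json(truth_file, simplifyVector = TRUE)
  }
  structure(list(households = households, individuals = individuals,
                 truth = truth),
            class = "synthetic_survey")
}
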