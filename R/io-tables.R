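# Cohort demographics table and result-table writers.

SEX_LEVELS <- c("male", "female")
BREED_LEVELS <- c("smooth", "long", "wire")
COHORT_COLUMNS <- c("dog_id", "sex", "breed_type", "age", "weight",
                    "height_withers", "body_length", "bcs")

#' Read / write the cohort demographics table
#'
#' One row per dog: identifier, sex (`male`/`female`), breed type
#' (`smooth`/`long`/`wire` haired), age (years), weight (kg), height at the
#' withers (cm), body length (cm) and body condition score (BCS, 1--5).
#' Reading validates categorical tokens, the study inclusion rule (age above
#' 6 months) and the BCS scale, and derives the length-to-height ratio.
#'
#' @param path File path.
#' @param records A data frame with the cohort columns.
#' @return `read_cohort_table()` returns a tibble (possibly empty, with a
#'   warning, for an empty file).
#' @export
read_cohort_table <- function(path) {
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(out) == 0) {
    warning(sprintf("cohort table %s is empty", basename(path)), call. = FALSE)
    return(tibble::tibble(dog_id = character(), sex = character(),
                          breed_type = character(), age = numeric(),
                          weight = numeric(), height_withers = numeric(),
                          body_length = numeric(), bcs = numeric(),
                          length_height_ratio = numeric()))
  }
  missing <- setdiff(COHORT_COLUMNS, names(out))
  if (length(missing) > 0) {
    stop(sprintf("cohort table %s: missing column(s) %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad_sex <- setdiff(unique(out$sex), SEX_LEVELS)
  if (length(bad_sex) > 0) {
    stop(sprintf("cohort table %s: unknown sex token '%s'", basename(path),
                 bad_sex[1]), call. = FALSE)
  }
  bad_breed <- setdiff(unique(out$breed_type), BREED_LEVELS)
  if (length(bad_breed) > 0) {
    stop(sprintf("cohort table %s: unknown breed type '%s'", basename(path),
                 bad_breed[1]), call. = FALSE)
  }
  if (any(out$age <= 0.5)) {
    stop(sprintf("cohort table %s: dog %s violates the inclusion rule (age above 6 months)",
                 basename(path), out$dog_id[which(out$age <= 0.5)[1]]), call. = FALSE)
  }
  if (any(out$bcs < 1 | out$bcs > 5)) {
    stop(sprintf("cohort table %s: BCS outside the 1-5 scale for dog %s",
                 basename(path), out$dog_id[which(out$bcs < 1 | out$bcs > 5)[1]]),
         call. = FALSE)
  }
  dplyr::mutate(out,
                length_height_ratio = .data$body_length / .data$height_withers)
}

#' @rdname read_cohort_table
#' @param meta Named list of `# key: value` metadata lines.
#' @export
write_cohort_table <- function(records, path, meta = list()) {
  stopifnot(all(COHORT_COLUMNS %in% names(records)))
  write_results_table(dplyr::select(records, dplyr::all_of(COHORT_COLUMNS)),
                      path, meta = meta)
}

#' Write a results table with provenance metadata
#'
#' Writes any tibble as CSV preceded by `# key: value` header lines (seed,
#' thresholds, n), so every reported number is traceable to the run that
#' produced it. Files written this way are readable with
#' `readr::read_csv(..., comment = "#")`.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param meta Named list of metadata values.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(x, path, meta = list()) {
  hdr <- c(sprintf("# pawsway results table v1 (%s)", basename(path)),
           vapply(names(meta), function(k) sprintf("# %s: %s", k, format(meta[[k]])),
                  character(1)))
  writeLines(hdr, path)
  readr::write_csv(dplyr::as_tibble(x), path, append = TRUE, col_names = TRUE)
  invisible(path)
}
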