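# Cohort metadata: per-patient clinical records and their summary counts.

#' Path to the bundled cohort metadata table
#'
#' Per-patient metadata for a 33-child absence-epilepsy cohort (age, sex,
#' seizure count, whether seizures occurred spontaneously or under
#' hyperventilation, and the clinician-annotated seizure-origin region).
#'
#' @return File path of the bundled CSV.
#' @export
cohort_fixture_path <- function() {
  system.file("extdata", "cae_cohort.csv", package = "swdeeg",
              mustWork = TRUE)
}

#' Parse a cohort metadata table
#'
#' Reads a CSV with columns `patient_id`, `age_years`, `sex`,
#' `n_seizures`, `induction`, `origin_text`. Induction labels are
#' normalized case-insensitively to `spontaneous` / `hyperventilation`.
#' A trailing `Total` row, if present, is dropped.
#'
#' @param path CSV path, default the bundled table.
#' @return Tibble of patient records.
#' @examples
#' cohort <- parse_cohort()
#' nrow(cohort)  # 33
#' @export
parse_cohort <- function(path = cohort_fixture_path()) {
  tbl <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  need <- c("patient_id", "age_years", "sex", "n_seizures", "induction",
            "origin_text")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop("parse error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tbl <- tbl[tolower(trimws(as.character(tbl$patient_id))) != "total", ,
             drop = FALSE]
  if (nrow(tbl) == 0) stop("parse error: no patient rows", call. = FALSE)
  age <- suppressWarnings(as.numeric(tbl$age_years))
  if (any(is.na(age))) {
    stop("parse error: unparseable age in row ", which(is.na(age))[1],
         call. = FALSE)
  }
  ind <- tolower(trimws(tbl$induction))
  bad <- which(!ind %in% c("spontaneous", "hyperventilation"))
  if (length(bad) > 0) {
    stop("parse error: unknown induction label in row ", bad[1],
         call. = FALSE)
  }
  sex <- tolower(trimws(tbl$sex))
  badsex <- which(!sex %in% c("female", "male"))
  if (length(badsex) > 0) {
    stop("parse error: unknown sex label in row ", badsex[1], call. = FALSE)
  }
  tibble::tibble(
    patient_id = as.integer(tbl$patient_id),
    age_years = age,
    sex = sex,
    n_seizures = as.integer(tbl$n_seizures),
    induction = ind,
    origin_text = as.character(tbl$origin_text)
  )
}

#' Classify a seizure-origin annotation as frontal-related
#'
#' True when the free-text region mentions a frontal-related structure
#' (frontal, prefrontal, parafrontal, lateral/right/left frontal ...),
#' matched case-insensitively; `"Not found"` and non-frontal regions are
#' false. The keyword list is configurable.
#'
#' @param origin_text Character vector of origin annotations.
#' @param keywords Regular expressions counted as frontal-related;
#'   default `c("frontal")` (which also matches prefrontal, parafrontal).
#' @return Logical vector.
#' @examples
#' classify_frontal_origin(c("Right frontal region", "Occipital region"))
#' @export
classify_frontal_origin <- function(origin_text, keywords = c("frontal")) {
  pat <- paste(keywords, collapse = "|")
  grepl(pat, origin_text, ignore.case = TRUE)
}

#' Summarize a cohort
#'
#' Totals and demographics: patient and seizure counts, seizure counts by
#' induction mode, age mean and SD, and the number and fraction of
#' patients whose seizures originate from frontal-related regions.
#'
#' @param records Patient tibble from [parse_cohort()].
#' @param sd_mode `"sample"` (n-1 denominator, default) or `"population"`;
#'   the convention used is echoed in the output.
#' @param frontal_keywords Passed to [classify_frontal_origin()].
#' @return One-row tibble: `n_patients`, `mean_age`, `sd_age`, `sd_mode`,
#'   `n_female`, `n_male`, `total_seizures`, `n_spontaneous_seizures`,
#'   `n_hyperventilation_seizures`, `n_spontaneous_patients`,
#'   `n_frontal_origin_patients`, `frontal_fraction`.
#' @examples
#' summarize_cohort(parse_cohort())
#' @export
summarize_cohort <- function(records, sd_mode = c("sample", "population"),
                             frontal_keywords = c("frontal")) {
  sd_mode <- match.arg(sd_mode)
  if (nrow(records) < 1) stop("need at least one record", call. = FALSE)
  age <- records$age_years
  sd_age <- if (sd_mode == "sample") {
    if (length(age) > 1) stats::sd(age) else NA_real_
  } else {
    sqrt(mean((age - mean(age))^2))
  }
  frontal <- classify_frontal_origin(records$origin_text, frontal_keywords)
  spont <- records$induction == "spontaneous"
  tibble::tibble(
    n_patients = nrow(records),
    mean_age = mean(age),
    sd_age = sd_age,
    sd_mode = sd_mode,
    n_female = sum(records$sex == "female"),
    n_male = sum(records$sex == "male"),
    total_seizures = sum(records$n_seizures),
    n_spontaneous_seizures = sum(records$n_seizures[spont]),
    n_hyperventilation_seizures = sum(records$n_seizures[!spont]),
    n_spontaneous_patients = sum(spont),
    n_frontal_origin_patients = sum(frontal),
    frontal_fraction = sum(frontal) / nrow(records)
  )
}
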