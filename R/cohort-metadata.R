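#' Summarize a clinical sample sheet
#'
#' Counts tumors and controls, tumor sex and invasiveness, and the mean tumor
#' age in months (over tumors with a known age, unrounded). Samples with
#' unknown sex are excluded from the sex counts; the published cohort's
#' controls carry unknown sex, so the counts describe tumors only.
#'
#' @param samples a \code{DataFrame}/data.frame as returned by
#'   [readSampleSheet()]: columns \code{group}, \code{sex},
#'   \code{invasiveness}, \code{age_months}.
#' @return one-row \code{DataFrame}: n_tumors, n_controls, n_male, n_female,
#'   n_invasive, n_noninvasive, mean_age_months.
#' @examples
#' sheet <- system.file("extdata", "table1_samples.tsv", package = "lncscope")
#' summarizeCohort(readSampleSheet(sheet))
#' @export
summarizeCohort <- function(samples) {
    samples <- as.data.frame(samples)
    if (!nrow(samples))
        stop("empty sample collection")
    need <- c("group", "sex", "invasiveness", "age_months")
    miss <- setdiff(need, names(samples))
    if (length(miss))
        stop("sample sheet is missing column(s): ",
             paste(miss, collapse = ", "))
    tum <- samples[samples$group == "tumor", , drop = FALSE]
    if (!nrow(tum))
        stop("no tumor samples in the cohort")
    ages <- tum$age_months[!is.na(tum$age_months)]
    DataFrame(n_tumors = nrow(tum),
              n_controls = sum(samples$group == "control"),
              n_male = sum(tum$sex == "male"),
              n_female = sum(tum$sex == "female"),
              n_invasive = sum(tum$invasiveness == "invasive"),
              n_noninvasive = sum(tum$invasiveness == "non-invasive"),
              mean_age_months = if (length(ages)) mean(ages) else NA_real_)
}

#' Format an age in months as "Y years M months"
#'
#' @param months numeric age in months.
#' @return character, e.g. \code{formatAgeMonths(32)} is
#'   \code{"2 years 8 months"}.
#' @export
formatAgeMonths <- function(months) {
    y <- months %/% 12
    m <- round(months %% 12)
    paste0(y, " years ", m, " months")
}
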