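# Mapping from deprivation-direction binary items to the raw survey-style
# columns they are derived from. Used to emit a realistic raw cohort table
# and, inversely, by the default dichotomization rules.
raw_item_map <- function() {
  yn <- function(item, col) list(item = item, column = col, type = "levels",
                                 deprived = "Yes", other = "No")
  list(
    list(item = "education", column = "education", type = "levels",
         deprived = "High school diploma or less",
         other = "More than high school"),
    list(item = "vulnerable_housing", column = "housing", type = "levels",
         deprived = "Vulnerably housed", other = "Housed"),
    list(item = "living_alone", column = "living", type = "levels",
         deprived = "Alone", other = "Not alone"),
    list(item = "low_income", column = "income_cad", type = "threshold_lt",
         threshold = 1500),
    list(item = "not_married", column = "marital", type = "levels",
         deprived = "Not married", other = "Married"),
    list(item = "unemployed", column = "employment", type = "levels",
         deprived = "Unemployed", other = "Employed"),
    list(item = "non_gbmsm", column = "sexual_identity", type = "levels",
         deprived = "Heterosexual", other = "Gay or bisexual"),
    yn("indigenous", "indigenous"),
    yn("incarceration", "incarceration"),
    yn("idu_ever", "idu_ever"),
    yn("idu_6mo", "idu_6mo"),
    yn("snort_6mo", "snort_6mo"),
    yn("sex_client_ever", "sex_client_ever"),
    yn("sex_work_ever", "sex_work_ever"),
    yn("sex_work_6mo", "sex_work_6mo"),
    yn("depression", "depression"),
    yn("psych_hosp", "psych_hosp"),
    yn("schizophrenia", "schizophrenia"),
    yn("sti_6mo", "sti_6mo")
  )
}

#' Simulate a cohort in raw (pre-dichotomization) form
#'
#' Generates the binary cohort from `config` and re-expresses each item as
#' the raw survey column it would have been collected as (category labels,
#' or a monthly income amount for the income item), with missing cells left
#' empty. The result is the kind of table [dichotomize()] consumes.
#'
#' @param config a [cohort_config()]; item labels must be among the 19
#'   candidate indicators.
#' @return list with `data` (raw data.frame incl. outcome) and `truth`.
#' @export
simulate_raw_cohort <- function(config) {
  sim <- simulate_cohort(config)
  dat <- sim$data
  set.seed(child_seed(config$seed, "rawvalues"))
  out <- data.frame(id = dat$id, province = dat$province,
                    stringsAsFactors = FALSE)
  for (m in raw_item_map()) {
    if (!m$item %in% names(dat)) next
    x <- dat[[m$item]]
    if (m$type == "threshold_lt") {
      lo <- sample(seq(300, 1450, by = 50), length(x), replace = TRUE)
      hi <- sample(seq(1500, 8000, by = 100), length(x), replace = TRUE)
      out[[m$column]] <- ifelse(is.na(x), NA, ifelse(x == 1, lo, hi))
    } else {
      out[[m$column]] <- ifelse(is.na(x), NA_character_,
                                ifelse(x == 1, m$deprived, m$other))
    }
  }
  out$outcome <- dat$outcome
  list(data = out, truth = sim$truth)
}
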