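#' MET intensity assignment for the five activity categories
#'
#' The activity questionnaire records daily minutes in five intensity
#' categories; each category carries an average MET intensity (multiples of
#' resting metabolic rate). Values must be positive and non-decreasing from
#' `stable` to `high`. Defaults follow compendium convention; they are a
#' configuration input, not part of any result.
#'
#' @param stable,sitting,low,medium,high MET intensity per category.
#' @return named numeric vector of class `met_assignment`.
#' @export
met_assignment <- function(stable = 1.0, sitting = 1.5, low = 3.0,
                           medium = 5.0, high = 7.0) {
  met <- c(stable = stable, sitting = sitting, low = low,
           medium = medium, high = high)
  validate_met(structure(met, class = "met_assignment"))
}

validate_met <- function(met) {
  cats <- c("stable", "sitting", "low", "medium", "high")
  if (!all(cats %in% names(met)))
    stopf("MET assignment must name all five categories: %s",
          paste(cats, collapse = ", "))
  met <- met[cats]
  if (any(met <= 0)) stopf("MET intensities must be > 0")
  if (is.unsorted(met)) stopf("MET intensities must be non-decreasing from stable to high")
  structure(met, class = "met_assignment")
}

#' Total daily physical activity in MET·min/day
#'
#' For each sample, `pa = sum over categories of MET_c * minutes_c`. Totals
#' exceeding 1440 min/day of recorded time are flagged with a warning but
#' kept (implausible totals are surfaced, never silently dropped).
#'
#' @param activity data frame with `sample_id` and one duration column
#'   (min/day) per MET category.
#' @param met a [met_assignment()].
#' @param on_missing `"error"` (default) to fail on any missing duration,
#'   `"drop"` to drop incomplete samples with a message.
#' @return data frame `sample_id`, `pa`.
#' @export
compute_total_pa <- function(activity, met = met_assignment(),
                             on_missing = c("error", "drop")) {
  met <- validate_met(met)
  on_missing <- match.arg(on_missing)
  cats <- names(met)
  miss <- setdiff(cats, names(activity))
  if (length(miss))
    stopf("activity table lacks duration column(s): %s", paste(miss, collapse = ", "))
  dur <- as.matrix(activity[, cats])
  storage.mode(dur) <- "double"
  incomplete <- rowSums(is.na(dur)) > 0
  if (any(incomplete)) {
    if (on_missing == "error")
      stopf("missing duration(s) for sample(s): %s",
            paste(utils::head(activity$sample_id[incomplete], 5), collapse = ", "))
    message(sprintf("dropping %d sample(s) with missing durations", sum(incomplete)))
    activity <- activity[!incomplete, , drop = FALSE]
    dur <- dur[!incomplete, , drop = FALSE]
  }
  neg <- rowSums(dur < 0) > 0
  if (any(neg))
    stopf("negative duration(s) for sample(s): %s",
          paste(utils::head(activity$sample_id[neg], 5), collapse = ", "))
  over <- rowSums(dur) > 1440
  if (any(over))
    warnf("%d sample(s) report more than 1440 min/day of activity", sum(over))
  data.frame(sample_id = activity$sample_id,
             pa = drop(dur %*% unclass(met)),
             stringsAsFactors = FALSE)
}

#' Cohort summary of the PA phenotype
#'
#' Per-group sample size, mean, SD (sample SD, n-1 denominator), median and
#' IQR of PA; supports sex/area/age-band style summaries.
#'
#' @param pheno data frame with a `pa` column.
#' @param group_by optional name of a grouping column in `pheno`; `NULL`
#'   summarises the whole cohort as one group.
#' @return data frame with columns `group`, `n`, `mean`, `sd`, `median`,
#'   `iqr`. Groups with fewer than two samples report `sd = NA`; empty
#'   groups (empty factor levels) report `n = 0` and all-NA statistics.
#' @export
summarize_cohort <- function(pheno, group_by = NULL) {
  if (!"pa" %in% names(pheno)) stopf("`pheno` lacks a `pa` column")
  g <- if (is.null(group_by)) {
    factor(rep("all", nrow(pheno)))
  } else {
    if (!group_by %in% names(pheno)) stopf("no column `%s` in `pheno`", group_by)
    col <- pheno[[group_by]]
    if (is.factor(col)) col else factor(col)   # keep declared (possibly empty) levels
  }
  rows <- lapply(levels(g), function(lv) {
    x <- pheno$pa[g == lv]
    if (!length(x))
      return(data.frame(group = lv, n = 0L, mean = NA_real_, sd = NA_real_,
                        median = NA_real_, iqr = NA_real_))
    data.frame(group = lv, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               median = stats::median(x),
               iqr = stats::IQR(x))
  })
  do.call(rbind, rows)
}

#' Age bands for cohort summaries
#'
#' Cuts age into the conventional bands 40-44, 45-49, 50-54, 55-59, 60-64,
#' 65+ (configurable lower breaks).
#'
#' @param age numeric vector of ages in years.
#' @param breaks increasing lower bounds of the bands.
#' @return factor of band labels.
#' @export
age_band <- function(age, breaks = c(40, 45, 50, 55, 60, 65)) {
  labs <- c(paste(breaks[-length(breaks)], breaks[-1] - 1, sep = "-"),
            paste0(breaks[length(breaks)], "+"))
  cut(age, c(breaks, Inf), labels = labs, right = FALSE)
}
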