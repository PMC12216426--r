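#' KDIGO staging cutoffs
#'
#' Single editable constant encoding the staging table used by
#' [kdigo_ordinal()]. Stage 1 follows the creatinine-ratio band 1.5-1.9
#' (read as \[1.5, 2.0) so it abuts the stage-2 lower bound) or more than 6
#' but fewer than 12 hours of urine output below 0.5 ml/kg/h within the
#' 48-hour postoperative window; stages 2 and 3 encode ratio bands
#' \[2.0, 3.0) and >= 3.0, >= 12 hours below 0.5 ml/kg/h, and >= 24 hours
#' below 0.3 ml/kg/h respectively. Anuria-based stage 3 is intentionally not
#' encoded.
#'
#' @format A list with components `ratio` (stage lower bounds), `hours05`
#'   (stage-1 open interval and stage-2 threshold) and `hours03`
#'   (stage-3 threshold).
#' @export
kdigo_cutoffs <- list(
  ratio   = c(stage1 = 1.5, stage2 = 2.0, stage3 = 3.0),
  hours05 = c(stage1_over = 6, stage1_under = 12, stage2_min = 12),
  hours03 = c(stage3_min = 24)
)

#' Postoperative-to-baseline serum creatinine ratio
#'
#' @param postop Postoperative serum creatinine concentration (> 0 expected,
#'   any positive value accepted).
#' @param baseline Baseline (preoperative) concentration; must be > 0.
#' @return `postop / baseline`. Vectorized.
#' @export
creatinine_ratio <- function(postop, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline creatinine must be positive", call. = FALSE)
  postop / baseline
}

#' Hours of low urine output in the 48-hour postoperative window
#'
#' Counts the hours whose urine output (ml per kg body mass per hour) falls
#' strictly below the threshold.
#'
#' @param series Numeric vector of 48 hourly urine-output values, ml/kg/h,
#'   non-negative.
#' @param threshold Threshold in ml/kg/h (0.5 and 0.3 are the KDIGO values).
#' @return Integer count of hours in \[0, 48\].
#' @export
urine_low_hours <- function(series, threshold) {
  if (length(series) != 48L)
    stop("urine series must cover 48 hourly values, got ", length(series),
         call. = FALSE)
  if (any(!is.finite(series)) || any(series < 0))
    stop("urine series must be non-negative and finite", call. = FALSE)
  sum(series < threshold)
}

.kdigo_stage_one <- function(ratio, hours05, hours03) {
  co <- kdigo_cutoffs
  cr_stage <- if (ratio >= co$ratio[["stage3"]]) 3L
  else if (ratio >= co$ratio[["stage2"]]) 2L
  else if (ratio >= co$ratio[["stage1"]]) 1L
  else 0L
  ur_stage <- if (hours03 >= co$hours03[["stage3_min"]]) 3L
  else if (hours05 >= co$hours05[["stage2_min"]]) 2L
  else if (hours05 > co$hours05[["stage1_over"]] &&
           hours05 < co$hours05[["stage1_under"]]) 1L
  else 0L
  max(cr_stage, ur_stage)
}

#' KDIGO ordinal acute kidney injury stage (0-3)
#'
#' The stage is the maximum of the creatinine-based and urine-output-based
#' stages under [kdigo_cutoffs]. For instance, stage 1 is assigned when the
#' postoperative-to-preoperative creatinine ratio lies between 1.5 and 1.9 or
#' the time with urine output below 0.5 ml/kg/h exceeds 6 but is under 12
#' hours.
#'
#' @param ratio Creatinine ratio (positive real). Vectorized.
#' @param hours05 Hours with urine output below 0.5 ml/kg/h, in \[0, 48\].
#' @param hours03 Hours with urine output below 0.3 ml/kg/h, in \[0, 48\];
#'   cannot exceed `hours05`.
#' @return Integer stage(s) in 0-3.
#' @examples
#' kdigo_ordinal(1.7, 8, 0)   # stage 1
#' kdigo_ordinal(3.2, 30, 25) # stage 3
#' @export
kdigo_ordinal <- function(ratio, hours05, hours03) {
  stopifnot(length(ratio) == length(hours05),
            length(ratio) == length(hours03))
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("creatinine ratio must be positive", call. = FALSE)
  if (any(hours05 < 0 | hours05 > 48) || any(hours03 < 0 | hours03 > 48))
    stop("urine-low hours must lie in [0, 48]", call. = FALSE)
  if (any(hours03 > hours05))
    stop("hours below 0.3 cannot exceed hours below 0.5", call. = FALSE)
  vapply(seq_along(ratio), function(i)
    .kdigo_stage_one(ratio[i], hours05[i], hours03[i]), integer(1))
}

#' Binary severe-AKI indicator from the KDIGO ordinal stage
#'
#' 1 if the ordinal stage is 2 or 3 (severe injury), 0 if it is 0 or 1. The
#' binary collapse reflects that most stage-1 cases are mild with full
#' recovery, making severe cases the clinically relevant target.
#'
#' @param ordinal Integer stage(s) in 0-3.
#' @return Integer 0/1 vector.
#' @export
kdigo_binary <- function(ordinal) {
  if (any(!ordinal %in% 0:3))
    stop("KDIGO ordinal stage must be an integer in 0-3", call. = FALSE)
  as.integer(ordinal >= 2)
}

#' Compute the five AKI outcomes for a cohort table
#'
#' From each row's creatinine ratio and 48-hour urine series, derives the
#' five outcome measures: the creatinine ratio itself, hours of urine output
#' below 0.5 and below 0.3 ml/kg/h, the KDIGO ordinal stage and the severe
#' (binary) indicator.
#'
#' @param cohort Data frame with columns `creatinine_ratio` and `urine`
#'   (a list column of 48-value series, or a character column of JSON-encoded
#'   arrays as written by [write_cohort()]).
#' @return Data frame keyed by `row_id` with columns `creatinine_ratio`,
#'   `hours_below_05`, `hours_below_03`, `kdigo_ordinal`, `kdigo_binary`.
#' @export
compute_aki_outcomes <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("creatinine_ratio", "urine") %in% names(cohort)))
  urine <- cohort$urine
  if (is.character(urine))
    urine <- lapply(urine, function(s) jsonlite::fromJSON(s))
  h05 <- vapply(urine, urine_low_hours, integer(1), threshold = 0.5)
  h03 <- vapply(urine, urine_low_hours, integer(1), threshold = 0.3)
  ord <- kdigo_ordinal(cohort$creatinine_ratio, h05, h03)
  data.frame(
    row_id = if ("row_id" %in% names(cohort)) cohort$row_id
             else seq_len(nrow(cohort)),
    creatinine_ratio = cohort$creatinine_ratio,
    hours_below_05 = h05,
    hours_below_03 = h03,
    kdigo_ordinal = ord,
    kdigo_binary = kdigo_binary(ord)
  )
}
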