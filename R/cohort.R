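## Reference cohort metadata mirroring the published study table: nine
## preterm infants, ten measurements (subject 4 recorded twice), with
## gestational and postmenstrual age, recording duration and the QS/AS
## epoch ratio per measurement. Used as input for fold planning and as the
## template the simulator's manifests follow.

#' Reference cohort metadata
#'
#' @return data.frame with one row per measurement: `measurement_id`,
#'   `subject_id`, `ga_weeks`, `pma_weeks`, `sex`, `birthweight_g`,
#'   `duration_min`, `qs_as_ratio`.
#' @export
example_cohort <- function() {
  data.frame(
    measurement_id = c("1", "2", "3", "4a", "4b", "5", "6", "7", "8", "9"),
    subject_id     = c("1", "2", "3", "4", "4", "5", "6", "7", "8", "9"),
    ga_weeks       = c(25.7, 31.7, 34.6, 37, 37, 34.6, 30.9, 31.3, 31.7, 35),
    pma_weeks      = c(34.8, 31.8, 35.1, 38.1, 38.2, 34.7, 36.4, 34.2, 32.8, 35.1),
    sex            = c("F", "M", "M", "M", "M", "F", "M", "F", "M", "F"),
    birthweight_g  = c(635, 1355, 1700, 2650, 2650, 1976, 1900, 1550, 1710, 2350),
    duration_min   = c(75, 57, 74, 99, 13, 180, 73, 35, 96, 21),
    qs_as_ratio    = c(0.21, 0.12, 0.68, 0.15, 1.60, 0.34, 0.40, 0.59, 0.34, 4.25)
  )
}

#' Pooled epoch inventory of the reference annotation
#'
#' One-minute behavioral sleep scores of the reference cohort: 191 quiet
#' sleep, 532 active sleep and 38 wake epochs; the binary AS-vs-QS task uses
#' the QS + AS total.
#'
#' @return named list `qs`, `as`, `wake`, `binary_total`.
#' @export
epoch_inventory <- function() {
  counts <- list(qs = 191L, as = 532L, wake = 38L)
  counts$binary_total <- counts$qs + counts$as
  counts
}

#' Published leave-measurement-out fold plan
#'
#' The fixture grouping of the ten reference measurements into five
#' subject-exclusive folds of two measurements each, with per-fold total
#' durations derived from the cohort table.
#'
#' @return object of class `fold_plan` (scheme
#'   `leave_measurement_out_5fold`) with a `groups` list and per-fold
#'   `duration_min`.
#' @export
reference_fold_plan <- function() {
  groups <- list(c("2", "9"), c("4a", "4b"), c("1", "3"), c("7", "8"), c("5", "6"))
  meta <- example_cohort()
  dur <- vapply(groups, function(g)
    sum(meta$duration_min[match(g, meta$measurement_id)]), numeric(1))
  structure(list(scheme = "leave_measurement_out_5fold",
                 assignment = data.frame(
                   measurement_id = unlist(groups),
                   fold = rep(seq_along(groups), lengths(groups))),
                 groups = groups, duration_min = dur, seed = NA_integer_),
            class = "fold_plan")
}
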