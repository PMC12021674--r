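#' Screening strategy schedules
#'
#' The four comparators share one protocol skeleton: a primary test at a
#' fixed interval, colonoscopy referral on a positive result, surveillance
#' colonoscopy every 3 years after polypectomy of an advanced colorectal
#' neoplasm (until a colonoscopy finds nothing to remove), and a 10-year
#' pause after a normal colonoscopy before the primary test resumes.
#'
#' * `none` -- no screening events, ever.
#' * `fit` -- annual faecal immunochemical test, referral on positive.
#' * `colotect` -- annual multi-target stool-DNA test, referral on positive.
#' * `colonoscopy` -- colonoscopy as the primary test every 10 years (the
#'   10-year post-normal pause *is* the interval).
#'
#' @param name one of `"none"`, `"fit"`, `"colotect"`, `"colonoscopy"`.
#' @return A `strategy_schedule`: list with `name`, `modality`
#'   (`"none"`, `"stool"` or `"colonoscopy"`), `primary_interval`,
#'   `surveillance_interval`, `post_normal_reset`, `referral_on_positive`.
#' @export
#' @examples
#' make_strategy("colotect")$primary_interval  # 1
#' make_strategy("colonoscopy")$primary_interval  # 10
make_strategy <- function(name) {
  name <- match.arg(name, strategy_names())
  sch <- switch(name,
    none = list(name = "none", modality = "none",
                primary_interval = NA_integer_,
                referral_on_positive = FALSE),
    fit = list(name = "fit", modality = "stool", primary_interval = 1L,
               referral_on_positive = TRUE),
    colotect = list(name = "colotect", modality = "stool",
                    primary_interval = 1L, referral_on_positive = TRUE),
    colonoscopy = list(name = "colonoscopy", modality = "colonoscopy",
                       primary_interval = 10L, referral_on_positive = FALSE))
  sch$surveillance_interval <- 3L
  sch$post_normal_reset <- 10L
  class(sch) <- "strategy_schedule"
  sch
}

#' Strategy names accepted across the package (and the CLI)
#' @return Character vector.
#' @export
strategy_names <- function() c("none", "fit", "colotect", "colonoscopy")

#' Which cohort mass is due for screening this cycle
#'
#' Applies the eligibility rules to a cohort state: well mass (not in a
#' post-normal pause or under surveillance) is due for the primary test;
#' surveillance-clock mass whose clock has reached the surveillance interval
#' is due for surveillance colonoscopy; pause-clock mass whose clock has
#' reached the reset interval re-enters the primary pool (and, by the tie
#' rule, receives the primary test that same year, not a colonoscopy).
#'
#' @param state a `cohort_state` (see [new_cohort_state()]).
#' @param schedule a `strategy_schedule` or strategy name.
#' @param age current age (must lie within the model range implied by the
#'   state).
#' @return List with `primary_due` and `surveillance_due` masses (persons).
#' @export
due_for_screening <- function(state, schedule, age) {
  if (!inherits(schedule, "strategy_schedule"))
    schedule <- make_strategy(schedule)
  m <- state$masses
  if (schedule$modality == "none")
    return(list(primary_due = 0, surveillance_due = 0))
  reset_idx <- paste0("pause", schedule$post_normal_reset - 1L)
  returning <- if (reset_idx %in% names(m)) unname(m[reset_idx]) else 0
  surv_due_idx <- paste0("surv", schedule$surveillance_interval - 1L)
  surveillance_due <- if (surv_due_idx %in% names(m)) unname(m[surv_due_idx]) else 0
  list(primary_due = unname(m["well"]) + returning,
       surveillance_due = surveillance_due)
}

#' @export
print.strategy_schedule <- function(x, ...) {
  if (x$modality == "none") {
    cat("<strategy> no screening\n")
  } else {
    cat(sprintf("<strategy> %s: primary %s every %dy%s; surveillance every %dy; %dy pause after normal colonoscopy\n",
                x$name, x$modality, x$primary_interval,
                if (x$referral_on_positive) ", colonoscopy on positive" else "",
                x$surveillance_interval, x$post_normal_reset))
  }
  invisible(x)
}
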