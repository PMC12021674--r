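## Deterministic expected-value Markov cohort engine.
##
## Cohort mass moves through: well (undiagnosed, in the primary screening
## pool), a surveillance clock after polypectomy (colonoscopy every
## `surveillance_interval` years), a pause clock after a normal colonoscopy
## (primary testing resumes after `post_normal_reset` years), four diagnosed
## CRC stages with year-in-state clocks (stage III splits at diagnosis into a
## cure track and a failure track that progresses to stage-IV-like
## mortality), cured, and three absorbing death states (CRC, other cause,
## colonoscopy complication). Fractional persons are carried throughout;
## mass is conserved exactly at every cycle.
##
## Fixed per-cycle event order: clock advance -> scheduled screening (with
## its colonoscopies) -> CRC incidence -> stage-specific CRC mortality ->
## other-cause mortality -> cost / life-year accrual discounted by years
## since the start age. After the final screening age the cohort is followed
## to the closing age for cancer-related life-year accounting only.

.comp_names <- function(si, reset, cure_years) {
  c("well", paste0("surv", 0:(si - 1)), paste0("pause", 0:(reset - 1)),
    paste0("s1y", 1:cure_years), paste0("s2y", 1:cure_years),
    paste0("s3cy", 1:cure_years), paste0("s3fy", 1:cure_years),
    "s4", "cured", "dead_crc", "dead_other", "dead_compl")
}

#' Create a fresh cohort state
#'
#' All mass starts in the `well` compartment at the model start age.
#'
#' @param params a `crc_params` bundle (sets cohort size, clock lengths).
#' @return A `cohort_state`: list with `masses` (named non-negative numeric
#'   vector summing to the cohort size) and `age`.
#' @export
new_cohort_state <- function(params = default_parameters()) {
  m <- params$model
  comp <- .comp_names(m$surveillance_interval, m$post_normal_reset,
                      m$cure_years)
  masses <- stats::setNames(numeric(length(comp)), comp)
  masses["well"] <- m$cohort_size
  structure(list(masses = masses, age = m$start_age, referred = 0),
            class = "cohort_state")
}

#' Shift a stage-at-diagnosis distribution toward earlier stages
#'
#' Screen-detected cancers are diagnosed earlier: a fraction `shift` of the
#' stage III and IV probability mass is reassigned onto stages I and II in
#' proportion to their baseline probabilities.
#'
#' @param dist length-4 probability vector over stages I--IV (sums to 1).
#' @param shift fraction of late-stage mass moved forward, in \[0,1\].
#' @return Shifted length-4 probability vector.
#' @export
shift_stage_distribution <- function(dist, shift) {
  stopifnot(length(dist) == 4, abs(sum(dist) - 1) < 1e-9,
            shift >= 0, shift <= 1)
  moved <- shift * (dist[3] + dist[4])
  early <- dist[1] + dist[2]
  out <- dist
  out[1] <- dist[1] + moved * dist[1] / early
  out[2] <- dist[2] + moved * dist[2] / early
  out[3] <- dist[3] * (1 - shift)
  out[4] <- dist[4] * (1 - shift)
  out
}

## Expected colonoscopy tallies for a block of colonoscopies.
## `clear`: cancer-free persons scoped (routed to surveillance / pause);
## `cancer`: persons whose cancer is found at the scope (routed to stages by
## the caller); `fn`: persons scoped whose cancer the scope misses (counted
## as colonoscopies, routed by the caller). The therapeutic/diagnostic split
## is applied to ALL colonoscopies so the therapeutic fraction equals the
## polypectomy rate exactly.
.colo_block <- function(clear, cancer, fn, proc) {
  n <- clear + cancer + fn
  ther_count <- n * proc$polypectomy_rate
  perf <- n * proc$perforation_rate
  perf_d <- n * proc$perforation_mortality
  bleeds <- if (proc$bleeding_basis == "per_colonoscopy")
    n * proc$bleeding_rate else ther_count * proc$bleeding_rate_per_polypectomy
  surv_factor <- 1 - proc$perforation_mortality
  ther_route <- clear * proc$polypectomy_rate
  list(n = n, ther_count = ther_count, diag_count = n - ther_count,
       perforations = perf, perf_deaths = perf_d, bleeds = bleeds,
       to_surv = ther_route * surv_factor,
       to_pause = (clear - ther_route) * surv_factor,
       cancer_out = cancer * surv_factor, fn_out = fn * surv_factor,
       cost_colo = n * (proc$cost + proc$consultation),
       cost_poly = ther_count * proc$histopathology,
       cost_bleed = bleeds * proc$bleeding_cost,
       cost_perf = perf * proc$perforation_cost)
}

#' One stool-test screening round (expected-value)
#'
#' Attending mass is the well pool times the round's compliance; expected
#' positives combine true positives at the test's sensitivity with false
#' positives at one minus specificity; positives are referred to colonoscopy
#' at the post-positive compliance. Negatives simply repeat next year.
#'
#' @param state a `cohort_state`.
#' @param test a screening test profile (e.g. `params$tests$colotect`).
#' @param params the parameter bundle.
#' @param prevalence fraction of the attending mass with detectable CRC
#'   (the detection context for this cycle).
#' @return List: updated `state` (with the referral recorded in
#'   `state$referred`), `referred_mass`, `tests_used`, `positives`.
#' @export
screening_round <- function(state, test, params, prevalence = 0) {
  att <- unname(state$masses["well"]) * test$compliance
  pos <- att * (prevalence * test$sensitivity +
                  (1 - prevalence) * (1 - test$specificity))
  referred <- pos * params$procedure$compliance_after_positive
  state$referred <- referred
  list(state = state, referred_mass = referred, tests_used = att,
       positives = pos)
}

#' One colonoscopy round (expected-value)
#'
#' Performs `mass` colonoscopies on cancer-free mass drawn from the well
#' pool: the polypectomy-rate fraction is therapeutic and enters the
#' surveillance clock, the rest is diagnostic and enters the post-normal
#' pause. Perforations, perforation deaths (moved to the complication death
#' state) and bleeds are accrued, as are procedure, histopathology and
#' complication costs (undiscounted; the engine discounts at accrual).
#'
#' @param state a `cohort_state`.
#' @param profile the colonoscopy procedure profile (`params$procedure`).
#' @param params the parameter bundle.
#' @param mass colonoscopies to perform (defaults to the recorded referral).
#' @return List: updated `state` and `tallies` (counts and undiscounted
#'   costs as returned for every colonoscopy block).
#' @export
colonoscopy_round <- function(state, profile = params$procedure, params,
                              mass = state$referred) {
  cb <- .colo_block(mass, 0, 0, profile)
  m <- state$masses
  m["well"] <- m["well"] - mass
  m["surv0"] <- m["surv0"] + cb$to_surv
  m["pause0"] <- m["pause0"] + cb$to_pause
  m["dead_compl"] <- m["dead_compl"] + cb$perf_deaths
  state$masses <- m
  state$referred <- 0
  list(state = state, tallies = cb)
}

#' Apply one cycle of CRC incidence to the undiagnosed pool (expected-value)
#'
#' The screen-protected fraction of the well mass incurs the incidence rate
#' reduced by the prevention fraction; the remainder incurs the full rate.
#' Incident cases are assigned to stages I--IV by the stage-at-diagnosis
#' distribution; the screen-detected fraction of cases uses the
#' earlier-stage shifted distribution (see [shift_stage_distribution()]).
#'
#' @param state a `cohort_state`.
#' @param rate CRC incidence per person-year.
#' @param protected_fraction fraction of the well mass under screening
#'   protection.
#' @param prevention fraction of cancers prevented among the protected.
#' @param params the parameter bundle (stage distribution, stage-III split,
#'   stage-shift fraction).
#' @param screen_detected_fraction fraction of incident cases detected by
#'   screening (these use the shifted stage distribution).
#' @return List: updated `state`, `new_cases_by_stage` (length-4).
#' @export
apply_incidence <- function(state, rate, protected_fraction, prevention,
                            params, screen_detected_fraction = 0) {
  stopifnot(rate >= 0, protected_fraction >= 0, protected_fraction <= 1,
            prevention >= 0, prevention <= 1)
  well <- unname(state$masses["well"])
  eff_rate <- protected_fraction * rate * (1 - prevention) +
    (1 - protected_fraction) * rate
  cases <- well * eff_rate
  dist <- params$stages$distribution
  dist_mix <- (1 - screen_detected_fraction) * dist +
    screen_detected_fraction * shift_stage_distribution(dist, params$model$stage_shift)
  by_stage <- cases * dist_mix
  state$masses <- .enter_stages(state$masses, by_stage,
                                params$model$stage3_cure_rate)
  state$masses["well"] <- state$masses["well"] - cases
  list(state = state, new_cases_by_stage = stats::setNames(by_stage,
                                                           c("I", "II", "III", "IV")))
}

.enter_stages <- function(m, by_stage, cure3) {
  m["s1y1"] <- m["s1y1"] + by_stage[1]
  m["s2y1"] <- m["s2y1"] + by_stage[2]
  m["s3cy1"] <- m["s3cy1"] + by_stage[3] * cure3
  m["s3fy1"] <- m["s3fy1"] + by_stage[3] * (1 - cure3)
  m["s4"] <- m["s4"] + by_stage[4]
  m
}

#' Apply one cycle of stage-specific CRC mortality (expected-value)
#'
#' Every diagnosed-stage compartment loses its annual stage mortality to
#' the CRC death state (the stage-III failure track uses stage-III mortality
#' while on its clock and stage-IV mortality after progression; movement to
#' `cured` past the cure horizon happens when year clocks advance at the
#' next cycle).
#'
#' @param state a `cohort_state`.
#' @param params the parameter bundle.
#' @return List: updated `state`, `crc_deaths` (persons this cycle).
#' @export
apply_stage_mortality <- function(state, params) {
  qs <- params$stages$mortality
  cy <- params$model$cure_years
  m <- state$masses
  groups <- list(list(paste0("s1y", 1:cy), qs[["I"]]),
                 list(paste0("s2y", 1:cy), qs[["II"]]),
                 list(paste0("s3cy", 1:cy), qs[["III"]]),
                 list(paste0("s3fy", 1:cy), qs[["III"]]),
                 list("s4", qs[["IV"]]))
  deaths <- 0
  for (g in groups) {
    d <- sum(m[g[[1]]]) * g[[2]]
    m[g[[1]]] <- m[g[[1]]] * (1 - g[[2]])
    deaths <- deaths + d
  }
  m["dead_crc"] <- m["dead_crc"] + deaths
  state$masses <- m
  list(state = state, crc_deaths = unname(deaths))
}

#' Discounted cancer-related life-years lost
#'
#' For deaths at each age, multiplies the count by the remaining life
#' expectancy at that age and the discount factor for years elapsed since
#' the start age. A zero discount rate gives the plain sum.
#'
#' @param crc_deaths_by_age named numeric vector (names are ages).
#' @param life a `life_table`.
#' @param discount_rate annual rate (>= 0).
#' @param start_age age at which discounting starts (exponent zero).
#' @return Discounted life-years lost (scalar).
#' @export
life_years_lost <- function(crc_deaths_by_age, life, discount_rate = 0.03,
                            start_age = 50) {
  if (length(crc_deaths_by_age) == 0) return(0)
  ages <- as.integer(names(crc_deaths_by_age))
  ex <- remaining_life_expectancy(life, ages)
  sum(crc_deaths_by_age * ex * discount_factor(ages - start_age, discount_rate))
}

#' Run the deterministic cohort model for one strategy
#'
#' Advances the whole cohort through annual cycles from the start age to the
#' final screening age (then to the closing age for cancer-related
#' life-year accounting only), applying the strategy's screening protocol,
#' CRC incidence with prevention among the screen-protected, stage-specific
#' cancer mortality, other-cause mortality, and discounted cost and
#' life-year accrual. All tallies are exact expectations; no sampling.
#'
#' @param strategy strategy name (`"none"`, `"fit"`, `"colotect"`,
#'   `"colonoscopy"`) or a [make_strategy()] schedule.
#' @param params a valid `crc_params` bundle.
#' @param incidence an `incidence_table` covering the screening ages.
#' @param life a `life_table` covering start age through closing age.
#' @return A `strategy_result`: list with `strategy`, `cases_total`,
#'   `cases_by_stage`, `crc_deaths_total`, `deaths_by_age`,
#'   `life_years_lost` (discounted), `tests_used`, `colonoscopies`
#'   (`total`, `diagnostic`, `therapeutic`), `complications` (`bleeds`,
#'   `perforations`, `perforation_deaths`), `costs` (discounted USD ledger
#'   with `total`), and `mass_audit` (per-cycle compartment-mass totals).
#' @export
#' @examples
#' inc <- gen_incidence()
#' lt <- gen_life_table()
#' res <- run_cohort("colotect", default_parameters(), inc, lt)
#' res$cases_total
run_cohort <- function(strategy, params = default_parameters(),
                       incidence = gen_incidence(), life = gen_life_table()) {
  sch <- if (inherits(strategy, "strategy_schedule")) strategy
         else make_strategy(strategy)
  errs <- validate_params(params)
  if (length(errs))
    stop(paste(c("invalid parameters:", errs), collapse = "\n  "),
         call. = FALSE)
  mdl <- params$model

  if (mdl$attendance_model == "once_ever" && sch$modality != "none") {
    w <- params$tests[[sch$name]]$compliance
    p1 <- params
    p1$model$attendance_model <- "independent_per_round"
    p1$tests[[sch$name]]$compliance <- 1
    r1 <- run_cohort(sch, p1, incidence, life)
    r0 <- run_cohort("none", p1, incidence, life)
    return(.mix_results(r1, r0, w, sch$name))
  }

  ages_main <- mdl$start_age:mdl$end_age
  ages_tail <- (mdl$end_age + 1):mdl$closing_age
  .incidence_at(incidence, ages_main)          # coverage check
  .mortality_at(life, c(ages_main, ages_tail)) # coverage check

  si <- mdl$surveillance_interval
  reset <- mdl$post_normal_reset
  cy <- mdl$cure_years
  comp <- .comp_names(si, reset, cy)
  st <- stats::setNames(numeric(length(comp)), comp)
  st["well"] <- mdl$cohort_size

  test <- if (sch$modality == "none") NULL else params$tests[[sch$name]]
  scope_sens <- params$tests$colonoscopy$sensitivity
  proc <- params$procedure
  dist_std <- unname(params$stages$distribution)
  dist_shift <- shift_stage_distribution(dist_std, mdl$stage_shift)
  cure3 <- mdl$stage3_cure_rate
  r <- mdl$discount_rate

  surv_names <- paste0("surv", 0:(si - 1))
  pause_names <- paste0("pause", 0:(reset - 1))
  stage_names <- c(paste0("s1y", 1:cy), paste0("s2y", 1:cy),
                   paste0("s3cy", 1:cy), paste0("s3fy", 1:cy), "s4")
  alive_names <- c("well", surv_names, pause_names, stage_names, "cured")

  all_ages <- c(ages_main, ages_tail)
  deaths_by_age <- stats::setNames(numeric(length(all_ages)), all_ages)
  cases_by_stage <- c(I = 0, II = 0, III = 0, IV = 0)
  tests_used <- 0
  colos <- c(total = 0, diagnostic = 0, therapeutic = 0)
  compl <- c(bleeds = 0, perforations = 0, perforation_deaths = 0)
  costs <- c(kit = 0, colonoscopy = 0, polypectomy = 0, bleeding = 0,
             perforation = 0, care_I = 0, care_II = 0, care_III = 0,
             care_IV = 0)
  lyl <- 0
  mass_audit <- stats::setNames(numeric(length(all_ages)), all_ages)

  for (age in all_ages) {
    t <- age - mdl$start_age
    df <- discount_factor(t, r)
    in_main <- age <= mdl$end_age

    ## (1) clock advance
    dueS <- 0
    if (t > 0) {
      if (in_main && sch$modality != "none") {
        # surveillance clock: top slot becomes due for colonoscopy
        dueS <- unname(st[surv_names[si]])
        if (si > 1) st[surv_names[2:si]] <- st[surv_names[1:(si - 1)]]
        st[surv_names[1]] <- 0
        # pause clock: expiring mass rejoins the primary pool (tie rule:
        # it receives the primary test this same year)
        back <- unname(st[pause_names[reset]])
        if (reset > 1) st[pause_names[2:reset]] <- st[pause_names[1:(reset - 1)]]
        st[pause_names[1]] <- 0
        st["well"] <- st["well"] + back
      }
      # stage year clocks: cure past the horizon; stage-III failure track
      # progresses to stage-IV-like mortality
      for (pref in c("s1y", "s2y", "s3cy")) {
        nm <- paste0(pref, 1:cy)
        st["cured"] <- st["cured"] + st[nm[cy]]
        if (cy > 1) st[nm[2:cy]] <- st[nm[1:(cy - 1)]]
        st[nm[1]] <- 0
      }
      nm <- paste0("s3fy", 1:cy)
      st["s4"] <- st["s4"] + st[nm[cy]]
      if (cy > 1) st[nm[2:cy]] <- st[nm[1:(cy - 1)]]
      st[nm[1]] <- 0
    }

    rate <- if (in_main) .incidence_at(incidence, age) else 0
    qall <- .mortality_at(life, age)

    ## (2) screening round + colonoscopies, (3) incidence
    new_shift <- 0   # screen-detected incident cases (shifted stages)
    new_std <- 0     # clinically detected incident cases (standard stages)

    if (in_main && sch$modality != "none") {
      c_t <- test$compliance *
        if (mdl$attendance_model == "geometric_attrition") mdl$attrition^t else 1
      rate_prot <- rate * (1 - test$prevention)
      # mass in the surveillance / pause states has been protected by
      # colonoscopy (with polypectomy where indicated), so the colonoscopy
      # prevention fraction applies there regardless of the primary test
      rate_scope <- rate * (1 - params$tests$colonoscopy$prevention)
      W <- unname(st["well"])

      # protected pool already under colonoscopy follow-up (snapshot before
      # this cycle's routings)
      pool_names <- c(surv_names, pause_names)
      pool <- st[pool_names]
      cases_pool <- sum(pool) * rate_scope
      st[pool_names] <- pool * (1 - rate_scope)
      new_std <- new_std + cases_pool

      # surveillance colonoscopy on due mass (full attendance)
      cases_dueS <- dueS * rate_scope
      detS <- cases_dueS * scope_sens
      missS <- cases_dueS - detS
      clear_dueS <- dueS - cases_dueS

      if (sch$modality == "stool") {
        att <- W * c_t
        nonatt <- W - att
        tests_used <- tests_used + att
        costs["kit"] <- costs["kit"] + att * test$cost * df
        cases_att <- att * rate_prot
        det <- cases_att * test$sensitivity
        miss <- cases_att - det
        fp <- (att - cases_att) * (1 - test$specificity) *
          proc$compliance_after_positive
        cases_nonatt <- nonatt * rate
        cb <- .colo_block(fp + clear_dueS, det + detS, missS, proc)
        new_shift <- new_shift + cb$cancer_out
        new_std <- new_std + miss + cb$fn_out + cases_nonatt
        st["well"] <- (att - cases_att - fp) + (nonatt - cases_nonatt)
      } else { # colonoscopy as the primary test
        att <- W * c_t
        nonatt <- W - att
        cases_att <- att * rate_prot
        det <- cases_att * scope_sens
        miss <- cases_att - det
        clear_att <- att - cases_att
        cases_nonatt <- nonatt * rate
        cb <- .colo_block(clear_att + clear_dueS, det + detS, miss + missS,
                          proc)
        new_shift <- new_shift + cb$cancer_out
        new_std <- new_std + cb$fn_out + cases_nonatt
        st["well"] <- nonatt - cases_nonatt
      }

      st["surv0"] <- st["surv0"] + cb$to_surv
      st["pause0"] <- st["pause0"] + cb$to_pause
      st["dead_compl"] <- st["dead_compl"] + cb$perf_deaths
      colos["total"] <- colos["total"] + cb$n
      colos["diagnostic"] <- colos["diagnostic"] + cb$diag_count
      colos["therapeutic"] <- colos["therapeutic"] + cb$ther_count
      compl["bleeds"] <- compl["bleeds"] + cb$bleeds
      compl["perforations"] <- compl["perforations"] + cb$perforations
      compl["perforation_deaths"] <- compl["perforation_deaths"] + cb$perf_deaths
      costs["colonoscopy"] <- costs["colonoscopy"] + cb$cost_colo * df
      costs["polypectomy"] <- costs["polypectomy"] + cb$cost_poly * df
      costs["bleeding"] <- costs["bleeding"] + cb$cost_bleed * df
      costs["perforation"] <- costs["perforation"] + cb$cost_perf * df
    } else if (in_main) { # no screening
      W <- unname(st["well"])
      cases_now <- W * rate
      st["well"] <- W - cases_now
      new_std <- new_std + cases_now
    }

    ## stage assignment of this cycle's diagnoses
    if (new_std + new_shift > 0) {
      by_stage <- new_std * dist_std + new_shift * dist_shift
      cases_by_stage <- cases_by_stage + by_stage
      st <- .enter_stages(st, by_stage, cure3)
      costs[c("care_I", "care_II", "care_III", "care_IV")] <-
        costs[c("care_I", "care_II", "care_III", "care_IV")] +
        by_stage * unname(params$stages$cost_total) * df
    }

    ## (4) stage-specific CRC mortality
    deaths_cycle <- 0
    for (g in list(list(paste0("s1y", 1:cy), params$stages$mortality[["I"]]),
                   list(paste0("s2y", 1:cy), params$stages$mortality[["II"]]),
                   list(paste0("s3cy", 1:cy), params$stages$mortality[["III"]]),
                   list(paste0("s3fy", 1:cy), params$stages$mortality[["III"]]),
                   list("s4", params$stages$mortality[["IV"]]))) {
      d <- sum(st[g[[1]]]) * g[[2]]
      st[g[[1]]] <- st[g[[1]]] * (1 - g[[2]])
      deaths_cycle <- deaths_cycle + d
    }
    st["dead_crc"] <- st["dead_crc"] + deaths_cycle
    deaths_by_age[[as.character(age)]] <- deaths_cycle

    ## (5) other-cause mortality on every alive compartment
    d_other <- sum(st[alive_names]) * qall
    st[alive_names] <- st[alive_names] * (1 - qall)
    st["dead_other"] <- st["dead_other"] + d_other

    ## (6) life-year accrual
    lyl <- lyl + deaths_cycle * remaining_life_expectancy(life, age) * df

    mass_audit[[as.character(age)]] <- sum(st)
  }

  costs_total <- c(costs, total = sum(costs))
  structure(list(
    strategy = sch$name,
    cohort_size = mdl$cohort_size,
    cases_total = unname(sum(cases_by_stage)),
    cases_by_stage = cases_by_stage,
    crc_deaths_total = unname(sum(deaths_by_age)),
    deaths_by_age = deaths_by_age,
    life_years_lost = lyl,
    tests_used = unname(tests_used),
    colonoscopies = as.list(colos),
    complications = as.list(compl),
    costs = costs_total,
    mass_audit = mass_audit,
    final_masses = st
  ), class = "strategy_result")
}

# Linear mixture of two strategy results (used by the once_ever attendance
# model: weight w attends every round at compliance 1, weight 1-w never
# screens). Valid because every tally is linear in cohort mass.
.mix_results <- function(r1, r0, w, name) {
  mix <- function(a, b) w * a + (1 - w) * b
  out <- r1
  out$strategy <- name
  for (f in c("cases_total", "crc_deaths_total", "life_years_lost",
              "tests_used"))
    out[[f]] <- mix(r1[[f]], r0[[f]])
  for (f in c("cases_by_stage", "deaths_by_age", "costs", "mass_audit",
              "final_masses"))
    out[[f]] <- mix(r1[[f]], r0[[f]])
  out$colonoscopies <- Map(mix, r1$colonoscopies, r0$colonoscopies)
  out$complications <- Map(mix, r1$complications, r0$complications)
  out
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s (cohort %s)\n", x$strategy,
              format(x$cohort_size, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  CRC cases %.1f (I %.1f, II %.1f, III %.1f, IV %.1f); CRC deaths %.1f\n",
              x$cases_total, x$cases_by_stage[1], x$cases_by_stage[2],
              x$cases_by_stage[3], x$cases_by_stage[4], x$crc_deaths_total))
  cat(sprintf("  discounted life-years lost %.1f\n", x$life_years_lost))
  cat(sprintf("  primary tests %.0f; colonoscopies %.0f (diagnostic %.0f, therapeutic %.0f)\n",
              x$tests_used, x$colonoscopies$total, x$colonoscopies$diagnostic,
              x$colonoscopies$therapeutic))
  cat(sprintf("  complications: bleeds %.1f, perforations %.1f (deaths %.2f)\n",
              x$complications$bleeds, x$complications$perforations,
              x$complications$perforation_deaths))
  cat(sprintf("  total discounted cost %s USD\n",
              format(round(x$costs[["total"]]), big.mark = ",")))
  invisible(x)
}
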