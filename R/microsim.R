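## Seeded individual-level microsimulation.
##
## Simulates n independent life histories with the same event logic and the
## same fixed per-cycle event order as the deterministic cohort engine, then
## scales tallies to cohort size. It exists as a cross-validation oracle for
## run_cohort(): for matching inputs its headline tallies converge on the
## cohort expectations at the binomial rate.

# state codes
.MS <- c(WELL = 1L, SURV = 2L, PAUSE = 3L, S1 = 4L, S2 = 5L, S3C = 6L,
         S3F = 7L, S4 = 8L, CURED = 9L, DEAD_CRC = 10L, DEAD_OTHER = 11L,
         DEAD_COMPL = 12L)

#' Individual-level microsimulation of one strategy
#'
#' @inheritParams run_cohort
#' @param n number of simulated persons (tallies are scaled up to the
#'   cohort size).
#' @param seed integer seed; identical seeds give identical results. The
#'   caller's RNG stream is left untouched.
#' @return A `strategy_result` (same shape as [run_cohort()]); additionally
#'   carries `n_sim` and `lyl_per_person` (per-person discounted
#'   life-years-lost contributions, for standard-error estimates).
#' @export
microsim_run <- function(strategy, params = default_parameters(),
                         incidence = gen_incidence(),
                         life = gen_life_table(), n = 10000L, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  .with_seed(seed,
             .microsim_impl(strategy, params, incidence, life, as.integer(n)))
}

.microsim_impl <- function(strategy, params, incidence, life, n) {
  sch <- if (inherits(strategy, "strategy_schedule")) strategy
         else make_strategy(strategy)
  errs <- validate_params(params)
  if (length(errs))
    stop(paste(c("invalid parameters:", errs), collapse = "\n  "),
         call. = FALSE)
  mdl <- params$model
  test <- if (sch$modality == "none") NULL else params$tests[[sch$name]]
  proc <- params$procedure
  scope_sens <- params$tests$colonoscopy$sensitivity
  dist_std <- unname(params$stages$distribution)
  dist_shift <- shift_stage_distribution(dist_std, mdl$stage_shift)
  qs <- params$stages$mortality
  cy <- mdl$cure_years
  si <- mdl$surveillance_interval
  reset <- mdl$post_normal_reset
  r <- mdl$discount_rate
  scale <- mdl$cohort_size / n
  S <- .MS

  state <- rep(S[["WELL"]], n)
  clk <- integer(n)
  participant <- if (!is.null(test) && mdl$attendance_model == "once_ever")
    stats::runif(n) < test$compliance else NULL

  all_ages <- mdl$start_age:mdl$closing_age
  deaths_by_age <- stats::setNames(numeric(length(all_ages)), all_ages)
  cases_by_stage <- c(I = 0, II = 0, III = 0, IV = 0)
  tests_used <- 0
  colos <- c(total = 0, diagnostic = 0, therapeutic = 0)
  compl <- c(bleeds = 0, perforations = 0, perforation_deaths = 0)
  costs <- c(kit = 0, colonoscopy = 0, polypectomy = 0, bleeding = 0,
             perforation = 0, care_I = 0, care_II = 0, care_III = 0,
             care_IV = 0)
  lyl_pp <- numeric(n)

  draw_stage <- function(k, dist) {
    if (k == 0) return(integer(0))
    sample.int(4L, k, replace = TRUE, prob = dist)
  }

  diagnose <- function(idx, shifted, df) {
    if (!length(idx)) return(invisible())
    stg <- draw_stage(length(idx), if (shifted) dist_shift else dist_std)
    for (s in 1:4)
      cases_by_stage[s] <<- cases_by_stage[s] + sum(stg == s)
    costs[paste0("care_", c("I", "II", "III", "IV"))] <<-
      costs[paste0("care_", c("I", "II", "III", "IV"))] +
      tabulate(stg, 4) * unname(params$stages$cost_total) * df
    newstate <- c(S[["S1"]], S[["S2"]], S[["S3C"]], S[["S4"]])[stg]
    is3 <- stg == 3L
    if (any(is3)) {
      fail <- stats::runif(sum(is3)) >= mdl$stage3_cure_rate
      newstate[is3][fail] <- S[["S3F"]]
    }
    state[idx] <<- newstate
    clk[idx] <<- 1L
    invisible()
  }

  # colonoscopy participants: perforation deaths sampled per person;
  # survivors reported back for routing/diagnosis
  scope <- function(idx, df) {
    k <- length(idx)
    if (!k) return(idx)
    colos["total"] <<- colos["total"] + k
    poly <- stats::runif(k) < proc$polypectomy_rate
    colos["therapeutic"] <<- colos["therapeutic"] + sum(poly)
    colos["diagnostic"] <<- colos["diagnostic"] + sum(!poly)
    nb <- if (proc$bleeding_basis == "per_colonoscopy")
      stats::rbinom(1, k, proc$bleeding_rate)
    else stats::rbinom(1, sum(poly), proc$bleeding_rate_per_polypectomy)
    np <- stats::rbinom(1, k, proc$perforation_rate)
    compl["bleeds"] <<- compl["bleeds"] + nb
    compl["perforations"] <<- compl["perforations"] + np
    costs["colonoscopy"] <<- costs["colonoscopy"] +
      k * (proc$cost + proc$consultation) * df
    costs["polypectomy"] <<- costs["polypectomy"] +
      sum(poly) * proc$histopathology * df
    costs["bleeding"] <<- costs["bleeding"] + nb * proc$bleeding_cost * df
    costs["perforation"] <<- costs["perforation"] +
      np * proc$perforation_cost * df
    dead <- stats::runif(k) < proc$perforation_mortality
    if (any(dead)) {
      compl["perforation_deaths"] <<- compl["perforation_deaths"] + sum(dead)
      state[idx[dead]] <<- S[["DEAD_COMPL"]]
    }
    idx2 <- idx[!dead]
    attr(idx2, "poly") <- poly[!dead]
    idx2
  }

  route_clear <- function(idx2) {
    # idx2 carries the per-person polypectomy flag from scope()
    poly <- attr(idx2, "poly")
    if (!length(idx2)) return(invisible())
    state[idx2[poly]] <<- S[["SURV"]]
    state[idx2[!poly]] <<- S[["PAUSE"]]
    clk[idx2] <<- 0L
    invisible()
  }

  for (age in all_ages) {
    t <- age - mdl$start_age
    df <- discount_factor(t, r)
    in_main <- age <= mdl$end_age

    ## (1) clock advance
    due <- logical(n)
    if (t > 0) {
      if (in_main && sch$modality != "none") {
        i_s <- state == S[["SURV"]]
        clk[i_s] <- clk[i_s] + 1L
        due <- i_s & clk == si
        i_p <- state == S[["PAUSE"]]
        clk[i_p] <- clk[i_p] + 1L
        ret <- i_p & clk == reset
        state[ret] <- S[["WELL"]]
        clk[ret] <- 0L
      }
      i_stage <- state %in% c(S[["S1"]], S[["S2"]], S[["S3C"]], S[["S3F"]],
                              S[["S4"]])
      clk[i_stage] <- clk[i_stage] + 1L
      cure <- state %in% c(S[["S1"]], S[["S2"]], S[["S3C"]]) & clk > cy
      state[cure] <- S[["CURED"]]
      prog <- state == S[["S3F"]] & clk > cy
      state[prog] <- S[["S4"]]
    }

    rate <- if (in_main) .incidence_at(incidence, age) else 0
    qall <- .mortality_at(life, age)

    ## (2) screening + (3) incidence
    if (in_main && sch$modality != "none") {
      c_t <- if (mdl$attendance_model == "once_ever") NA else
        test$compliance *
          if (mdl$attendance_model == "geometric_attrition") mdl$attrition^t else 1
      rate_prot <- rate * (1 - test$prevention)
      # post-colonoscopy states carry the colonoscopy prevention fraction
      rate_scope <- rate * (1 - params$tests$colonoscopy$prevention)

      i_well <- which(state == S[["WELL"]])
      att_flag <- if (is.null(participant)) stats::runif(length(i_well)) < c_t
                  else participant[i_well]
      i_att <- i_well[att_flag]
      i_non <- i_well[!att_flag]

      # protected pool (surveillance not due + pause): reduced incidence,
      # clinical detection at standard stages
      i_pool <- which((state == S[["SURV"]] & !due) | state == S[["PAUSE"]])
      pool_cases <- i_pool[stats::runif(length(i_pool)) < rate_scope]

      # due surveillance colonoscopies (full attendance)
      i_due <- which(due)
      due_case <- stats::runif(length(i_due)) < rate_scope
      i_due_case <- i_due[due_case]
      det_flagS <- stats::runif(length(i_due_case)) < scope_sens
      i_due_clear <- i_due[!due_case]

      if (sch$modality == "stool") {
        tests_used <- tests_used + length(i_att)
        costs["kit"] <- costs["kit"] + length(i_att) * test$cost * df
        case_flag <- stats::runif(length(i_att)) < rate_prot
        i_case <- i_att[case_flag]
        det_flag <- stats::runif(length(i_case)) < test$sensitivity
        i_clear_att <- i_att[!case_flag]
        fp_flag <- stats::runif(length(i_clear_att)) <
          (1 - test$specificity) * proc$compliance_after_positive
        i_fp <- i_clear_att[fp_flag]
        # colonoscopy participants: false positives, due clear, scope-found
        # cancers, scope-missed cancers
        sc_clear <- scope(c(i_fp, i_due_clear), df)
        sc_cancer <- scope(i_due_case[det_flagS], df)
        sc_fn <- scope(i_due_case[!det_flagS], df)
        # stool true positives are confirmed at colonoscopy
        sc_tp <- scope(i_case[det_flag], df)
        route_clear(sc_clear)
        diagnose(c(sc_cancer, sc_tp), shifted = TRUE, df = df)
        diagnose(c(i_case[!det_flag], sc_fn), shifted = FALSE, df = df)
      } else { # colonoscopy primary
        case_flag <- stats::runif(length(i_att)) < rate_prot
        i_case <- i_att[case_flag]
        det_flag <- stats::runif(length(i_case)) < scope_sens
        i_clear_att <- i_att[!case_flag]
        sc_clear <- scope(c(i_clear_att, i_due_clear), df)
        sc_cancer <- scope(c(i_case[det_flag], i_due_case[det_flagS]), df)
        sc_fn <- scope(c(i_case[!det_flag], i_due_case[!det_flagS]), df)
        route_clear(sc_clear)
        diagnose(sc_cancer, shifted = TRUE, df = df)
        diagnose(sc_fn, shifted = FALSE, df = df)
      }
      # unprotected non-attenders: full incidence
      non_cases <- i_non[stats::runif(length(i_non)) < rate]
      diagnose(non_cases, shifted = FALSE, df = df)
      diagnose(pool_cases, shifted = FALSE, df = df)
    } else if (in_main) {
      i_well <- which(state == S[["WELL"]])
      newc <- i_well[stats::runif(length(i_well)) < rate]
      diagnose(newc, shifted = FALSE, df = df)
    }

    ## (4) CRC mortality
    qvec <- rep(0, n)
    qvec[state == S[["S1"]]] <- qs[["I"]]
    qvec[state == S[["S2"]]] <- qs[["II"]]
    qvec[state %in% c(S[["S3C"]], S[["S3F"]])] <- qs[["III"]]
    qvec[state == S[["S4"]]] <- qs[["IV"]]
    i_risk <- which(qvec > 0)
    if (length(i_risk)) {
      dies <- i_risk[stats::runif(length(i_risk)) < qvec[i_risk]]
      if (length(dies)) {
        state[dies] <- S[["DEAD_CRC"]]
        deaths_by_age[[as.character(age)]] <-
          deaths_by_age[[as.character(age)]] + length(dies)
        lyl_pp[dies] <- remaining_life_expectancy(life, age) * df
      }
    }

    ## (5) other-cause mortality
    alive <- which(state <= S[["CURED"]])
    if (length(alive) && qall > 0) {
      dies <- alive[stats::runif(length(alive)) < qall]
      state[dies] <- S[["DEAD_OTHER"]]
    }
  }

  costs_sc <- costs * scale
  costs_total <- c(costs_sc, total = sum(costs_sc))
  structure(list(
    strategy = sch$name,
    cohort_size = mdl$cohort_size,
    n_sim = n,
    cases_total = unname(sum(cases_by_stage)) * scale,
    cases_by_stage = cases_by_stage * scale,
    crc_deaths_total = unname(sum(deaths_by_age)) * scale,
    deaths_by_age = deaths_by_age * scale,
    life_years_lost = sum(lyl_pp) * scale,
    lyl_per_person = lyl_pp,
    tests_used = tests_used * scale,
    colonoscopies = as.list(colos * scale),
    complications = as.list(compl * scale),
    costs = costs_total,
    mass_audit = NULL,
    final_masses = NULL
  ), class = "strategy_result")
}
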