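## One-way sensitivity analysis: parameter sweeps, tornado diagrams, the
## compliance-by-cost ICER grid, and threshold search against the
## willingness-to-pay line.

#' Define a one-way sweep
#'
#' @param parameter_key dotted configuration key (see [param_keys()]).
#' @param low,high sweep end points (`low < high`); values must stay inside
#'   the parameter's validity range.
#' @param steps number of evenly spaced points (>= 2).
#' @return A `sweep_spec`.
#' @export
sweep_spec <- function(parameter_key, low, high, steps = 2L) {
  if (!parameter_key %in% param_keys())
    stop(sprintf("unknown parameter key '%s'", parameter_key), call. = FALSE)
  if (!(low < high)) stop("low must be < high", call. = FALSE)
  if (steps < 2) stop("steps must be >= 2", call. = FALSE)
  structure(list(parameter_key = parameter_key, low = low, high = high,
                 steps = as.integer(steps)), class = "sweep_spec")
}

# ICER of `strategy` vs `reference` for one parameter bundle
.icer_pair <- function(strategy, reference, params, incidence, life) {
  rs <- run_cohort(strategy, params, incidence, life)
  rr <- run_cohort(reference, params, incidence, life)
  icer(rs$costs[["total"]] - rr$costs[["total"]],
       rr$life_years_lost - rs$life_years_lost)
}

#' One-way parameter sweep of the ICER
#'
#' Re-runs the full model (both the strategy and the reference) at each
#' swept value, all other parameters at baseline.
#'
#' @param spec a [sweep_spec()].
#' @param strategy,reference strategy names.
#' @param params baseline bundle.
#' @param incidence,life model inputs.
#' @return Data frame with columns `value` and `icer`.
#' @export
one_way_sweep <- function(spec, strategy, reference = "none",
                          params = default_parameters(),
                          incidence = gen_incidence(),
                          life = gen_life_table()) {
  stopifnot(inherits(spec, "sweep_spec"))
  values <- seq(spec$low, spec$high, length.out = spec$steps)
  ic <- vapply(values, function(v) {
    p <- set_param(params, spec$parameter_key, v)
    errs <- validate_params(p)
    if (length(errs))
      stop(paste(c(sprintf("sweep of '%s' leaves invalid parameters:",
                           spec$parameter_key), errs), collapse = "\n  "),
           call. = FALSE)
    .icer_pair(strategy, reference, p, incidence, life)
  }, numeric(1))
  data.frame(value = values, icer = ic)
}

#' Default sweep ranges for the tornado diagram
#'
#' Probabilities sweep +/-20% of baseline (clipped to \[0,1\]), costs
#' +/-25%, covering the drivers examined for the stool-DNA strategy:
#' specificity, compliance, polypectomy rate, sensitivity, kit cost and the
#' prevention fraction.
#'
#' @param params baseline bundle.
#' @param strategy strategy whose parameters are swept.
#' @return List of [sweep_spec()] objects.
#' @export
default_tornado_specs <- function(params = default_parameters(),
                                  strategy = "colotect") {
  keyset <- c(paste0(strategy, c(".specificity", ".compliance",
                                 ".sensitivity", ".prevention", ".cost")),
              "procedure.polypectomy_rate")
  lapply(keyset, function(k) {
    base <- get_param(params, k)
    if (grepl("\\.cost$", k)) {
      sweep_spec(k, base * 0.75, base * 1.25)
    } else {
      sweep_spec(k, max(0, base * 0.8), min(1, base * 1.2))
    }
  })
}

#' Tornado analysis
#'
#' Evaluates the ICER at the low and high end of each sweep and orders the
#' entries by descending bar width (the absolute ICER range), the usual
#' tornado-diagram layout. Order is invariant to the input order of specs.
#'
#' @param specs list of [sweep_spec()] objects (>= 1).
#' @inheritParams one_way_sweep
#' @return Data frame: `parameter_key`, `low`, `high`, `icer_at_low`,
#'   `icer_at_high`, `bar_width`, sorted by decreasing `bar_width`.
#' @export
tornado <- function(specs, strategy = "colotect", reference = "none",
                    params = default_parameters(),
                    incidence = gen_incidence(), life = gen_life_table()) {
  if (!length(specs)) stop("need at least one sweep spec", call. = FALSE)
  rows <- lapply(specs, function(sp) {
    stopifnot(inherits(sp, "sweep_spec"))
    at <- function(v) .icer_pair(strategy, reference,
                                 set_param(params, sp$parameter_key, v),
                                 incidence, life)
    lo <- at(sp$low); hi <- at(sp$high)
    data.frame(parameter_key = sp$parameter_key, low = sp$low, high = sp$high,
               icer_at_low = lo, icer_at_high = hi,
               bar_width = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$bar_width, out$parameter_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ICER grid over kit cost and compliance
#'
#' Recomputes the strategy-versus-reference ICER for every combination of
#' kit cost and compliance, holding everything else at baseline. Under the
#' defaults each fixed-cost column is non-increasing in compliance.
#'
#' @param costs kit costs (USD) to evaluate.
#' @param compliance_points compliance probabilities to evaluate.
#' @inheritParams one_way_sweep
#' @param strategy swept strategy (default the stool-DNA test).
#' @return Matrix of ICERs, rows = compliance points, columns = costs.
#' @export
compliance_cost_grid <- function(costs = c(55, 60, 65),
                                 compliance_points = seq(0.5, 1, by = 0.1),
                                 strategy = "colotect", reference = "none",
                                 params = default_parameters(),
                                 incidence = gen_incidence(),
                                 life = gen_life_table()) {
  if (!length(costs) || !length(compliance_points))
    stop("costs and compliance_points must be non-empty", call. = FALSE)
  if (any(compliance_points < 0 | compliance_points > 1))
    stop("compliance_points must lie in [0,1]", call. = FALSE)
  out <- matrix(NA_real_, length(compliance_points), length(costs),
                dimnames = list(format(compliance_points),
                                format(costs)))
  ckey <- paste0(strategy, ".compliance")
  kkey <- paste0(strategy, ".cost")
  for (j in seq_along(costs)) {
    pj <- set_param(params, kkey, costs[j])
    for (i in seq_along(compliance_points)) {
      pij <- set_param(pj, ckey, compliance_points[i])
      out[i, j] <- .icer_pair(strategy, reference, pij, incidence, life)
    }
  }
  out
}

#' Threshold value of a parameter at the willingness-to-pay line
#'
#' Bisection search for the parameter value at which the strategy's ICER
#' versus the reference crosses the WTP threshold; `NA` when the ICER does
#' not cross within the bracket.
#'
#' @param parameter_key dotted configuration key.
#' @param low,high search bracket.
#' @inheritParams one_way_sweep
#' @param wtp threshold in USD per life-year (default [wtp_threshold_usd()]).
#' @param tol bisection tolerance in parameter units.
#' @return The crossing value, or `NA_real_`.
#' @export
wtp_crossing <- function(parameter_key, low, high, strategy = "colotect",
                         reference = "none", params = default_parameters(),
                         incidence = gen_incidence(),
                         life = gen_life_table(),
                         wtp = wtp_threshold_usd(), tol = 1e-4) {
  f <- function(v) .icer_pair(strategy, reference,
                              set_param(params, parameter_key, v),
                              incidence, life) - wtp
  flo <- f(low); fhi <- f(high)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
  while (high - low > tol) {
    mid <- (low + high) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (flo * fm < 0) { high <- mid; fhi <- fm } else { low <- mid; flo <- fm }
  }
  (low + high) / 2
}
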