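## Cost-effectiveness arithmetic: discounting, pairwise comparisons, the
## efficiency frontier with extended dominance, and the willingness-to-pay
## threshold.

#' Discount factor
#'
#' `(1 + rate)^-years_elapsed`; vectorised over `years_elapsed`.
#'
#' @param years_elapsed years since the reference time (>= 0).
#' @param rate annual discount rate (>= 0).
#' @return Numeric factor(s) in (0, 1].
#' @export
discount_factor <- function(years_elapsed, rate) {
  if (any(years_elapsed < 0) || rate < 0)
    stop("years_elapsed and rate must be >= 0", call. = FALSE)
  (1 + rate)^(-years_elapsed)
}

#' Additional cost of a comparator over a reference
#' @param total_cost_comparator,total_cost_reference total discounted USD.
#' @return Comparator minus reference (exact when inputs are integers).
#' @export
additional_cost <- function(total_cost_comparator, total_cost_reference) {
  total_cost_comparator - total_cost_reference
}

#' Incremental cost-effectiveness ratio
#'
#' Additional cost per additional unit of effectiveness (here, per life-year
#' saved). A zero effectiveness difference leaves the ratio undefined: the
#' comparator is neither dominated nor rankable by ICER.
#'
#' @param delta_cost cost difference (USD).
#' @param delta_effect effectiveness difference (life-years); must be
#'   non-zero.
#' @return USD per life-year.
#' @export
icer <- function(delta_cost, delta_effect) {
  if (any(delta_effect == 0))
    stop("ICER undefined for zero effectiveness difference", call. = FALSE)
  delta_cost / delta_effect
}

#' Total cost per life-year saved
#' @param total_cost total discounted cost (USD).
#' @param life_years_saved must be > 0.
#' @return USD per life-year.
#' @export
cost_per_life_year_saved <- function(total_cost, life_years_saved) {
  if (any(life_years_saved <= 0))
    stop("life_years_saved must be > 0", call. = FALSE)
  total_cost / life_years_saved
}

#' Proportion of CRC cases prevented
#' @param cases_reference cases without screening (> 0).
#' @param cases_strategy cases under the strategy.
#' @param digits report precision (default one decimal, as displayed).
#' @return Percentage.
#' @export
proportion_prevented <- function(cases_reference, cases_strategy,
                                 digits = 1) {
  if (any(cases_reference <= 0))
    stop("cases_reference must be > 0", call. = FALSE)
  round(100 * (cases_reference - cases_strategy) / cases_reference, digits)
}

#' Willingness-to-pay threshold in USD
#'
#' One GDP per capita converted from HKD; strategies with an ICER below the
#' threshold are classified highly cost-effective (WHO convention).
#'
#' @param gdp_per_capita_hkd GDP per capita in HKD (> 0).
#' @param hkd_per_usd HKD per USD (> 0).
#' @return Integer USD threshold.
#' @export
#' @examples
#' wtp_threshold_usd(395429, 7.8)  # 50696
wtp_threshold_usd <- function(gdp_per_capita_hkd = 395429,
                              hkd_per_usd = 7.8) {
  if (gdp_per_capita_hkd <= 0 || hkd_per_usd <= 0)
    stop("inputs must be > 0", call. = FALSE)
  as.integer(round(gdp_per_capita_hkd / hkd_per_usd))
}

#' Pairwise comparison table against a reference strategy
#'
#' Life-years saved are the reduction in discounted cancer-related
#' life-years lost relative to the reference (conventionally no screening).
#'
#' @param results list of `strategy_result` objects (must include the
#'   reference).
#' @param reference reference strategy name.
#' @return Data frame: `strategy`, `total_cost`, `life_years_lost`,
#'   `life_years_saved`, `additional_cost`, `icer_vs_reference` (NA for the
#'   reference itself and for zero effect difference).
#' @export
compare_strategies <- function(results, reference = "none") {
  labs <- vapply(results, `[[`, character(1), "strategy")
  if (!reference %in% labs)
    stop(sprintf("reference strategy '%s' not among results", reference),
         call. = FALSE)
  ref <- results[[match(reference, labs)]]
  out <- data.frame(
    strategy = labs,
    total_cost = vapply(results, function(r) r$costs[["total"]], numeric(1)),
    life_years_lost = vapply(results, `[[`, numeric(1), "life_years_lost"),
    stringsAsFactors = FALSE
  )
  out$life_years_saved <- ref$life_years_lost - out$life_years_lost
  out$additional_cost <- additional_cost(out$total_cost, ref$costs[["total"]])
  out$icer_vs_reference <- ifelse(
    out$strategy == reference | out$life_years_saved == 0, NA_real_,
    out$additional_cost / out$life_years_saved)
  out
}

#' All pairwise ICERs
#'
#' @param results list of `strategy_result` objects.
#' @return Square matrix; entry (i, j) is the ICER of strategy j versus
#'   strategy i (NA on the diagonal and for zero effect difference).
#' @export
icer_matrix <- function(results) {
  labs <- vapply(results, `[[`, character(1), "strategy")
  n <- length(results)
  m <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  cost <- vapply(results, function(r) r$costs[["total"]], numeric(1))
  lyl <- vapply(results, `[[`, numeric(1), "life_years_lost")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    de <- lyl[i] - lyl[j] # life-years saved by j over i
    if (de != 0) m[i, j] <- (cost[j] - cost[i]) / de
  }
  m
}

#' Efficiency frontier with strict and extended dominance
#'
#' Entries are ordered by effectiveness. A strategy is strictly dominated
#' when another costs no more and is at least as effective (one strictly;
#' exact ties flag the later entry). Extended dominance is removed
#' iteratively: while incremental ICERs along the candidate frontier are not
#' strictly increasing, the intermediate strategy is dropped.
#'
#' @param x data frame with columns `label`, `cost`, `effect`
#'   (life-years saved); at least two rows, unique labels.
#' @return `x` ordered by effectiveness with logical columns `dominated`,
#'   `extended_dominated`, `on_frontier` and `incremental_icer` (the ICER
#'   versus the previous frontier member; NA off the frontier and for its
#'   first member).
#' @export
#' @examples
#' tab <- data.frame(label = c("none", "fit", "colotect", "colonoscopy"),
#'                   cost = c(224665128, 237692344, 297587292, 434230750),
#'                   effect = c(0, 268, 2236, 2940))
#' efficiency_frontier(tab)
efficiency_frontier <- function(x) {
  stopifnot(is.data.frame(x), all(c("label", "cost", "effect") %in% names(x)))
  if (nrow(x) < 2) stop("need at least two strategies", call. = FALSE)
  if (anyDuplicated(x$label)) stop("duplicate strategy labels", call. = FALSE)
  x <- x[order(x$effect, x$cost), , drop = FALSE]
  n <- nrow(x)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      better <- x$cost[j] <= x$cost[i] && x$effect[j] >= x$effect[i]
      strict <- x$cost[j] < x$cost[i] || x$effect[j] > x$effect[i]
      tie <- !strict && j < i   # identical points: later entry yields
      if (better && (strict || tie)) { dominated[i] <- TRUE; break }
    }
  }
  ext <- logical(n)
  repeat {
    idx <- which(!dominated & !ext)
    if (length(idx) < 3) break
    cost <- x$cost[idx]; eff <- x$effect[idx]
    inc <- diff(cost) / diff(eff)
    bad <- which(diff(inc) <= 0)
    if (!length(bad)) break
    ext[idx[bad[1] + 1]] <- TRUE   # drop the intermediate strategy
  }
  x$dominated <- dominated
  x$extended_dominated <- ext
  x$on_frontier <- !dominated & !ext
  x$incremental_icer <- NA_real_
  idx <- which(x$on_frontier)
  if (length(idx) > 1)
    x$incremental_icer[idx[-1]] <-
      diff(x$cost[idx]) / diff(x$effect[idx])
  rownames(x) <- NULL
  x
}
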