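## Synthetic epidemiological inputs.
##
## The registry incidence curve and the standard life table behind the
## original analysis are not deposited, so the package generates stand-ins
## with the right structure: an exponentially age-increasing CRC incidence
## over 50-75 and a Gompertz-Makeham all-cause life table from which
## remaining life expectancy is computed by survival-product sums.

#' Generate a synthetic age-specific CRC incidence table
#'
#' Rates follow `base_rate_at_50 * exp(log_slope * (age - 50))`, optionally
#' perturbed by seeded multiplicative log-normal jitter, then clipped to
#' \[0, 0.05\] per person-year. `jitter_sd = 0` gives a deterministic curve.
#'
#' Defaults emulate a Hong-Kong-like registry curve: roughly 60 per 100,000
#' at age 50 rising about four-fold by 75.
#'
#' @param base_rate_at_50 incidence per person-year at age 50 (> 0).
#' @param log_slope log-linear increase per year of age.
#' @param seed integer seed for the jitter (ignored when `jitter_sd = 0`).
#' @param jitter_sd standard deviation of the log-normal jitter (>= 0).
#' @param ages integer age grid (default 50:75).
#' @return An `incidence_table`: data.frame with columns `age`, `rate`.
#' @export
#' @examples
#' inc <- gen_incidence()
#' head(inc)
gen_incidence <- function(base_rate_at_50 = 6e-4, log_slope = 0.055,
                          seed = 1L, jitter_sd = 0, ages = 50:75) {
  if (!is.numeric(base_rate_at_50) || base_rate_at_50 <= 0)
    stop("base_rate_at_50 must be > 0", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  rate <- base_rate_at_50 * exp(log_slope * (ages - 50))
  if (jitter_sd > 0) {
    rate <- rate * exp(.with_seed(seed, stats::rnorm(length(ages), 0, jitter_sd)))
  }
  rate <- pmin(pmax(rate, 0), 0.05)
  structure(data.frame(age = as.integer(ages), rate = rate),
            class = c("incidence_table", "data.frame"))
}

#' Generate a synthetic all-cause life table
#'
#' Annual mortality follows the Gompertz-Makeham law
#' `q(a) = min(1, A + B * exp(c * (a - 50)))`; remaining life expectancy is
#' the curtate expectation, i.e. the sum of cumulative survival
#' probabilities from each age up to `closing_age`.
#'
#' Defaults give a high-income-Asia-like schedule (q(50) about 0.002,
#' remaining life expectancy at 50 in the low thirties).
#'
#' @param makeham_a age-independent hazard component (>= 0).
#' @param gompertz_b baseline of the exponential component (>= 0).
#' @param gompertz_c exponential slope per year of age (>= 0).
#' @param start_age,closing_age age range of the table.
#' @return A `life_table`: data.frame with columns `age`, `qx` (annual
#'   mortality probability) and `ex` (remaining life expectancy, years).
#' @export
gen_life_table <- function(makeham_a = 5e-4, gompertz_b = 1.5e-3,
                           gompertz_c = 0.095, start_age = 50L,
                           closing_age = 110L) {
  if (min(makeham_a, gompertz_b, gompertz_c) < 0)
    stop("life-table parameters must be >= 0", call. = FALSE)
  ages <- start_age:closing_age
  qx <- pmin(1, makeham_a + gompertz_b * exp(gompertz_c * (ages - 50)))
  tab <- structure(data.frame(age = as.integer(ages), qx = qx, ex = NA_real_),
                   class = c("life_table", "data.frame"))
  tab$ex <- .life_expectancy_vector(qx)
  tab
}

# Curtate life expectancy for every row given the qx column:
# e_i = sum_{k=1}^{n-i} prod_{j=0}^{k-1} (1 - q_{i+j}); the sum closes at the
# table's last age, so e at the closing age is 0 and a zero-mortality table
# gives closing_age - age exactly.
.life_expectancy_vector <- function(qx) {
  n <- length(qx)
  ex <- numeric(n)
  if (n < 2) return(ex)
  # backward recursion: e_i = (1 - q_i) * (1 + e_{i+1})
  for (i in (n - 1):1) ex[i] <- (1 - qx[i]) * (1 + ex[i + 1])
  ex
}

#' Remaining life expectancy at an age
#'
#' Expected undiscounted future years lived from `age` under the table
#' (curtate expectation, truncated at the table's closing age).
#'
#' @param table a `life_table`.
#' @param age age in years; must be covered by the table.
#' @return Years (numeric scalar, vectorised over `age`).
#' @export
remaining_life_expectancy <- function(table, age) {
  idx <- match(age, table$age)
  if (anyNA(idx))
    stop(sprintf("age %s outside life table range %d-%d",
                 paste(age[is.na(idx)], collapse = ","),
                 min(table$age), max(table$age)), call. = FALSE)
  table$ex[idx]
}

## ---- lookups used by the engine -----------------------------------------

.incidence_at <- function(incidence, age) {
  idx <- match(age, incidence$age)
  if (anyNA(idx))
    stop(sprintf("incidence table does not cover age %s",
                 paste(age[is.na(idx)], collapse = ",")), call. = FALSE)
  incidence$rate[idx]
}

.mortality_at <- function(life, age) {
  idx <- match(age, life$age)
  if (anyNA(idx))
    stop(sprintf("life table does not cover age %s",
                 paste(age[is.na(idx)], collapse = ",")), call. = FALSE)
  life$qx[idx]
}

## ---- delimited-text I/O --------------------------------------------------

#' Read and write incidence / life tables as two-column delimited text
#'
#' Files are tab-separated with a one-line header (`age<TAB>rate` or
#' `age<TAB>qx`). Incidence files may be on a quinquennial grid
#' (ages 50, 55, ...); rates are then expanded to an annual grid by
#' constant-within-band assignment, since the engine cycles annually.
#' Life-table files carry `qx` only; `ex` is recomputed on read.
#'
#' @param path file path.
#' @param ages annual grid the incidence table must cover after expansion.
#' @return `read_incidence_table`: an `incidence_table`;
#'   `read_life_table`: a `life_table`. Writers return `path` invisibly.
#' @name epi_io
NULL

#' @rdname epi_io
#' @export
read_incidence_table <- function(path, ages = 50:75) {
  x <- utils::read.delim(path)
  names(x)[1:2] <- c("age", "rate")
  x <- x[order(x$age), , drop = FALSE]
  if (nrow(x) < length(ages) && all(diff(x$age) == 5)) {
    band <- findInterval(ages, x$age)
    if (any(band == 0)) stop("quinquennial table does not cover requested ages",
                             call. = FALSE)
    x <- data.frame(age = ages, rate = x$rate[band])
  }
  if (!all(ages %in% x$age))
    stop("incidence table does not cover the requested annual ages",
         call. = FALSE)
  x <- x[x$age %in% ages, c("age", "rate")]
  if (any(x$rate < 0 | x$rate > 0.05))
    stop("incidence rates must lie in [0, 0.05]", call. = FALSE)
  structure(data.frame(age = as.integer(x$age), rate = x$rate),
            class = c("incidence_table", "data.frame"))
}

#' @rdname epi_io
#' @param table the table to write.
#' @export
write_incidence_table <- function(table, path) {
  utils::write.table(table[, c("age", "rate")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname epi_io
#' @export
read_life_table <- function(path) {
  x <- utils::read.delim(path)
  names(x)[1:2] <- c("age", "qx")
  x <- x[order(x$age), c("age", "qx")]
  if (any(x$qx < 0 | x$qx > 1))
    stop("life-table mortality must lie in [0,1]", call. = FALSE)
  tab <- structure(data.frame(age = as.integer(x$age), qx = x$qx,
                              ex = NA_real_),
                   class = c("life_table", "data.frame"))
  tab$ex <- .life_expectancy_vector(tab$qx)
  tab
}

#' @rdname epi_io
#' @export
write_life_table <- function(table, path) {
  utils::write.table(table[, c("age", "qx")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
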