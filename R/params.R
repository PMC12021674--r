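#' Default model parameters
#'
#' Returns the full parameter bundle with the published baseline estimates:
#' test performance and compliance, colonoscopy procedure characteristics and
#' complication rates, the stage distribution of colorectal cancer (CRC) at
#' diagnosis with stage-specific annual mortality and care costs, and the
#' cohort/model settings (100,000 persons aged 50--75, annual cycles, 3%
#' discounting, HKD->USD factor 0.13).
#'
#' The bundle is a plain nested list of class `crc_params`:
#' \describe{
#'   \item{`tests`}{one profile per primary modality (`fit`, `colotect`,
#'     `colonoscopy`): `sensitivity`, `specificity`, `compliance`, `cost`
#'     (USD per kit; 0 for colonoscopy, whose cost is procedural),
#'     `prevention` (fraction of CRC prevented among the screen-protected)
#'     and `interval` (years between primary rounds).}
#'   \item{`procedure`}{the colonoscopy procedure: `cost`, `consultation`,
#'     `histopathology` (USD), `polypectomy_rate`, bleeding/perforation rates
#'     and costs, perforation mortality, and `compliance_after_positive`.}
#'   \item{`stages`}{`distribution` over stages I--IV at diagnosis,
#'     `mortality` (annual, per stage), `cost_total` (one-off care cost per
#'     diagnosed case, per stage) and the printed `cost_components` kept for
#'     reference (the stage-IV components do not sum to the authoritative
#'     total).}
#'   \item{`model`}{cohort size, age range, discount rate, surveillance and
#'     post-normal-colonoscopy reset intervals, attendance model
#'     (`independent_per_round`, `once_ever`, `geometric_attrition`), the
#'     screen-detection stage-shift fraction, stage-III cure probability,
#'     cure horizon, closing age for life-table sums, and the RNG seed.}
#' }
#'
#' @return A `crc_params` bundle. Defaults validate cleanly
#'   (`validate_params()` returns an empty character vector).
#' @seealso [load_config()], [set_param()], [validate_params()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$tests$fit$sensitivity     # 0.73
#' p$stages$cost_total[["IV"]] # 45115
default_parameters <- function() {
  p <- list(
    tests = list(
      fit = list(name = "fit", sensitivity = 0.73, specificity = 0.919,
                 compliance = 0.60, cost = 19, prevention = 0.21,
                 interval = 1L),
      colotect = list(name = "colotect", sensitivity = 0.88,
                      specificity = 0.92, compliance = 0.9698, cost = 60,
                      prevention = 0.25, interval = 1L),
      # the paper reports no colonoscopy test accuracy; 0.95/1.00 are
      # field-standard values, used only for the detection-context stage shift
      colonoscopy = list(name = "colonoscopy", sensitivity = 0.95,
                         specificity = 1.0, compliance = 0.989, cost = 0,
                         prevention = 0.54, interval = 10L)
    ),
    procedure = list(
      cost = 1259, consultation = 96, histopathology = 142,
      polypectomy_rate = 0.1405,
      bleeding_basis = "per_colonoscopy",
      bleeding_rate = 0.002,               # calibrated basis (per colonoscopy)
      bleeding_rate_per_polypectomy = 0.0098,
      perforation_rate = 0.0008,           # per colonoscopy
      perforation_mortality = 0.000029,    # per colonoscopy
      bleeding_cost = 3320, perforation_cost = 10790,
      compliance_after_positive = 1.0
    ),
    stages = list(
      distribution = c(I = 0.112, II = 0.245, III = 0.315, IV = 0.328),
      mortality    = c(I = 0.010, II = 0.045, III = 0.087, IV = 0.430),
      cost_total   = c(I = 17071, II = 19755, III = 26883, IV = 45115),
      cost_components = rbind(
        diagnosis = c(I = 6091, II = 6091, III = 6091, IV = 38422),
        treatment = c(I = 10377, II = 13061, III = 20189, IV = 13061),
        follow_up = c(I = 603, II = 603, III = 603, IV = 603)
      )
    ),
    model = list(
      cohort_size = 100000, start_age = 50L, end_age = 75L,
      discount_rate = 0.03, cycle_length = 1L, hkd_to_usd = 0.13,
      surveillance_interval = 3L, post_normal_reset = 10L,
      attendance_model = "independent_per_round", attrition = 0.95,
      stage_shift = 0.5, stage3_cure_rate = 0.70, cure_years = 5L,
      closing_age = 110L, seed = 1L
    )
  )
  class(p) <- "crc_params"
  p
}

## ---- configuration key schema -------------------------------------------

# Each entry: dotted key -> list(path into the bundle, type, range).
# type: "prob", "nonneg", "posint", "enum", "int"
.param_schema <- function() {
  sch <- list()
  for (tn in c("fit", "colotect", "colonoscopy")) {
    sch[[paste0(tn, ".sensitivity")]] <- list(path = c("tests", tn, "sensitivity"), type = "prob")
    sch[[paste0(tn, ".specificity")]] <- list(path = c("tests", tn, "specificity"), type = "prob")
    sch[[paste0(tn, ".compliance")]]  <- list(path = c("tests", tn, "compliance"), type = "prob")
    sch[[paste0(tn, ".cost")]]        <- list(path = c("tests", tn, "cost"), type = "nonneg")
    sch[[paste0(tn, ".prevention")]]  <- list(path = c("tests", tn, "prevention"), type = "prob")
    sch[[paste0(tn, ".interval")]]    <- list(path = c("tests", tn, "interval"), type = "posint")
  }
  proc <- list(cost = "nonneg", consultation = "nonneg",
               histopathology = "nonneg", polypectomy_rate = "prob",
               bleeding_basis = "enum", bleeding_rate = "prob",
               bleeding_rate_per_polypectomy = "prob",
               perforation_rate = "prob", perforation_mortality = "prob",
               bleeding_cost = "nonneg", perforation_cost = "nonneg",
               compliance_after_positive = "prob")
  for (k in names(proc))
    sch[[paste0("procedure.", k)]] <- list(path = c("procedure", k), type = proc[[k]])
  sch[["procedure.bleeding_basis"]]$values <- c("per_colonoscopy", "per_polypectomy")
  stg <- c(I = "i", II = "ii", III = "iii", IV = "iv")
  for (s in names(stg)) {
    sch[[paste0("stage.dist_", stg[[s]])]] <- list(path = c("stages", "distribution", s), type = "prob")
    sch[[paste0("stage.mortality_", stg[[s]])]] <- list(path = c("stages", "mortality", s), type = "prob")
    sch[[paste0("stage.cost_", stg[[s]])]] <- list(path = c("stages", "cost_total", s), type = "nonneg")
  }
  mdl <- list(cohort_size = "nonneg", start_age = "int", end_age = "int",
              discount_rate = "nonneg", hkd_to_usd = "nonneg",
              surveillance_interval = "posint", post_normal_reset = "posint",
              attendance_model = "enum", attrition = "prob",
              stage_shift = "prob", stage3_cure_rate = "prob",
              cure_years = "posint", closing_age = "int", seed = "int")
  for (k in names(mdl))
    sch[[paste0("model.", k)]] <- list(path = c("model", k), type = mdl[[k]])
  sch[["model.attendance_model"]]$values <-
    c("independent_per_round", "once_ever", "geometric_attrition")
  sch
}

.coerce_param <- function(key, value, entry) {
  if (entry$type == "enum") {
    value <- as.character(value)
    if (!value %in% entry$values)
      stop(sprintf("config key '%s': value '%s' not one of {%s}", key, value,
                   paste(entry$values, collapse = ", ")), call. = FALSE)
    return(value)
  }
  num <- suppressWarnings(as.numeric(value))
  if (is.na(num))
    stop(sprintf("config key '%s': value '%s' is not numeric", key, value),
         call. = FALSE)
  ok <- switch(entry$type,
    prob   = num >= 0 && num <= 1,
    nonneg = num >= 0,
    posint = num >= 1 && num == round(num),
    int    = num == round(num),
    TRUE)
  if (!ok)
    stop(sprintf("config key '%s': value %s out of range for type '%s'",
                 key, format(num), entry$type), call. = FALSE)
  if (entry$type %in% c("posint", "int")) num <- as.integer(num)
  num
}

#' Set one parameter by its dotted configuration key
#'
#' @param params a `crc_params` bundle.
#' @param key dotted key, e.g. `"colotect.compliance"` or
#'   `"procedure.polypectomy_rate"` (the same schema [load_config()] reads).
#' @param value new value; range-checked against the key's declared type.
#' @return The modified bundle.
#' @export
set_param <- function(params, key, value) {
  sch <- .param_schema()
  entry <- sch[[key]]
  if (is.null(entry))
    stop(sprintf("unknown config key '%s'", key), call. = FALSE)
  value <- .coerce_param(key, value, entry)
  params[[entry$path]] <- value
  params
}

#' Get one parameter by its dotted configuration key
#' @inheritParams set_param
#' @return The current value.
#' @export
get_param <- function(params, key) {
  entry <- .param_schema()[[key]]
  if (is.null(entry)) stop(sprintf("unknown config key '%s'", key), call. = FALSE)
  params[[entry$path]]
}

#' Configuration keys understood by `load_config()` / `set_param()`
#' @return Character vector of dotted keys.
#' @export
param_keys <- function() names(.param_schema())

#' Load a configuration file over the defaults
#'
#' Reads a plain-text configuration of `key: value` lines (`#` starts a
#' comment; blank lines ignored) and applies each key over
#' [default_parameters()]. Unknown keys and out-of-range values are rejected
#' with an error naming the offending key. An empty file yields the defaults.
#'
#' @param path file path.
#' @param base bundle the file overrides (default [default_parameters()]).
#' @return A validated `crc_params` bundle.
#' @export
load_config <- function(path, base = default_parameters()) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  p <- base
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.+)$", ln))[[1]]
    if (length(m) != 3)
      stop(sprintf("cannot parse config line: '%s'", ln), call. = FALSE)
    p <- set_param(p, m[[2]], trimws(m[[3]]))
  }
  v <- validate_params(p)
  if (length(v))
    stop(paste(c("invalid configuration:", v), collapse = "\n  "),
         call. = FALSE)
  p
}

#' Save a configuration file
#'
#' Writes every schema key with its current value; [load_config()] on the
#' result round-trips the bundle exactly.
#'
#' @inheritParams set_param
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  sch <- .param_schema()
  vals <- vapply(names(sch), function(k) {
    v <- params[[sch[[k]]$path]]
    if (is.character(v)) v else format(v, digits = 17, scientific = FALSE)
  }, character(1))
  writeLines(paste0(names(sch), ": ", vals), path)
  invisible(path)
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant: probabilities in \[0,1\], costs
#' non-negative, intervals >= 1, the stage distribution summing to one
#' (within 1e-9), stage mortality non-decreasing from I to IV, perforation
#' mortality not exceeding the perforation rate, and `start_age < end_age`.
#' Violations are returned, not raised.
#'
#' @param params a `crc_params` bundle.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_params <- function(params) {
  v <- character(0)
  note <- function(msg) v <<- c(v, msg)
  chk_prob <- function(x, what) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
      note(sprintf("%s must be a probability in [0,1] (got %s)",
                   what, paste(format(x), collapse = ",")))
  }
  chk_nonneg <- function(x, what) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
      note(sprintf("%s must be >= 0 (got %s)", what,
                   paste(format(x), collapse = ",")))
  }
  for (tn in names(params$tests)) {
    t <- params$tests[[tn]]
    for (f in c("sensitivity", "specificity", "compliance", "prevention"))
      chk_prob(t[[f]], paste0(tn, ".", f))
    chk_nonneg(t$cost, paste0(tn, ".cost"))
    if (!is.numeric(t$interval) || t$interval < 1)
      note(sprintf("%s.interval must be >= 1", tn))
  }
  pr <- params$procedure
  for (f in c("polypectomy_rate", "bleeding_rate",
              "bleeding_rate_per_polypectomy", "perforation_rate",
              "perforation_mortality", "compliance_after_positive"))
    chk_prob(pr[[f]], paste0("procedure.", f))
  for (f in c("cost", "consultation", "histopathology", "bleeding_cost",
              "perforation_cost"))
    chk_nonneg(pr[[f]], paste0("procedure.", f))
  if (is.numeric(pr$perforation_mortality) && is.numeric(pr$perforation_rate) &&
      pr$perforation_mortality > pr$perforation_rate)
    note("procedure.perforation_mortality exceeds procedure.perforation_rate")
  if (!pr$bleeding_basis %in% c("per_colonoscopy", "per_polypectomy"))
    note("procedure.bleeding_basis must be per_colonoscopy or per_polypectomy")
  st <- params$stages
  chk_prob(st$distribution, "stage distribution")
  if (is.numeric(st$distribution) && abs(sum(st$distribution) - 1) > 1e-9)
    note(sprintf("stage distribution sums to %.10f, not 1", sum(st$distribution)))
  chk_prob(st$mortality, "stage mortality")
  if (is.numeric(st$mortality) && is.unsorted(st$mortality))
    note("stage mortality must be non-decreasing from stage I to IV")
  chk_nonneg(st$cost_total, "stage care cost")
  m <- params$model
  if (!(m$start_age < m$end_age)) note("model.start_age must be < model.end_age")
  chk_nonneg(m$discount_rate, "model.discount_rate")
  if (!(m$cohort_size > 0)) note("model.cohort_size must be > 0")
  chk_prob(m$stage_shift, "model.stage_shift")
  chk_prob(m$stage3_cure_rate, "model.stage3_cure_rate")
  if (m$closing_age <= m$end_age) note("model.closing_age must exceed model.end_age")
  v
}

#' @export
print.crc_params <- function(x, ...) {
  cat("<crc_params> screening cost-effectiveness parameter bundle\n")
  for (tn in names(x$tests)) {
    t <- x$tests[[tn]]
    cat(sprintf("  %-11s sens %.3f spec %.3f compl %.4f cost %g prevention %.2f every %dy\n",
                t$name, t$sensitivity, t$specificity, t$compliance, t$cost,
                t$prevention, t$interval))
  }
  cat(sprintf("  colonoscopy procedure: %g USD (+%g consult), polypectomy %.2f%%\n",
              x$procedure$cost, x$procedure$consultation,
              100 * x$procedure$polypectomy_rate))
  cat(sprintf("  cohort %s aged %d-%d, discount %.0f%%\n",
              format(x$model$cohort_size, big.mark = ","),
              x$model$start_age, x$model$end_age,
              100 * x$model$discount_rate))
  invisible(x)
}
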