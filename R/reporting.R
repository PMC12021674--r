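## Result rendering in the published table layout, run orchestration,
## manifests, and the command-line interface.

# half-up rounding for count display (base round() is half-to-even)
.round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Run several strategies on shared inputs
#'
#' @param strategies character vector of strategy names.
#' @param params parameter bundle.
#' @param incidence,life model inputs.
#' @return Named list of `strategy_result` objects.
#' @export
run_strategies <- function(strategies = strategy_names(),
                           params = default_parameters(),
                           incidence = gen_incidence(),
                           life = gen_life_table()) {
  res <- lapply(strategies, run_cohort, params = params,
                incidence = incidence, life = life)
  names(res) <- strategies
  res
}

#' Render results in the published summary-table layout
#'
#' One column per strategy, rows in the canonical order: case and life-year
#' outcomes, procedure counts, complication counts, the discounted cost
#' ledger, and the cost-effectiveness summary versus the reference. Counts
#' are rounded half-up to integers, currency to whole USD, proportions to
#' one decimal.
#'
#' @param results named list of `strategy_result` objects.
#' @param reference reference strategy for the comparison rows (must be in
#'   `results`; the reference column shows an em-dash for ratio rows).
#' @return Data frame with a `row` label column and one character column
#'   per strategy. Deterministic for identical inputs.
#' @export
render_table3 <- function(results, reference = "none") {
  labs <- vapply(results, `[[`, character(1), "strategy")
  names(results) <- labs
  has_ref <- reference %in% labs
  ref <- if (has_ref) results[[reference]] else NULL

  num <- function(f) vapply(results, f, numeric(1))
  cases <- num(function(r) r$cases_total)
  lyl <- num(function(r) r$life_years_lost)
  total_cost <- num(function(r) r$costs[["total"]])
  prevented <- if (has_ref) ref$cases_total - cases else rep(NA, length(labs))
  lys <- if (has_ref) ref$life_years_lost - lyl else rep(NA, length(labs))

  int_row <- function(x) format(.round_half_up(x), scientific = FALSE,
                                trim = TRUE)
  usd_row <- int_row
  pct_row <- function(x) sprintf("%.1f%%", .round_half_up(x, 1))
  dash_if_ref <- function(x) {
    out <- ifelse(is.finite(x), int_row(ifelse(is.finite(x), x, 0)), "-")
    if (has_ref) out[labs == reference] <- "-"
    out
  }

  kit_tests <- function(r, name)
    if (r$strategy == name) r$tests_used else 0
  kit_cost <- function(r, name)
    if (r$strategy == name) r$costs[["kit"]] else 0
  colo_proc_cost <- num(function(r) r$costs[["colonoscopy"]])

  rows <- list(
    c("Total number CRC cases", int_row(cases)),
    c("Total loss of cancer-related life years", int_row(lyl)),
    c("Cases of CRC prevented (compared with no screening)",
      int_row(prevented)),
    c("Proportion of CRC case prevented (%)",
      pct_row(100 * prevented / if (has_ref) ref$cases_total else NA)),
    c("Life-years saved", int_row(lys)),
    c("Number of procedures", rep("", length(labs))),
    c("  FIT", int_row(num(function(r) kit_tests(r, "fit")))),
    c("  COLOTECT", int_row(num(function(r) kit_tests(r, "colotect")))),
    c("  Colonoscopy", int_row(num(function(r) r$colonoscopies$total))),
    c("  Diagnostic (without polypectomy)",
      int_row(num(function(r) r$colonoscopies$diagnostic))),
    c("  Therapeutic (with polypectomy)",
      int_row(num(function(r) r$colonoscopies$therapeutic))),
    c("Number of complications", rep("", length(labs))),
    c("  Bleeding", int_row(num(function(r) r$complications$bleeds))),
    c("  Perforations",
      int_row(num(function(r) r$complications$perforations))),
    c("Costs (USD)", rep("", length(labs))),
    c("  FIT", usd_row(num(function(r) kit_cost(r, "fit")))),
    c("  COLOTECT", usd_row(num(function(r) kit_cost(r, "colotect")))),
    c("  Colonoscopy", usd_row(colo_proc_cost)),
    c("  Polypectomy", usd_row(num(function(r) r$costs[["polypectomy"]]))),
    c("  Bleeding", usd_row(num(function(r) r$costs[["bleeding"]]))),
    c("  Perforations", usd_row(num(function(r) r$costs[["perforation"]]))),
    c("Care of CRC", rep("", length(labs))),
    c("  Stage I", usd_row(num(function(r) r$costs[["care_I"]]))),
    c("  Stage II", usd_row(num(function(r) r$costs[["care_II"]]))),
    c("  Stage III", usd_row(num(function(r) r$costs[["care_III"]]))),
    c("  Stage IV", usd_row(num(function(r) r$costs[["care_IV"]]))),
    c("  Total", usd_row(total_cost)),
    c("Total costs per life-years saved",
      dash_if_ref(total_cost / ifelse(lys > 0, lys, NA))),
    c("Additional cost",
      dash_if_ref(if (has_ref) total_cost - ref$costs[["total"]]
                  else rep(NA, length(labs)))),
    c("ICER versus no screening",
      dash_if_ref(ifelse(lys > 0,
                         (total_cost - if (has_ref) ref$costs[["total"]] else NA) /
                           ifelse(lys > 0, lys, NA), NA)))
  )
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- c("row", labs)
  tab
}

#' Write a reproducibility manifest
#'
#' Records everything needed to reproduce a run: strategies, configuration
#' source, input provenance (file paths or synthetic generation with its
#' seed), output directory, timestamp, and package version.
#'
#' @param path output file.
#' @param fields named list of manifest fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, fields) {
  fields$package_version <-
    as.character(utils::packageVersion("crcscreen"))
  writeLines(paste0(names(fields), ": ",
                    vapply(fields, function(v) paste(v, collapse = ","),
                           character(1))), path)
  invisible(path)
}

.cli_usage <- function() {
  paste(
    "usage: crcscreen <command> [options]",
    "",
    "commands:",
    "  run          run strategies; write result table, comparisons, frontier",
    "  sensitivity  tornado table and compliance-by-cost ICER grid",
    "  frontier     efficiency frontier only",
    "  synth        write synthetic incidence and life tables",
    "",
    "options:",
    "  --strategies a,b,c   (default: none,fit,colotect,colonoscopy)",
    "  --config PATH        key:value configuration overriding defaults",
    "  --incidence PATH     incidence table (default: synthetic)",
    "  --life PATH          life table (default: synthetic)",
    "  --seed N             seed for all randomness (default 1)",
    "  --out DIR            output directory (default '.')",
    sep = "\n")
}

.cli_parse <- function(args) {
  opts <- list(strategies = strategy_names(), config = NULL,
               incidence = NULL, life = NULL, seed = 1L, out = ".")
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    key <- substring(a, 3)
    if (i == length(args)) stop(sprintf("missing value for --%s", key),
                                call. = FALSE)
    val <- args[[i + 1]]
    i <- i + 2
    switch(key,
      strategies = { opts$strategies <- strsplit(val, ",")[[1]] },
      config = { opts$config <- val },
      incidence = { opts$incidence <- val },
      life = { opts$life <- val },
      seed = { opts$seed <- as.integer(val) },
      out = { opts$out <- val },
      stop(sprintf("unknown option --%s", key), call. = FALSE))
  }
  bad <- setdiff(opts$strategies, strategy_names())
  if (length(bad))
    stop(sprintf("unknown strategy: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  opts
}

.cli_inputs <- function(opts) {
  params <- if (is.null(opts$config)) default_parameters()
            else load_config(opts$config)
  incidence <- if (is.null(opts$incidence)) gen_incidence(seed = opts$seed)
               else read_incidence_table(opts$incidence)
  life <- if (is.null(opts$life)) gen_life_table()
          else read_life_table(opts$life)
  list(params = params, incidence = incidence, life = life)
}

#' Command-line entry point
#'
#' Subcommands: `run`, `sensitivity`, `frontier`, `synth` (see the usage
#' text printed on error). All outputs are comma-delimited text plus a
#' plain-text manifest; every source of randomness flows from `--seed`.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (0 on success).
#' @export
crc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop(.cli_usage(), call. = FALSE)
    cmd <- args[[1]]
    opts <- .cli_parse(args[-1])
    dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
    outfile <- function(f) file.path(opts$out, f)
    manifest <- list(command = cmd, strategies = opts$strategies,
                     config = if (is.null(opts$config)) "(defaults)" else opts$config,
                     incidence = if (is.null(opts$incidence))
                       paste0("synthetic(seed=", opts$seed, ")") else opts$incidence,
                     life = if (is.null(opts$life)) "synthetic" else opts$life,
                     seed = opts$seed, out = opts$out,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

    if (cmd == "synth") {
      inc <- gen_incidence(seed = opts$seed)
      lt <- gen_life_table()
      write_incidence_table(inc, outfile("incidence.tsv"))
      write_life_table(lt, outfile("lifetable.tsv"))
    } else if (cmd %in% c("run", "frontier")) {
      inp <- .cli_inputs(opts)
      res <- run_strategies(opts$strategies, inp$params, inp$incidence,
                            inp$life)
      cmp <- compare_strategies(res,
        reference = if ("none" %in% opts$strategies) "none"
                    else opts$strategies[[1]])
      fr <- efficiency_frontier(data.frame(
        label = cmp$strategy, cost = cmp$total_cost,
        effect = cmp$life_years_saved))
      if (cmd == "run") {
        utils::write.csv(render_table3(res), outfile("results.csv"),
                         row.names = FALSE)
        utils::write.csv(cmp, outfile("comparison.csv"), row.names = FALSE)
        im <- icer_matrix(res)
        utils::write.csv(cbind(strategy = rownames(im), as.data.frame(im)),
                         outfile("icer_matrix.csv"), row.names = FALSE)
      }
      utils::write.csv(fr, outfile("frontier.csv"), row.names = FALSE)
    } else if (cmd == "sensitivity") {
      inp <- .cli_inputs(opts)
      specs <- default_tornado_specs(inp$params)
      tor <- tornado(specs, params = inp$params, incidence = inp$incidence,
                     life = inp$life)
      utils::write.csv(tor, outfile("tornado.csv"), row.names = FALSE)
      grid <- compliance_cost_grid(params = inp$params,
                                   incidence = inp$incidence,
                                   life = inp$life)
      utils::write.csv(cbind(compliance = rownames(grid),
                             as.data.frame(grid)),
                       outfile("compliance_cost_grid.csv"),
                       row.names = FALSE)
    } else {
      stop(paste0("unknown command '", cmd, "'\n", .cli_usage()),
           call. = FALSE)
    }
    write_manifest(outfile("manifest.txt"), manifest)
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}
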