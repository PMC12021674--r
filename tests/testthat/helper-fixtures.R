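# Shared fixtures and independent oracles, built in code at test time.

# default synthetic inputs (deterministic)
fx_inc <- function() gen_incidence()
fx_life <- function() gen_life_table()

# memoised default-parameter cohort runs, shared across test files
.fx_cache <- new.env(parent = emptyenv())
fx_run <- function(strategy) {
  key <- paste0("run_", strategy)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- run_cohort(strategy, default_parameters(),
                                   fx_inc(), fx_life())
  .fx_cache[[key]]
}

# brute-force survival-product life expectancy (independent of the
# backward-recursion implementation)
oracle_life_expectancy <- function(qx_vec, i) {
  n <- length(qx_vec)
  total <- 0
  for (k in 1:(n - i)) {
    total <- total + prod(1 - qx_vec[i:(i + k - 1)])
  }
  total
}

# greedy lowest-incremental-ICER frontier construction: the classic CEA
# algorithm (ascend from the least costly strategy, always taking the
# lowest-ICER step), an independent route to the iterative-removal frontier
oracle_frontier_labels <- function(x) {
  x <- x[order(x$cost, x$effect), , drop = FALSE]
  chain <- 1L
  repeat {
    cur <- chain[length(chain)]
    cand <- which(x$effect > x$effect[cur] & x$cost > x$cost[cur])
    # points at least as effective but no costlier dominate cur and would
    # have been picked earlier; with continuous random inputs ties are null
    if (!length(cand)) break
    ic <- (x$cost[cand] - x$cost[cur]) / (x$effect[cand] - x$effect[cur])
    chain <- c(chain, cand[which.min(ic)])
  }
  x$label[chain]
}
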