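#' @importFrom stats rnorm rlnorm runif rbeta rgamma sd quantile median
#' @importFrom stats kruskal.test pt p.adjust glm predict binomial coef lm.fit
#' @importFrom stats .lm.fit qnorm dnorm pnorm setNames complete.cases
#' @importFrom utils head tail combn
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

# Internal logging: quiet by default, switchable for pipeline runs.
mf_log <- function(..., verbose = getOption("mobflow.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[mobflow] ", sprintf(...))
  invisible(NULL)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Deterministic integer split of a vector of totals across nb equal bins:
# bin b (1-based) of total F receives F %/% nb + (b <= F %% nb).
split_integer <- function(totals, nb) {
  base <- totals %/% nb
  rem <- totals %% nb
  list(base = base, rem = rem)
}
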