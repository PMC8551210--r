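#' Relative variation in nodal efficiency against a baseline window
#'
#' For each territory i and window t computes
#' \deqn{\Delta e_i^t = (e_{i,t} - e_{i,t_0}) / e_{i,t_0},}
#' where the baseline `t0` is the pre-disruption window. Territories with zero
#' baseline efficiency cannot be normalized and are masked invalid (their
#' count is logged). Values are kept as raw ratios; multiply by 100 for a
#' percentage display.
#'
#' @param nodal per-window nodal efficiency table (`window`, `llm_id` and the
#'   chosen efficiency column), e.g. `efficiency_series(...)$nodal`.
#' @param t0 baseline window index.
#' @param variant which nodal efficiency drives the indicator: the
#'   window-normalized `"norm"` (default) or the raw `"raw"` value.
#' @return An object of class `disruption_series`: list with `delta` (a
#'   territories x windows matrix of \eqn{\Delta e}), `t0`, `variant`, and
#'   `valid` (named logical mask of territories with positive baseline).
#' @export
relative_variation <- function(nodal, t0 = 0L, variant = c("norm", "raw")) {
  variant <- match.arg(variant)
  col <- if (variant == "norm") "e_norm" else "e_raw"
  nodal <- data.table::as.data.table(nodal)
  stopifnot(all(c("window", "llm_id", col) %in% names(nodal)))
  if (!t0 %in% nodal$window) stop("baseline window ", t0, " not present")
  E <- data.table::dcast(nodal, llm_id ~ window, value.var = col)
  ids <- E$llm_id
  M <- as.matrix(E[, -1])
  rownames(M) <- ids
  wcols <- as.integer(colnames(M))
  base <- M[, which(wcols == t0)]
  valid <- is.finite(base) & base > 0
  n_invalid <- sum(!valid)
  if (n_invalid > 0) {
    mf_log("relative_variation: %d territories masked (zero baseline efficiency)",
           n_invalid)
  }
  delta <- sweep(M, 1, base, `-`) / base
  delta[!valid, ] <- NA_real_
  structure(list(delta = delta, t0 = as.integer(t0), variant = variant,
                 valid = stats::setNames(valid, ids)),
            class = "disruption_series")
}

#' @export
print.disruption_series <- function(x, ...) {
  cat(sprintf(paste0("<disruption_series> %d territories x %d windows ",
                     "(baseline %d, %s efficiency, %d invalid)\n"),
              nrow(x$delta), ncol(x$delta), x$t0, x$variant, sum(!x$valid)))
  invisible(x)
}

#' Lockdown and recovery performance indicators
#'
#' The lockdown indicator is the mean relative variation over the first two
#' windows of the lockdown phase, and the recovery indicator the mean over
#' the first two windows after restrictions are lifted:
#' \deqn{\Delta e_i^{lockdown} = (\Delta e_i^{t_L} + \Delta e_i^{t_L+1})/2,
#'       \qquad
#'       \Delta e_i^{recovery} = (\Delta e_i^{t_R} + \Delta e_i^{t_R+1})/2.}
#' On the default study grid anchored at 2020-02-24 the lockdown starts in
#' window 1 (8/3-21/3) and is lifted in window 5 (4/5-17/5).
#'
#' @param series a `disruption_series`.
#' @param t_L first lockdown window index.
#' @param t_R first post-lockdown window index.
#' @return data.table with `llm_id`, `lockdown`, `recovery` (valid
#'   territories only), with `t_L`/`t_R` attached as attributes.
#' @export
compute_indicators <- function(series, t_L = 1L, t_R = 5L) {
  stopifnot(inherits(series, "disruption_series"))
  wcols <- as.integer(colnames(series$delta))
  need <- c(t_L, t_L + 1L, t_R, t_R + 1L)
  if (!all(need %in% wcols)) {
    stop_config("indicator windows %s outside the available range %d..%d",
                paste(need, collapse = ","), min(wcols), max(wcols))
  }
  pick <- function(w) series$delta[, which(wcols == w)]
  out <- data.table::data.table(
    llm_id = rownames(series$delta),
    lockdown = (pick(t_L) + pick(t_L + 1L)) / 2,
    recovery = (pick(t_R) + pick(t_R + 1L)) / 2)
  out <- out[series$valid[out$llm_id]]
  data.table::setattr(out, "t_L", as.integer(t_L))
  data.table::setattr(out, "t_R", as.integer(t_R))
  out[]
}

#' Extract the most and least affected classes from an indicator
#'
#' The most affected territories are the bottom K% of the indicator
#' distribution, the least affected the top K%; everything else is "rest".
#' Class sizes are `round(K/100 * N)`. Ties are broken deterministically by
#' (indicator value, territory id) lexical order.
#'
#' @param indicator data.table with `llm_id` and the indicator column, or a
#'   named numeric vector.
#' @param K tail percentage, in (0, 50].
#' @param indicator_col column name when `indicator` is a table.
#' @return data.table with `llm_id`, `label` in most/least/rest, and
#'   attributes `K` and `indicator_used`.
#' @export
extract_classes <- function(indicator, K = 30, indicator_col = "lockdown") {
  if (K <= 0 || K > 50) stop_config("K must be in (0, 50], got %g", K)
  if (is.data.frame(indicator)) {
    vals <- indicator[[indicator_col]]
    ids <- indicator$llm_id
  } else {
    vals <- as.numeric(indicator)
    ids <- names(indicator)
    indicator_col <- "indicator"
  }
  ok <- is.finite(vals)
  vals <- vals[ok]; ids <- ids[ok]
  N <- length(vals)
  n_tail <- round(K / 100 * N)
  ord <- order(vals, ids) # ascending; deterministic tie-break by id
  label <- rep("rest", N)
  label[ord[seq_len(n_tail)]] <- "most"
  label[ord[N - seq_len(n_tail) + 1L]] <- "least"
  out <- data.table::data.table(llm_id = ids, label = label)
  data.table::setattr(out, "K", K)
  data.table::setattr(out, "indicator_used", indicator_col)
  out[]
}

#' Per-class mean disruption trajectories with 95% confidence bands
#'
#' Cross-sectional mean of \eqn{\Delta e} per class and window with a normal
#' 95% confidence interval (mean +/- 1.96 SE). Classes with a single valid
#' member get an undefined (NA) interval and are flagged.
#'
#' @param series a `disruption_series`.
#' @param labels class labels from [extract_classes()] (or any table with
#'   `llm_id`, `label`).
#' @return data.table with `label`, `window`, `n`, `mean`, `se`, `ci_low`,
#'   `ci_high`, `singleton`.
#' @export
class_recovery_curves <- function(series, labels) {
  stopifnot(inherits(series, "disruption_series"))
  labels <- data.table::as.data.table(labels)
  delta <- series$delta[labels$llm_id[labels$llm_id %in% rownames(series$delta)], ,
                        drop = FALSE]
  lab <- labels$label[match(rownames(delta), labels$llm_id)]
  wcols <- as.integer(colnames(delta))
  out <- data.table::rbindlist(lapply(split(seq_len(nrow(delta)), lab), function(ix) {
    sub <- delta[ix, , drop = FALSE]
    n <- colSums(is.finite(sub))
    m <- colMeans(sub, na.rm = TRUE)
    s <- apply(sub, 2, stats::sd, na.rm = TRUE)
    se <- s / sqrt(pmax(n, 1))
    se[n < 2] <- NA_real_
    data.table::data.table(label = lab[ix[1]], window = wcols, n = n, mean = m,
                           se = se, ci_low = m - 1.96 * se,
                           ci_high = m + 1.96 * se, singleton = n < 2)
  }))
  if (any(out$singleton)) mf_log("class_recovery_curves: singleton class-window cells flagged")
  out[]
}
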