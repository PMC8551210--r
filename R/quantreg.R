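#' Check (pinball) loss
#'
#' \deqn{\rho_\tau(r) = r(\tau - 1\{r < 0\})}, the loss whose minimizer over
#' a location parameter is the \eqn{\tau}-th sample quantile.
#'
#' @param r residuals.
#' @param tau quantile level in (0, 1).
#' @return Total check loss.
#' @export
check_loss <- function(r, tau) {
  sum(r * (tau - (r < 0)))
}

# One quantile fit by iteratively reweighted least squares with an annealed
# smoothing floor on |r|, followed (for small column counts) by an exact
# vertex polish: a basic optimum interpolates p observations, so the p-subsets
# of the smallest-|residual| observations near the IWLS solution are solved
# exactly and the best check-loss solution kept.
fit_one_tau <- function(X, y, tau, b0 = NULL, polish = TRUE,
                        eps_seq = 10^seq(-3, -11, by = -2), max_iter = 60L) {
  p <- ncol(X)
  n <- nrow(X)
  if (is.null(b0)) {
    qf <- qr(X)
    b <- qr.coef(qf, y)
    b[is.na(b)] <- 0
  } else {
    b <- b0
  }
  for (eps in eps_seq) {
    for (it in seq_len(max_iter)) {
      r <- y - as.numeric(X %*% b)
      w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), eps)
      sw <- sqrt(w)
      fit <- .lm.fit(X * sw, y * sw)
      b_new <- fit$coefficients
      if (any(!is.finite(b_new))) break
      if (max(abs(b_new - b)) < 1e-11 * (1 + max(abs(b)))) {
        b <- b_new
        break
      }
      b <- b_new
    }
  }
  loss <- check_loss(y - as.numeric(X %*% b), tau)

  if (polish) {
    r <- y - as.numeric(X %*% b)
    m <- min(n, max(2L * p, p + 4L))
    if (choose(m, p) <= 3000) {
      cand <- order(abs(r))[seq_len(m)]
      subsets <- utils::combn(cand, p)
      for (ci in seq_len(ncol(subsets))) {
        ix <- subsets[, ci]
        Xi <- X[ix, , drop = FALSE]
        if (abs(det(Xi)) < 1e-12) next
        bb <- tryCatch(solve(Xi, y[ix]), error = function(e) NULL)
        if (is.null(bb) || any(!is.finite(bb))) next
        ll <- check_loss(y - as.numeric(X %*% bb), tau)
        if (ll < loss - 1e-12 * (1 + abs(loss))) {
          loss <- ll
          b <- bb
        }
      }
    }
  }
  list(coefficients = as.numeric(b), loss = loss)
}

# fast warm-started IWLS refit (normal equations, single smoothing floor);
# used for bootstrap replications where the start value is already near the
# replication's optimum and full annealing would be wasted
iwls_refit <- function(X, y, tau, b0, eps_seq = c(1e-4, 1e-6, 1e-8),
                       max_iter = 15L, tol = 1e-8) {
  b <- b0
  for (eps in eps_seq) {
    b_stage <- b
    for (it in seq_len(max_iter)) {
      r <- y - as.numeric(X %*% b)
      w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), eps)
      Xw <- X * w
      b_new <- tryCatch(solve(crossprod(X, Xw), crossprod(Xw, y)),
                        error = function(e) NULL)
      if (is.null(b_new)) return(NULL)
      b_new <- as.numeric(b_new)
      if (any(!is.finite(b_new))) return(NULL)
      conv <- max(abs(b_new - b)) < tol * (1 + max(abs(b)))
      b <- b_new
      if (conv) break
    }
    # a later (smaller) smoothing floor cannot move a solution this stage
    # already left unchanged
    if (max(abs(b - b_stage)) < tol * (1 + max(abs(b)))) break
  }
  b
}

# iid-error asymptotic covariance with Hall-Sheather sparsity bandwidth
asymptotic_se <- function(X, resid, tau) {
  n <- nrow(X)
  z <- stats::qnorm(tau)
  h <- n^(-1 / 3) * stats::qnorm(0.975)^(2 / 3) *
    ((1.5 * stats::dnorm(z)^2) / (2 * z^2 + 1))^(1 / 3)
  lo <- max(tau - h, 1e-4)
  hi <- min(tau + h, 1 - 1e-4)
  s <- (stats::quantile(resid, hi, names = FALSE) -
          stats::quantile(resid, lo, names = FALSE)) / (hi - lo)
  s <- max(s, .Machine$double.eps)
  V <- tau * (1 - tau) * s^2 * solve(crossprod(X))
  sqrt(diag(V))
}

#' Build the quantile-regression design matrix
#'
#' Assembles the design for the disruption-indicator regression: an
#' intercept; six aggregate socioeconomic covariates (income per capita,
#' inequality, density, revenue concentration, essential and remote worker
#' shares); 16 per-sector employee columns; 16 per-sector
#' revenue-per-employee columns; macroarea dummies against a reference area;
#' and the interactions between each dummy and the revenue-per-employee of
#' four designated sectors. With 16 sectors and 5 macroareas this is 59
#' columns including the intercept. Covariates come in standardized; the
#' response is standardized by default.
#'
#' @param features_std standardized feature table (see
#'   [standardize_features()]).
#' @param indicator data.table with `llm_id` and the indicator column.
#' @param indicator_col which indicator column to use.
#' @param interaction_sectors four sector ids whose revenue-per-employee
#'   columns interact with the macroarea dummies.
#' @param reference_area macroarea level absorbed by the intercept.
#' @param standardize_response center/scale the response to mean 0, SD 1.
#' @return An object of class `design_matrix`: list with `X` (matrix with
#'   column names), `y`, `llm_id`, `response_scale` (center/scale used, if
#'   any) and block bookkeeping.
#' @export
build_design <- function(features_std, indicator, indicator_col = "lockdown",
                         interaction_sectors = NULL,
                         reference_area = "north_west",
                         standardize_response = TRUE) {
  sectors <- attr(features_std, "sectors") %||%
    sub("^emp_", "", grep("^emp_", names(features_std), value = TRUE))
  if (is.null(interaction_sectors)) {
    interaction_sectors <- head(sectors, 4L)
  }
  bad <- setdiff(interaction_sectors, sectors)
  if (length(bad)) stop_config("interaction sectors not in the sector set: %s",
                               paste(bad, collapse = ", "))
  dt <- merge(data.table::as.data.table(indicator)[,
                c("llm_id", indicator_col), with = FALSE],
              features_std, by = "llm_id")
  y <- dt[[indicator_col]]
  response_scale <- NULL
  if (standardize_response) {
    response_scale <- c(center = mean(y), scale = stats::sd(y))
    y <- (y - response_scale[["center"]]) / response_scale[["scale"]]
  }
  x_cols <- c("income_per_capita", "inequality", "density",
              "revenue_concentration", "essential_share", "remote_share")
  l_cols <- paste0("emp_", sectors)
  r_cols <- paste0("rpe_", sectors)
  Xmain <- as.matrix(dt[, c(x_cols, l_cols, r_cols), with = FALSE])

  areas <- sort(unique(dt$macroarea))
  if (!reference_area %in% areas) {
    stop_config("reference area '%s' not among macroareas (%s)",
                reference_area, paste(areas, collapse = ", "))
  }
  other <- setdiff(areas, reference_area)
  Z <- sapply(other, function(a) as.numeric(dt$macroarea == a))
  colnames(Z) <- paste0("area_", other)
  ZR <- do.call(cbind, lapply(other, function(a) {
    blk <- as.numeric(dt$macroarea == a) *
      as.matrix(dt[, paste0("rpe_", interaction_sectors), with = FALSE])
    colnames(blk) <- paste0("area_", a, ":rpe_", interaction_sectors)
    blk
  }))
  X <- cbind(`(Intercept)` = 1, Xmain, Z, ZR)
  qf <- qr(X)
  if (qf$rank < ncol(X)) {
    dropped <- colnames(X)[qf$pivot[(qf$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = X, y = y, llm_id = dt$llm_id,
                 response = indicator_col,
                 response_scale = response_scale,
                 interaction_sectors = interaction_sectors,
                 reference_area = reference_area),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d observations x %d columns, response '%s'%s\n",
              nrow(x$X), ncol(x$X), x$response,
              if (is.null(x$response_scale)) "" else " (standardized)"))
  invisible(x)
}

#' Fit quantile regressions by iteratively reweighted least squares
#'
#' For every quantile level, the coefficients minimize the total check
#' (pinball) loss \eqn{\sum_i \rho_\tau(y_i - x_i'b)}. The solver is IWLS
#' with an annealed smoothing floor, refined by an exact basic-solution
#' polish on small designs; correctness is defined by the attained loss.
#' Asymptotic (iid-error, Hall-Sheather sparsity) standard errors are
#' reported by default; see [wild_bootstrap_se()] for heteroskedasticity-
#' robust ones. Information criteria come from an asymmetric-Laplace working
#' likelihood and are labelled as such.
#'
#' @param design a `design_matrix` from [build_design()], or any list with
#'   numeric matrix `X` and vector `y`.
#' @param taus quantile levels.
#' @return An object of class `quantile_fit`: list with `coefficients`
#'   (p x n_tau matrix), `se`, `loss` (total check loss per tau),
#'   `mean_loss`, `working_ic` (AIC/BIC per tau), `taus`, `n`, and the
#'   design.
#' @export
fit_quantile <- function(design, taus = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)) {
  X <- design$X
  y <- design$y
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (any(taus <= 0 | taus >= 1)) stop_config("taus must lie strictly in (0, 1)")
  if (nrow(X) <= ncol(X)) stop_config("need more rows than columns (n=%d, p=%d)",
                                      nrow(X), ncol(X))
  p <- ncol(X)
  n <- nrow(X)
  co <- matrix(NA_real_, p, length(taus),
               dimnames = list(colnames(X), paste0("tau_", taus)))
  se <- co
  loss <- numeric(length(taus))
  for (k in seq_along(taus)) {
    f <- fit_one_tau(X, y, taus[k], polish = p <= 6)
    co[, k] <- f$coefficients
    loss[k] <- f$loss
    se[, k] <- asymptotic_se(X, y - as.numeric(X %*% f$coefficients), taus[k])
  }
  mean_loss <- loss / n
  sigma <- pmax(mean_loss, .Machine$double.eps)
  loglik <- n * log(taus * (1 - taus)) - n * log(sigma) - n
  structure(list(coefficients = co, se = se, loss = loss,
                 mean_loss = mean_loss,
                 working_ic = data.table::data.table(
                   tau = taus, aic = 2 * p - 2 * loglik,
                   bic = log(n) * p - 2 * loglik),
                 taus = taus, n = n, design = design,
                 se_type = "asymptotic"),
            class = "quantile_fit")
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("<quantile_fit> %d observations, %d columns, taus: %s (%s SEs)\n",
              x$n, nrow(x$coefficients), paste(x$taus, collapse = ", "),
              x$se_type))
  invisible(x)
}

#' Tidy coefficient table of a quantile fit
#'
#' @param fit a `quantile_fit`.
#' @return data.table with `term`, `tau`, `estimate`, `se`, `p` (normal
#'   approximation).
#' @export
tidy_quantile_fit <- function(fit) {
  co <- fit$coefficients
  se <- fit$se
  data.table::rbindlist(lapply(seq_along(fit$taus), function(k) {
    z <- co[, k] / se[, k]
    data.table::data.table(term = rownames(co), tau = fit$taus[k],
                           estimate = co[, k], se = se[, k],
                           p = 2 * stats::pnorm(-abs(z)))
  }))
}

#' Wild-bootstrap standard errors for a quantile fit
#'
#' Residuals are perturbed with i.i.d. Rademacher (sign-symmetric) weights,
#' `y* = X b + w * r`, and the model refit per replication and per quantile;
#' the SE is the standard deviation of the replicated coefficients.
#' Replications that fail to produce finite coefficients are dropped and
#' counted; more than 5% failures is an error.
#'
#' @param fit a `quantile_fit`.
#' @param n_reps number of bootstrap replications.
#' @param seed integer seed.
#' @return The fit with `se` replaced by bootstrap SEs, `se_type` set to
#'   `"wild_bootstrap"`, and a `bootstrap` record (`n_reps`, `seed`,
#'   `n_failed` per tau) attached.
#' @export
wild_bootstrap_se <- function(fit, n_reps = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "quantile_fit"))
  X <- fit$design$X
  y <- fit$design$y
  n <- nrow(X)
  p <- ncol(X)
  set.seed(seed)
  se <- fit$se
  n_failed <- integer(length(fit$taus))
  for (k in seq_along(fit$taus)) {
    b <- fit$coefficients[, k]
    fitted <- as.numeric(X %*% b)
    r <- y - fitted
    reps <- matrix(NA_real_, n_reps, p)
    for (rep_i in seq_len(n_reps)) {
      w <- sample(c(-1, 1), n, replace = TRUE)
      ystar <- fitted + w * r
      fb <- iwls_refit(X, ystar, fit$taus[k], b0 = b)
      if (!is.null(fb)) reps[rep_i, ] <- fb
    }
    ok <- stats::complete.cases(reps)
    n_failed[k] <- sum(!ok)
    if (n_failed[k] > 0.05 * n_reps) {
      stop(sprintf("wild bootstrap: %d/%d replications failed at tau=%g",
                   n_failed[k], n_reps, fit$taus[k]))
    }
    se[, k] <- apply(reps[ok, , drop = FALSE], 2, stats::sd)
  }
  fit$se <- se
  fit$se_type <- "wild_bootstrap"
  fit$bootstrap <- list(n_reps = n_reps, seed = seed, n_failed = n_failed)
  fit
}

#' Ordinary least-squares reference fit on the same design
#'
#' @param design a `design_matrix` (or list with `X`, `y`).
#' @return data.table with `term`, `estimate`, `se`, `p`.
#' @export
fit_ols_reference <- function(design) {
  X <- design$X
  y <- design$y
  if (nrow(X) <= ncol(X)) stop_config("need more rows than columns")
  qf <- qr(X)
  if (qf$rank < ncol(X)) {
    dropped <- colnames(X)[qf$pivot[(qf$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  fit <- lm.fit(X, y)
  r <- fit$residuals
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(r^2) / df
  V <- sigma2 * solve(crossprod(X))
  est <- fit$coefficients[colnames(X)]
  se <- sqrt(diag(V))
  names(se) <- colnames(X)
  tt <- est / se
  data.table::data.table(term = colnames(X), estimate = unname(est),
                         se = unname(se),
                         p = unname(2 * pt(-abs(tt), df = df)))
}
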