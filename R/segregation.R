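#' Cosine distance matrix
#'
#' `1 - cos(x_i, x_j)` between observation rows. A zero-norm row has no
#' direction and is an error (named in the message).
#'
#' @param X numeric matrix (observations in rows).
#' @return A `dist` object.
#' @export
cosine_distance <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  zero <- which(nrm == 0)
  if (length(zero)) {
    nm <- rownames(X)[zero] %||% as.character(zero)
    stop("zero-vector observations have no cosine direction: ",
         paste(nm, collapse = ", "))
  }
  Xn <- X / nrm
  sim <- tcrossprod(Xn)
  sim[sim > 1] <- 1
  sim[sim < -1] <- -1
  stats::as.dist(1 - sim)
}

#' Clustering purity against known labels
#'
#' Each cluster votes for its most frequent label; purity is the number of
#' observations matching their cluster's majority label divided by the total.
#' A tied cluster contributes the tied count once (any majority choice gives
#' the same count).
#'
#' @param clusters integer/character cluster assignment.
#' @param labels class labels, same length.
#' @return Purity in `[0, 1]`.
#' @export
purity_score <- function(clusters, labels) {
  stopifnot(length(clusters) == length(labels))
  tab <- table(clusters, labels)
  sum(apply(tab, 1, max)) / length(labels)
}

#' Hierarchical clustering purity curve of the affected classes
#'
#' Agglomerates the standardized feature vectors of the most and least
#' affected territories once (cosine distance, average linkage by default)
#' and evaluates clustering purity against the class labels at every cut from
#' 1 to `max_clusters` clusters of the same tree. Because cuts of one tree
#' are nested, purity is non-decreasing in the number of clusters and reaches
#' 1 at the trivial all-singletons cut.
#'
#' @param features_std standardized feature table restricted to the two
#'   classes, or any data.table with `llm_id` and feature columns.
#' @param labels table with `llm_id`, `label`; only rows labelled most/least
#'   are used.
#' @param max_clusters largest cut evaluated.
#' @param distance `"cosine"` (default) or `"euclidean"`.
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return An object of class `purity_curve`: list with `curve` (data.table
#'   `n_clusters`, `purity`), `tree` (the `hclust`), `distance`, `linkage`.
#' @export
hierarchical_purity <- function(features_std, labels, max_clusters = 50L,
                                distance = c("cosine", "euclidean"),
                                linkage = "average") {
  distance <- match.arg(distance)
  labels <- data.table::as.data.table(labels)
  two <- labels[labels$label %in% c("most", "least")]
  cols <- attr(features_std, "feature_cols") %||%
    setdiff(names(features_std), c("llm_id", "macroarea"))
  dt <- merge(two, features_std, by = "llm_id")
  X <- as.matrix(dt[, cols, with = FALSE])
  rownames(X) <- dt$llm_id
  D <- if (distance == "cosine") cosine_distance(X) else stats::dist(X)
  tree <- stats::hclust(D, method = linkage)
  ks <- seq_len(min(max_clusters, nrow(X)))
  purity <- vapply(ks, function(k) {
    purity_score(stats::cutree(tree, k = k), dt$label)
  }, numeric(1))
  structure(list(curve = data.table::data.table(n_clusters = ks, purity = purity),
                 tree = tree, distance = distance, linkage = linkage,
                 labels = stats::setNames(dt$label, dt$llm_id)),
            class = "purity_curve")
}

#' @export
print.purity_curve <- function(x, ...) {
  k2 <- x$curve$purity[x$curve$n_clusters == 2]
  cat(sprintf("<purity_curve> %s distance, %s linkage; purity(2) = %.3f, purity(%d) = %.3f\n",
              x$distance, x$linkage, k2, max(x$curve$n_clusters),
              max(x$curve$purity)))
  invisible(x)
}

# stratified shuffle-split fold indices: per class, a fresh random test
# subset of size round(test_fraction * n_class) in every split
stratified_shuffle_split <- function(labels, n_splits, test_fraction) {
  idx_by_class <- split(seq_along(labels), labels)
  lapply(seq_len(n_splits), function(s) {
    test <- unlist(lapply(idx_by_class, function(ix) {
      sample(ix, max(2L, round(test_fraction * length(ix))))
    }))
    list(train = setdiff(seq_along(labels), test), test = sort(test))
  })
}

# macro-averaged one-vs-rest AUROC for a binary problem
macro_auroc <- function(truth, score_pos, positive) {
  lev <- levels(truth)
  negative <- setdiff(lev, positive)
  a1 <- as.numeric(pROC::auc(response = truth, predictor = score_pos,
                             levels = c(negative, positive), direction = "<",
                             quiet = TRUE))
  a2 <- as.numeric(pROC::auc(response = truth, predictor = 1 - score_pos,
                             levels = c(positive, negative), direction = "<",
                             quiet = TRUE))
  mean(c(a1, a2))
}

#' Cross-validated classification of most vs least affected territories
#'
#' Trains off-the-shelf binary classifiers (logistic regression, random
#' forest, k-nearest neighbours, support-vector machine; ecosystem-default
#' hyperparameters) on standardized features under a stratified shuffle-split
#' scheme and reports the macro-averaged AUROC per fold.
#'
#' @param features_std standardized feature table.
#' @param labels table with `llm_id`, `label`; exactly the two classes
#'   `most` and `least` are used.
#' @param classifiers subset of
#'   `c("logistic", "random_forest", "knn", "svm")`.
#' @param n_splits number of shuffle splits.
#' @param test_fraction fraction of observations held out per split.
#' @param seed integer seed for the splits and the stochastic learners.
#' @return An object of class `cv_report`: list with `folds` (data.table
#'   `classifier`, `fold`, `auroc`), `summary` (mean and SD per classifier),
#'   and the fold definition record.
#' @export
classify_classes <- function(features_std, labels,
                             classifiers = c("logistic", "random_forest",
                                             "knn", "svm"),
                             n_splits = 10L, test_fraction = 0.2,
                             seed = 1L) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  labels <- data.table::as.data.table(labels)
  two <- labels[labels$label %in% c("most", "least")]
  cols <- attr(features_std, "feature_cols") %||%
    setdiff(names(features_std), c("llm_id", "macroarea"))
  dt <- merge(two, features_std, by = "llm_id")
  X <- as.matrix(dt[, cols, with = FALSE])
  yf <- factor(dt$label, levels = c("most", "least"))
  if (any(table(yf) < 10)) stop("need at least 10 observations per class")
  set.seed(seed)
  splits <- stratified_shuffle_split(yf, n_splits, test_fraction)

  score_fold <- function(clf, tr, te) {
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    ytr <- yf[tr]
    switch(clf,
      logistic = {
        df_tr <- data.frame(Xtr); df_te <- data.frame(Xte)
        names(df_te) <- names(df_tr)
        fit <- suppressWarnings(glm(ytr ~ ., data = cbind(ytr = ytr, df_tr),
                                    family = binomial()))
        suppressWarnings(predict(fit, newdata = df_te, type = "response"))
      },
      random_forest = {
        fit <- randomForest::randomForest(Xtr, ytr)
        predict(fit, Xte, type = "prob")[, "least"]
      },
      knn = {
        pr <- class::knn(Xtr, Xte, ytr, k = 5, prob = TRUE)
        p_win <- attr(pr, "prob")
        ifelse(pr == "least", p_win, 1 - p_win)
      },
      svm = {
        fit <- e1071::svm(Xtr, ytr, probability = TRUE)
        attr(predict(fit, Xte, probability = TRUE),
             "probabilities")[, "least"]
      })
  }

  folds <- data.table::rbindlist(lapply(classifiers, function(clf) {
    data.table::rbindlist(lapply(seq_along(splits), function(s) {
      sp <- splits[[s]]
      sc <- score_fold(clf, sp$train, sp$test)
      data.table::data.table(
        classifier = clf, fold = s,
        auroc = macro_auroc(yf[sp$test], as.numeric(sc), positive = "least"))
    }))
  }))
  summary <- folds[, list(mean_auroc = mean(auroc), sd_auroc = stats::sd(auroc)),
                   by = "classifier"]
  structure(list(folds = folds, summary = summary,
                 n_splits = n_splits, test_fraction = test_fraction,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d stratified shuffle splits (%.0f%% test)\n",
              x$n_splits, 100 * x$test_fraction))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-14s macro AUROC %.3f +/- %.3f\n",
                x$summary$classifier[i], x$summary$mean_auroc[i],
                x$summary$sd_auroc[i]))
  }
  invisible(x)
}

# Conover-Iman post-hoc t statistics on the pooled ranks, conditional on the
# (tie-corrected) Kruskal-Wallis statistic H; p-values from t with N-k df.
conover_pairwise <- function(values, groups, H) {
  groups <- factor(groups)
  N <- length(values)
  k <- nlevels(groups)
  r <- rank(values)
  n_g <- tapply(r, groups, length)
  rbar <- tapply(r, groups, mean)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  denom_scale <- S2 * (N - 1 - H) / (N - k)
  pairs <- utils::combn(levels(groups), 2)
  data.table::rbindlist(apply(pairs, 2, function(pp) {
    i <- pp[1]; j <- pp[2]
    se <- sqrt(denom_scale * (1 / n_g[[i]] + 1 / n_g[[j]]))
    tt <- (rbar[[i]] - rbar[[j]]) / se
    data.table::data.table(group_i = i, group_j = j, statistic = tt,
                           p_raw = 2 * pt(-abs(tt), df = N - k))
  }, simplify = FALSE))
}

#' Per-feature group-difference tests across the three classes
#'
#' For every feature, an omnibus Kruskal-Wallis rank test over the
#' most/least/rest classes, followed by pairwise Conover post-hoc comparisons
#' with Bonferroni correction (`p_adj = min(1, p_raw * n_pairs)`). Post-hoc
#' comparisons are computed regardless of omnibus significance and reported
#' alongside the omnibus p-value; the intended decision rule gates the
#' post-hoc on the omnibus. Constant features are flagged and skipped.
#'
#' The omnibus p-value uses a permutation reference distribution by default:
#' several covariates are measured at the province level and therefore take
#' identical values across the territories of one province, which makes the
#' chi-square approximation of the (tie-corrected) Kruskal-Wallis statistic
#' anticonservative; permuting the class labels gives a reference that is
#' valid under any value-duplication pattern. The chi-square approximation is
#' available via `omnibus = "asymptotic"`. The permutation p-value is bounded
#' below by `1/(n_perm + 1)`.
#'
#' @param features raw (unstandardized) feature table.
#' @param labels table with `llm_id`, `label` (three classes).
#' @param omnibus `"permutation"` (default) or `"asymptotic"` reference
#'   distribution for the omnibus p-value.
#' @param n_perm number of label permutations.
#' @param perm_seed seed for the permutation draw (recorded in the result).
#' @return An object of class `group_test_table`: data.table with one row per
#'   feature and pairwise comparison: `feature`, `kw_statistic`, `kw_p`,
#'   `group_i`, `group_j`, `statistic`, `p_raw`, `p_adj`, `constant`.
#' @export
group_tests <- function(features, labels, omnibus = c("permutation", "asymptotic"),
                        n_perm = 999L, perm_seed = 1L) {
  omnibus <- match.arg(omnibus)
  labels <- data.table::as.data.table(labels)
  cols <- attr(features, "feature_cols") %||%
    setdiff(names(features), c("llm_id", "macroarea"))
  dt <- merge(labels, features, by = "llm_id")
  grp <- factor(dt$label)
  if (any(table(grp) < 2)) stop("need at least 2 observations per class")
  n_pairs <- choose(nlevels(grp), 2)
  variable <- vapply(cols, function(cn) length(unique(dt[[cn]])) > 1, logical(1))

  perm_p <- NULL
  if (omnibus == "permutation" && any(variable)) {
    vc <- cols[variable]
    R <- vapply(vc, function(cn) rank(dt[[cn]]), numeric(nrow(dt)))
    G <- stats::model.matrix(~ grp - 1)
    n_g <- colSums(G)
    # the tie-corrected KW statistic is a fixed monotone transform of
    # T = sum_g S_g^2 / n_g with S_g the rank sum of group g, so permutation
    # tail counts can compare T directly
    T_stat <- function(Rm) colSums(crossprod(G, Rm)^2 / n_g)
    T_obs <- T_stat(R)
    set.seed(perm_seed)
    exceed <- numeric(length(vc))
    for (b in seq_len(n_perm)) {
      Tb <- T_stat(R[sample.int(nrow(R)), , drop = FALSE])
      exceed <- exceed + (Tb >= T_obs - 1e-9)
    }
    perm_p <- stats::setNames((1 + exceed) / (n_perm + 1), vc)
  }

  out <- data.table::rbindlist(lapply(cols, function(cn) {
    v <- dt[[cn]]
    if (length(unique(v)) == 1) {
      return(data.table::data.table(feature = cn, kw_statistic = NA_real_,
                                    kw_p = NA_real_, group_i = NA_character_,
                                    group_j = NA_character_,
                                    statistic = NA_real_, p_raw = NA_real_,
                                    p_adj = NA_real_, constant = TRUE))
    }
    kw <- kruskal.test(v, grp)
    kw_p <- if (is.null(perm_p)) kw$p.value else unname(perm_p[cn])
    pw <- conover_pairwise(v, grp, unname(kw$statistic))
    pw[, p_adj := pmin(1, p_raw * n_pairs)]
    cbind(feature = cn, kw_statistic = unname(kw$statistic),
          kw_p = kw_p, pw, constant = FALSE)
  }), use.names = TRUE)
  data.table::setattr(out, "omnibus", omnibus)
  data.table::setattr(out, "class", c("group_test_table", class(out)))
  out[]
}
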