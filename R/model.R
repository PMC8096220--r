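#' Configuration for the pause random-forest model
#'
#' @param tune_fraction Fraction of sites held out for hyperparameter
#'   optimisation (default 0.2).
#' @param k_folds Cross-validation folds on the remaining sites
#'   (default 10; 5 suits small site sets).
#' @param grid Hyperparameter candidates: a list with `n_trees`,
#'   `max_depth` (0 = unlimited) and `min_node` vectors; the grid is their
#'   cross product.
#' @param seed Integer seed governing the split, tuning, folds and
#'   permutations.
#' @param importance_repeats Column-shuffle repeats per feature and fold
#'   (default 10).
#' @param alpha_importance Significance level for the permutation-importance
#'   filter (default 0.05).
#' @return A `model_config` list.
#' @export
model_config <- function(tune_fraction = 0.2, k_folds = 10L,
                         grid = list(n_trees = c(100L, 300L, 500L),
                                     max_depth = c(0L, 10L, 20L),
                                     min_node = c(1L, 5L, 10L)),
                         seed = 1L, importance_repeats = 10L,
                         alpha_importance = 0.05) {
  stopifnot(tune_fraction > 0, tune_fraction < 1, k_folds >= 2)
  structure(list(tune_fraction = tune_fraction, k_folds = as.integer(k_folds),
                 grid = grid, seed = as.integer(seed),
                 importance_repeats = as.integer(importance_repeats),
                 alpha_importance = alpha_importance),
            class = "model_config")
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over score thresholds with tied scores grouped: at
#' each distinct score (descending), precision is evaluated after admitting
#' the whole tie group, and the area accumulates precision times the recall
#' increment.
#'
#' @param scores Numeric classifier scores (higher = more pause-like).
#' @param labels Logical or 0/1 vector; `TRUE`/1 marks positives.
#' @return PR-AUC in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels)
  if (npos == 0 || npos == length(labels)) abort("both classes required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- which(!duplicated(s, fromLast = TRUE)) # last index of each tie group
  tp <- cumsum(y)[grp_end]
  nn <- grp_end
  prec <- tp / nn
  rec <- tp / npos
  sum(prec * diff(c(0, rec)))
}

stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Stratified tune / evaluation split
#'
#' @param fm A `feature_matrix` (needs `label` plus feature columns).
#' @param tune_fraction Fraction assigned to the tune set.
#' @param seed Integer seed.
#' @return List with `tune` and `rest` tibbles (disjoint, exhaustive).
#' @export
split_tune_rest <- function(fm, tune_fraction = 0.2, seed = 1L) {
  fm <- as_tibble(fm)
  if (length(unique(fm$label)) < 2) abort("both labels required")
  with_seed(seed, {
    take <- logical(nrow(fm))
    for (lv in unique(fm$label)) {
      idx <- which(fm$label == lv)
      take[sample(idx, round(length(idx) * tune_fraction))] <- TRUE
    }
    list(tune = fm[take, ], rest = fm[!take, ])
  })
}

feature_cols <- function(fm) setdiff(names(fm), c("site_id", "label"))

fit_rf <- function(data, hp, seed) {
  x <- as.data.frame(data[, feature_cols(data)])
  y <- factor(data$label, levels = c("non-pause", "pause"))
  ranger::ranger(x = x, y = y, probability = TRUE,
                 num.trees = hp$n_trees,
                 max.depth = if (hp$max_depth == 0) NULL else hp$max_depth,
                 min.node.size = hp$min_node,
                 seed = seed, num.threads = 1)
}

rf_scores <- function(model, data) {
  predict(model, data = as.data.frame(data[, feature_cols(data)]),
          num.threads = 1)$predictions[, "pause"]
}

#' Grid-search hyperparameters by cross-validated PR-AUC
#'
#' Scores every grid candidate by stratified k-fold cross-validated mean
#' PR-AUC on the tune set; ties break toward the smaller model (fewer
#' trees, shallower, larger terminal nodes).
#'
#' @param tune Tune-set tibble from [split_tune_rest()].
#' @param grid List of candidate vectors (see [model_config()]).
#' @param seed Integer seed.
#' @param k Internal folds (default 5).
#' @return List `n_trees`, `max_depth`, `min_node`, `tune_pr_auc`.
#' @export
tune_hyperparameters <- function(tune, grid, seed = 1L, k = 5L) {
  cand <- expand.grid(n_trees = grid$n_trees, max_depth = grid$max_depth,
                      min_node = grid$min_node)
  fold <- stratified_folds(tune$label, k, seed)
  scores <- vapply(seq_len(nrow(cand)), function(ci) {
    hp <- as.list(cand[ci, ])
    mean(vapply(seq_len(k), function(f) {
      fit <- fit_rf(tune[fold != f, ], hp, seed + f)
      pr_auc(rf_scores(fit, tune[fold == f, ]), tune$label[fold == f] == "pause")
    }, 0))
  }, 0)
  # ties toward the smaller model: fewer trees, shallower (0 = unlimited is
  # deepest), larger min node
  depth_rank <- ifelse(cand$max_depth == 0, Inf, cand$max_depth)
  ord <- order(-scores, cand$n_trees, depth_rank, -cand$min_node)
  best <- as.list(cand[ord[1], ])
  best$tune_pr_auc <- scores[ord[1]]
  best
}

#' Stratified k-fold evaluation of chosen hyperparameters
#'
#' @param rest Evaluation-set tibble from [split_tune_rest()].
#' @param hp Hyperparameter list (`n_trees`, `max_depth`, `min_node`).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List with `fold_pr_auc`, `mean_pr_auc`, and per-fold fitted
#'   models plus held-out indices (used for permutation importance).
#' @export
cv_evaluate <- function(rest, hp, k = 10L, seed = 1L) {
  fold <- stratified_folds(rest$label, k, seed)
  if (any(tapply(rest$label == "pause", fold, sum) == 0)) {
    abort("a fold has no positive examples")
  }
  models <- vector("list", k)
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    models[[f]] <- fit_rf(rest[fold != f, ], hp, seed + 1000L + f)
    aucs[f] <- pr_auc(rf_scores(models[[f]], rest[fold == f, ]),
                      rest$label[fold == f] == "pause")
  }
  list(fold_pr_auc = aucs, mean_pr_auc = mean(aucs), models = models,
       fold = fold, data = rest, hp = hp)
}

#' Permutation feature importance with significance filtering
#'
#' For each feature, held-out fold and repeat: shuffle the feature column
#' in the held-out data and record the drop in PR-AUC from the fold's
#' baseline. Repeats within one fold share a fitted model and are
#' correlated, so the repeat values are first averaged per fold; a feature
#' is significant when a one-sided one-sample t-test of its per-fold mean
#' importances (mean > 0), BH-corrected across features, passes `alpha` and
#' its overall mean importance is positive. Features near zero or negative
#' are noise.
#'
#' @param cv Result of [cv_evaluate()].
#' @param repeats Shuffles per feature and fold.
#' @param seed Integer seed.
#' @param alpha Significance level after BH correction.
#' @return Tibble `feature`, `importance_mean`, `importance_sd`, `p`, `q`,
#'   `significant`.
#' @export
permutation_importances <- function(cv, repeats = 10L, seed = 1L,
                                    alpha = 0.05) {
  feats <- feature_cols(cv$data)
  k <- length(cv$models)
  imp <- matrix(0, length(feats), k * repeats,
                dimnames = list(feats, NULL))
  with_seed(seed, {
    for (f in seq_len(k)) {
      hold <- cv$data[cv$fold == f, ]
      base <- pr_auc(rf_scores(cv$models[[f]], hold), hold$label == "pause")
      for (r in seq_len(repeats)) {
        for (ft in feats) {
          sh <- hold
          sh[[ft]] <- sample(sh[[ft]])
          imp[ft, (f - 1) * repeats + r] <-
            base - pr_auc(rf_scores(cv$models[[f]], sh), sh$label == "pause")
        }
      }
    }
  })
  # cluster-aware test: average the correlated repeats within each fold,
  # then test across the k independent folds
  fold_of <- rep(seq_len(k), each = repeats)
  fold_means <- t(apply(imp, 1, function(v) tapply(v, fold_of, mean)))
  pvals <- apply(fold_means, 1, function(v) {
    if (sd(v) == 0) return(if (mean(v) > 0) 0 else 1)
    t.test(v, alternative = "greater")$p.value
  })
  q <- bh_adjust(pvals)
  tibble(feature = feats,
         importance_mean = rowMeans(imp),
         importance_sd = apply(imp, 1, sd),
         p = unname(pvals), q = unname(q),
         significant = unname(q < alpha & rowMeans(imp) > 0))
}

#' Fit and evaluate the pause random-forest model end to end
#'
#' Splits off the tune fraction, grid-searches hyperparameters there,
#' evaluates them on the remainder by stratified k-fold cross-validation
#' (PR-AUC), and computes permutation feature importances on the held-out
#' folds. Deterministic given the config seed.
#'
#' @param fm A `feature_matrix` with both labels.
#' @param config A [model_config()].
#' @return A `pause_rf` object; see [tidy.pause_rf()] and
#'   [glance.pause_rf()].
#' @export
pause_model <- function(fm, config = model_config()) {
  sp <- split_tune_rest(fm, config$tune_fraction, config$seed)
  hp <- tune_hyperparameters(sp$tune, config$grid, config$seed)
  cv <- cv_evaluate(sp$rest, hp, config$k_folds, config$seed)
  imp <- permutation_importances(cv, config$importance_repeats,
                                 config$seed + 7L, config$alpha_importance)
  structure(list(hyperparameters = hp, fold_pr_auc = cv$fold_pr_auc,
                 mean_pr_auc = cv$mean_pr_auc, importance = imp,
                 n = nrow(fm), p = length(feature_cols(fm)),
                 config = config),
            class = "pause_rf")
}

#' @export
print.pause_rf <- function(x, ...) {
  cat(sprintf(paste0("<pause_rf> n = %d sites, p = %d features\n",
                     "  hyperparameters: %d trees, depth %s, min node %d\n",
                     "  mean CV PR-AUC = %.3f over %d folds; %d significant features\n"),
              x$n, x$p, x$hyperparameters$n_trees,
              ifelse(x$hyperparameters$max_depth == 0, "unlimited",
                     x$hyperparameters$max_depth),
              x$hyperparameters$min_node, x$mean_pr_auc,
              length(x$fold_pr_auc), sum(x$importance$significant)))
  invisible(x)
}

#' Tidy the per-feature importances of a fitted pause model
#'
#' @param x A `pause_rf` object.
#' @param ... Unused.
#' @return Tibble of per-feature permutation importances, descending.
#' @export
tidy.pause_rf <- function(x, ...) {
  arrange(x$importance, dplyr::desc(.data$importance_mean))
}

#' One-row model summary
#'
#' @param x A `pause_rf` object.
#' @param ... Unused.
#' @return One-row tibble: n, p, folds, hyperparameters, mean and sd of the
#'   per-fold PR-AUC, number of significant features.
#' @export
glance.pause_rf <- function(x, ...) {
  tibble(n = x$n, p = x$p, k_folds = length(x$fold_pr_auc),
         n_trees = x$hyperparameters$n_trees,
         max_depth = x$hyperparameters$max_depth,
         min_node = x$hyperparameters$min_node,
         mean_pr_auc = x$mean_pr_auc, sd_pr_auc = sd(x$fold_pr_auc),
         n_significant_features = sum(x$importance$significant))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
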