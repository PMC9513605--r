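#' Construct balanced training subsets
#'
#' Each subset reuses every positive pair and pairs it with an equal-size
#' uniform draw (without replacement within a subset, independently
#' across subsets) from the negative set, so the ensemble members see
#' diverse negatives while every member trains on a balanced problem.
#'
#' @param positive_pairs tibble of positive pairs (`mirna`, `disease`).
#' @param negative_pairs tibble of negative pairs; must be at least as
#'   many as the positives.
#' @param m number of subsets (default 10).
#' @param seed integer master seed; subset draws derive from it.
#' @return list of `m` tibbles with columns `mirna`, `disease`, `label`
#'   (1 positive / 0 negative).
#' @export
make_training_subsets <- function(positive_pairs, negative_pairs, m = 10,
                                  seed = 1) {
  n_pos <- nrow(positive_pairs)
  n_neg <- nrow(negative_pairs)
  if (n_neg < n_pos) {
    rlang::abort("negative set smaller than the positive set; cannot balance subsets")
  }
  if (m < 1L) rlang::abort("`m` must be at least 1")
  lapply(seq_len(m), function(j) {
    draw <- withr::with_seed(
      derive_seed(seed, j),
      sort(sample.int(n_neg, n_pos))
    )
    dplyr::bind_rows(
      dplyr::mutate(positive_pairs[, c("mirna", "disease")], label = 1L),
      dplyr::mutate(negative_pairs[draw, c("mirna", "disease")], label = 0L)
    )
  })
}

#' Random-forest variable-importance feature selection
#'
#' Fits a random forest on the subset, ranks features by importance
#' (impurity by default; permutation importance as an opt-in), and keeps
#' the top fraction, with ties broken by the lower feature index. The
#' retained count is `round(fraction * n_features)` under
#' half-away-from-zero rounding, so 75% of 878 features keeps 659.
#'
#' @param features numeric matrix (samples x features).
#' @param labels 0/1 vector; both classes must be present.
#' @param fraction fraction of features to keep, in (0, 1].
#' @param num_trees forest size (default 100).
#' @param seed integer seed.
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @return sorted integer vector of retained feature indices, with the
#'   importance scores as attribute `importance`.
#' @export
select_features <- function(features, labels, fraction = 0.75,
                            num_trees = 100, seed = 1,
                            importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  assert_prob(fraction, "fraction", open_left = TRUE)
  if (length(unique(labels)) < 2L) {
    rlang::abort("feature selection needs both classes in the subset")
  }
  n_feat <- ncol(features)
  x <- as.data.frame(features)
  names(x) <- paste0("f", seq_len(n_feat))
  fit <- ranger::ranger(
    x = x, y = factor(labels, levels = c(0, 1)),
    num.trees = num_trees, importance = importance,
    seed = seed, num.threads = 1
  )
  imp <- as.numeric(fit$variable.importance)
  keep <- round_half_up(fraction * n_feat)
  keep <- max(1L, min(n_feat, keep))
  selected <- sort(order(-imp, seq_len(n_feat))[seq_len(keep)])
  structure(selected, importance = imp)
}

# ---- base learners -------------------------------------------------------

default_learner_params <- function(learner) {
  switch(learner,
    xgb = list(nrounds = 100, max_depth = 6, eta = 0.1),
    rf = list(num_trees = 100, max_depth = 6),
    extratrees = list(num_trees = 100, max_depth = 6),
    adaboost = list(n_rounds = 50, max_depth = 3)
  )
}

fit_base_learner <- function(features, labels, learner, params, seed) {
  p <- utils::modifyList(default_learner_params(learner), params)
  fit <- switch(learner,
    xgb = withr::with_seed(seed, {
      dtrain <- xgboost::xgb.DMatrix(features, label = labels)
      xgboost::xgb.train(
        params = list(
          objective = "binary:logistic", max_depth = p$max_depth,
          eta = p$eta, nthread = 1
        ),
        data = dtrain, nrounds = p$nrounds, verbose = 0
      )
    }),
    rf = ,
    extratrees = ranger::ranger(
      x = as.data.frame(features), y = factor(labels, levels = c(0, 1)),
      probability = TRUE, num.trees = p$num_trees, max.depth = p$max_depth,
      splitrule = if (learner == "extratrees") "extratrees" else "gini",
      seed = seed, num.threads = 1
    ),
    adaboost = fit_adaboost(features, labels,
      n_rounds = p$n_rounds,
      max_depth = p$max_depth, seed = seed
    ),
    rlang::abort(sprintf("unknown learner '%s'", learner))
  )
  list(learner = learner, fit = fit, n_features = ncol(features))
}

predict_base_learner <- function(member, features) {
  if (ncol(features) != member$n_features) {
    rlang::abort("feature length does not match the fitted member")
  }
  switch(member$learner,
    xgb = as.numeric(stats::predict(member$fit, xgboost::xgb.DMatrix(features))),
    rf = ,
    extratrees = {
      pr <- stats::predict(member$fit, data = as.data.frame(features),
        num.threads = 1
      )$predictions
      as.numeric(pr[, "1"])
    },
    adaboost = predict_adaboost(member$fit, features)
  )
}

# Real AdaBoost (SAMME.R) over depth-limited CART trees: each round fits a
# weighted tree, adds half the log-odds of its class-1 probability to the
# additive score, and reweights samples by the exponential loss.
fit_adaboost <- function(features, labels, n_rounds = 50, max_depth = 3,
                         seed = 1) {
  eps <- 1e-6
  y <- 2 * labels - 1
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- factor(labels, levels = c(0, 1))
  w <- rep(1 / nrow(df), nrow(df))
  trees <- vector("list", n_rounds)
  withr::with_seed(seed, {
    for (t in seq_len(n_rounds)) {
      fit <- rpart::rpart(
        .y ~ ., data = df, weights = w, method = "class",
        control = rpart::rpart.control(
          maxdepth = max_depth, cp = 0, minsplit = 5, xval = 0
        )
      )
      prob <- pmin(pmax(stats::predict(fit, df, type = "prob")[, "1"], eps), 1 - eps)
      h <- 0.5 * log(prob / (1 - prob))
      w <- w * exp(-y * h)
      w <- w / sum(w)
      trees[[t]] <- fit
    }
  })
  structure(list(trees = trees, eps = eps), class = "pumda_adaboost")
}

predict_adaboost <- function(model, features) {
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(df)))
  score <- rep(0, nrow(df))
  for (fit in model$trees) {
    prob <- pmin(pmax(stats::predict(fit, df, type = "prob")[, "1"], model$eps),
      1 - model$eps
    )
    score <- score + 0.5 * log(prob / (1 - prob))
  }
  1 / (1 + exp(-2 * score))
}

# ---- ensemble ------------------------------------------------------------

#' Train the soft-voting ensemble
#'
#' One base classifier per training subset. For each subset the features
#' are built from the similarity bundle, a per-subset random-forest
#' importance ranking selects the retained features, and a tree learner
#' is fitted on the selected-feature view. At prediction time each member
#' scores pairs on its own selected features and the ensemble output is
#' the plain average of member scores.
#'
#' @param bundle a [similarity_bundle()].
#' @param subsets list of training-subset tibbles from
#'   [make_training_subsets()].
#' @param learner `"xgb"` (default), `"rf"`, `"adaboost"` or
#'   `"extratrees"`.
#' @param feature_fraction fraction of features kept per subset
#'   (default 0.75); 1 disables selection.
#' @param fs_num_trees,fs_importance feature-selection forest size and
#'   importance measure (see [select_features()]).
#' @param params named list of learner hyperparameters overriding the
#'   defaults (100 trees / boosting rounds, depth 6, learning rate 0.1).
#' @param seed master seed; member seeds derive from it.
#' @return object of class `mda_ensemble`.
#' @export
train_ensemble <- function(bundle, subsets, learner = c("xgb", "rf", "adaboost", "extratrees"),
                           feature_fraction = 0.75, fs_num_trees = 100,
                           fs_importance = "impurity", params = list(),
                           seed = 1) {
  learner <- match.arg(learner)
  if (length(subsets) < 1L) rlang::abort("need at least one training subset")
  members <- vector("list", length(subsets))
  for (j in seq_along(subsets)) {
    sub <- subsets[[j]]
    features <- pair_features(bundle, sub)
    selected <- if (feature_fraction >= 1) {
      seq_len(ncol(features))
    } else {
      as.integer(select_features(
        features, sub$label,
        fraction = feature_fraction, num_trees = fs_num_trees,
        seed = derive_seed(seed, 1000L + j), importance = fs_importance
      ))
    }
    member <- tryCatch(
      fit_base_learner(
        features[, selected, drop = FALSE], sub$label, learner,
        params, derive_seed(seed, 2000L + j)
      ),
      error = function(e) {
        rlang::abort(sprintf("training of ensemble member %d failed: %s", j, conditionMessage(e)))
      }
    )
    member$selected_features <- selected
    members[[j]] <- member
  }
  structure(
    list(
      members = members, learner = learner, m = length(subsets),
      feature_fraction = feature_fraction,
      feature_names = colnames(pair_features(bundle, subsets[[1]][1, ])),
      n_feature = feature_length(bundle), seed = seed
    ),
    class = "mda_ensemble"
  )
}

#' @export
print.mda_ensemble <- function(x, ...) {
  cat(sprintf(
    "# Soft-voting ensemble: %d %s member(s), %d/%d features per member\n",
    x$m, x$learner, length(x$members[[1]]$selected_features), x$n_feature
  ))
  invisible(x)
}

#' Soft-vote scores of member predictions
#'
#' The ensemble output for a sample is the arithmetic mean of its member
#' scores; a pair is called associated when the mean strictly exceeds the
#' voting threshold (an exact 0.5 is *not* associated).
#'
#' @param score_matrix samples x members matrix of member scores in
#'   \[0, 1\].
#' @param threshold voting threshold (default 0.5).
#' @return tibble with columns `score` and `label`.
#' @export
soft_vote <- function(score_matrix, threshold = 0.5) {
  score <- rowMeans(score_matrix)
  tibble::tibble(score = score, label = as.integer(score > threshold))
}

#' Score miRNA-disease pairs with a trained ensemble
#'
#' @param object an `mda_ensemble`.
#' @param bundle the [similarity_bundle()] the model was trained against.
#' @param pairs tibble of pairs (`mirna`, `disease`); `NULL` scores the
#'   whole grid.
#' @param features optional precomputed full-length feature matrix
#'   (overrides `bundle`/`pairs`).
#' @param threshold voting threshold (default 0.5, strict).
#' @param ... unused.
#' @return tibble with `mirna`, `disease` (when pairs are known),
#'   `score`, `label`.
#' @export
predict.mda_ensemble <- function(object, bundle = NULL, pairs = NULL,
                                 features = NULL, threshold = 0.5, ...) {
  if (is.null(features)) {
    if (is.null(bundle)) rlang::abort("supply either `features` or `bundle`")
    if (is.null(pairs)) pairs <- pair_grid(bundle$mirna_index, bundle$disease_index)
    features <- pair_features(bundle, pairs)
  }
  if (ncol(features) != object$n_feature) {
    rlang::abort(sprintf(
      "feature length %d does not match the model's %d",
      ncol(features), object$n_feature
    ))
  }
  member_scores <- vapply(
    object$members,
    function(mem) {
      predict_base_learner(mem, features[, mem$selected_features, drop = FALSE])
    },
    numeric(nrow(features))
  )
  member_scores <- matrix(member_scores, nrow = nrow(features))
  out <- soft_vote(member_scores, threshold = threshold)
  if (!is.null(pairs)) {
    out <- dplyr::bind_cols(pairs[, c("mirna", "disease")], out)
  }
  out
}
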