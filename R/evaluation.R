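#' Area under the ROC curve (trapezoid rule)
#'
#' ROC points are generated by sweeping the decision threshold through
#' the distinct score values (ties grouped), and the area is the
#' trapezoid integral over false-positive rate — equivalent to the
#' Mann-Whitney concordance probability with ties counted one half.
#'
#' @param truth 0/1 vector; both classes required.
#' @param scores numeric scores.
#' @return scalar in \[0, 1\].
#' @export
auroc <- function(truth, scores) {
  roc <- roc_points(truth, scores)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Area under the precision-recall curve (step integration)
#'
#' Average precision: the sum over threshold points of the recall
#' increment times the precision at that point.
#'
#' @inheritParams auroc
#' @return scalar in \[0, 1\].
#' @export
aupr <- function(truth, scores) {
  pts <- pr_points(truth, scores)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

check_binary_truth <- function(truth, scores) {
  if (length(truth) != length(scores)) {
    rlang::abort("`truth` and `scores` must have equal length")
  }
  if (!all(truth %in% c(0, 1))) rlang::abort("`truth` must be 0/1")
  if (length(unique(truth)) < 2L) {
    rlang::abort("both classes must be present for ranking metrics")
  }
}

roc_points <- function(truth, scores) {
  check_binary_truth(truth, scores)
  ord <- order(scores, decreasing = TRUE)
  truth <- truth[ord]
  scores <- scores[ord]
  last_of_tie <- c(scores[-1] != scores[-length(scores)], TRUE)
  tp <- cumsum(truth)[last_of_tie]
  fp <- cumsum(1 - truth)[last_of_tie]
  tibble::tibble(
    fpr = c(0, fp / sum(1 - truth)),
    tpr = c(0, tp / sum(truth))
  )
}

pr_points <- function(truth, scores) {
  check_binary_truth(truth, scores)
  ord <- order(scores, decreasing = TRUE)
  truth <- truth[ord]
  scores <- scores[ord]
  last_of_tie <- c(scores[-1] != scores[-length(scores)], TRUE)
  tp <- cumsum(truth)[last_of_tie]
  fp <- cumsum(1 - truth)[last_of_tie]
  tibble::tibble(
    recall = tp / sum(truth),
    precision = tp / (tp + fp)
  )
}

#' Classification metrics for scored pairs
#'
#' Confusion counts at a strict decision threshold (predicted positive
#' iff `score > threshold`) plus the six standard metrics: precision,
#' recall, F1, accuracy, AUROC and AUPR. Zero-denominator precision or
#' recall is reported as 0 with a warning; when only one class is
#' present the ranking metrics are `NA` with a warning while the
#' threshold metrics are still returned.
#'
#' @param truth 0/1 vector of reference labels.
#' @param scores numeric prediction scores.
#' @param threshold decision threshold (default 0.5).
#' @return one-row tibble with columns `precision`, `recall`, `f1`,
#'   `accuracy`, `auroc`, `aupr`, `tp`, `fp`, `tn`, `fn`.
#' @export
compute_metrics <- function(truth, scores, threshold = 0.5) {
  if (length(truth) != length(scores)) {
    rlang::abort("`truth` and `scores` must have equal length")
  }
  if (!all(truth %in% c(0, 1))) rlang::abort("`truth` must be 0/1")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & truth == 1)
  fp <- sum(pred == 1L & truth == 0)
  tn <- sum(pred == 0L & truth == 0)
  fn <- sum(pred == 0L & truth == 1)
  zero_div <- function(num, den, what) {
    if (den == 0) {
      rlang::warn(sprintf("%s undefined (zero denominator); reporting 0", what))
      0
    } else num / den
  }
  precision <- zero_div(tp, tp + fp, "precision")
  recall <- zero_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  accuracy <- (tp + tn) / length(truth)
  if (length(unique(truth)) < 2L) {
    rlang::warn("single-class truth; AUROC/AUPR unavailable")
    roc <- pr <- NA_real_
  } else {
    roc <- auroc(truth, scores)
    pr <- aupr(truth, scores)
  }
  tibble::tibble(
    precision = precision, recall = recall, f1 = f1, accuracy = accuracy,
    auroc = roc, aupr = pr,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

# Stratified fold assignment: within each class, a shuffled round-robin.
stratified_folds <- function(labels, folds, seed) {
  assignment <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Cross-validate the full pipeline
#'
#' Builds a balanced evaluation set (every positive plus an equal-size
#' seeded draw from the negative set), splits it into stratified folds,
#' and per fold retrains the whole modeling chain — training subsets,
#' per-subset feature selection, base learners — on the training folds
#' only, drawing subset negatives from the negative set minus the test
#' fold so no held-out pair ever enters a training subset. Metrics are
#' computed on the held-out fold; the procedure repeats with fresh
#' negative draws.
#'
#' @param bundle a [similarity_bundle()].
#' @param partition a `sample_partition` (clustering-based or uniform
#'   baseline) supplying the negative set.
#' @param folds number of folds (default 5).
#' @param repeats number of repetitions with fresh negative draws
#'   (default 10).
#' @param m,learner,feature_fraction,fs_num_trees,params ensemble
#'   configuration (see [train_ensemble()]).
#' @param ranking_mode `"balanced_fold"` (default: all six metrics on the
#'   balanced held-out fold) or `"fold_plus_unlabeled"` (the held-out
#'   fold is merged with all unlabeled pairs outside the training set;
#'   ranking metrics only, threshold metrics are `NA`).
#' @param strict_cv when `TRUE`, the interaction-profile kernels are
#'   recomputed inside each fold with the held-out positives masked out
#'   of the association matrix, removing the mild feature leak that
#'   computing similarities once on the full matrix entails (the
#'   default, which follows the conventional protocol).
#' @param seed master seed.
#' @return object of class `mda_cv` with per-fold metrics; see
#'   [tidy.mda_cv()] and [glance.mda_cv()].
#' @export
cross_validate <- function(bundle, partition, folds = 5, repeats = 10,
                           m = 10, learner = "xgb", feature_fraction = 0.75,
                           fs_num_trees = 100, params = list(),
                           ranking_mode = c("balanced_fold", "fold_plus_unlabeled"),
                           strict_cv = FALSE, seed = 1) {
  ranking_mode <- match.arg(ranking_mode)
  if (folds < 2L) rlang::abort("`folds` must be at least 2")
  pairs <- partition$pairs
  pos <- partition$positive_idx
  neg_pool <- partition$negative_idx
  if (length(neg_pool) < length(pos)) {
    rlang::abort("negative set smaller than positive set")
  }
  results <- list()
  diagnostics <- list()
  for (r in seq_len(repeats)) {
    rseed <- derive_seed(seed, 31L * r)
    neg_draw <- withr::with_seed(rseed, sort(sample(neg_pool, length(pos))))
    eval_idx <- c(pos, neg_draw)
    eval_lab <- rep(c(1L, 0L), c(length(pos), length(neg_draw)))
    fold_id <- stratified_folds(eval_lab, folds, derive_seed(rseed, 7L))
    for (f in seq_len(folds)) {
      test <- eval_idx[fold_id == f]
      test_lab <- eval_lab[fold_id == f]
      train_pos_idx <- pos[fold_id[seq_along(pos)] != f]
      subset_pool <- setdiff(neg_pool, test)
      fold_bundle <- if (strict_cv) {
        mask_bundle(bundle, pairs[intersect(test, pos), ])
      } else {
        bundle
      }
      subsets <- make_training_subsets(
        pairs[train_pos_idx, ], pairs[subset_pool, ],
        m = m, seed = derive_seed(rseed, 13L * f)
      )
      model <- train_ensemble(
        fold_bundle, subsets,
        learner = learner,
        feature_fraction = feature_fraction, fs_num_trees = fs_num_trees,
        params = params, seed = derive_seed(rseed, 17L * f)
      )
      train_keys <- unique(unlist(lapply(
        subsets, function(s) pair_key(s$mirna, s$disease)
      )))
      if (ranking_mode == "balanced_fold") {
        pred <- predict(model, fold_bundle, pairs[test, ])
        met <- compute_metrics(test_lab, pred$score)
      } else {
        md_vec <- bundle$MD[cbind(
          match(pairs$mirna, bundle$mirna_index),
          match(pairs$disease, bundle$disease_index)
        )]
        unlabeled <- which(md_vec == 0L)
        used <- union(eval_idx, match_keys(pairs, train_keys))
        extra <- setdiff(unlabeled, used)
        score_idx <- c(test, extra)
        lab <- c(test_lab, rep(0L, length(extra)))
        pred <- predict(model, fold_bundle, pairs[score_idx, ])
        met <- tibble::tibble(
          precision = NA_real_, recall = NA_real_, f1 = NA_real_,
          accuracy = NA_real_,
          auroc = auroc(lab, pred$score), aupr = aupr(lab, pred$score),
          tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
          fn = NA_integer_
        )
      }
      results[[length(results) + 1L]] <- dplyr::mutate(
        met,
        repeat_id = r, fold = f, .before = 1
      )
      diagnostics[[length(diagnostics) + 1L]] <- list(
        repeat_id = r, fold = f,
        test_keys = pair_key(pairs$mirna[test], pairs$disease[test]),
        train_keys = train_keys
      )
    }
  }
  structure(
    list(
      metrics = dplyr::bind_rows(results),
      diagnostics = diagnostics,
      config = list(
        folds = folds, repeats = repeats, m = m, learner = learner,
        feature_fraction = feature_fraction, ranking_mode = ranking_mode,
        seed = seed
      )
    ),
    class = "mda_cv"
  )
}

match_keys <- function(pairs, keys) {
  which(pair_key(pairs$mirna, pairs$disease) %in% keys)
}

# Rebuild the kernel-derived parts of a bundle with the given positive
# pairs masked out of the association matrix. Semantic and functional
# similarity do not depend on MD and are kept as-is.
mask_bundle <- function(bundle, masked_pairs) {
  md <- bundle$MD
  if (nrow(masked_pairs) > 0L) {
    md[cbind(
      match(masked_pairs$mirna, bundle$mirna_index),
      match(masked_pairs$disease, bundle$disease_index)
    )] <- 0L
  }
  out <- bundle
  out$MD <- md
  out$GD <- gipk_similarity(t(md), gamma_prime = bundle$gamma_prime)
  out$GM <- gipk_similarity(md, gamma_prime = bundle$gamma_prime)
  out$IDS <- integrate_similarity(bundle$SS, out$GD)
  out$IMS <- integrate_similarity(bundle$FS, out$GM)
  out
}

#' @export
print.mda_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "# %d-fold CV, %d repeat(s), learner %s\n#   AUROC %.4f +/- %.4f, AUPR %.4f +/- %.4f\n",
    x$config$folds, x$config$repeats, x$config$learner,
    g$auroc_mean, g$auroc_sd, g$aupr_mean, g$aupr_sd
  ))
  invisible(x)
}

#' Leave-one-disease-out case-study ranking
#'
#' Removes every pair involving the target disease from the training
#' material (positives and negative draws alike), trains the ensemble on
#' what remains, scores all miRNAs against the disease, and returns the
#' top of the ranking. The disease's own verified miRNAs are never seen
#' in training, so the ranking is an honest prospective prediction.
#'
#' @param bundle a [similarity_bundle()].
#' @param partition a `sample_partition` supplying negatives.
#' @param disease target disease id (must exist in the disease index).
#' @param top_k rows to return (default 20).
#' @param m,learner,feature_fraction,fs_num_trees,params ensemble
#'   configuration.
#' @param seed master seed.
#' @return tibble with `rank`, `mirna`, `score`, sorted by decreasing
#'   score, `top_k` rows.
#' @export
case_study_rank <- function(bundle, partition, disease, top_k = 20,
                            m = 10, learner = "xgb", feature_fraction = 0.75,
                            fs_num_trees = 100, params = list(), seed = 1) {
  if (!disease %in% bundle$disease_index) {
    rlang::abort(sprintf("unknown disease '%s'", disease))
  }
  pairs <- partition$pairs
  keep_pos <- partition$positive_idx[pairs$disease[partition$positive_idx] != disease]
  keep_neg <- partition$negative_idx[pairs$disease[partition$negative_idx] != disease]
  subsets <- make_training_subsets(
    pairs[keep_pos, ], pairs[keep_neg, ],
    m = m, seed = derive_seed(seed, 3L)
  )
  model <- train_ensemble(
    bundle, subsets,
    learner = learner, feature_fraction = feature_fraction,
    fs_num_trees = fs_num_trees, params = params,
    seed = derive_seed(seed, 5L)
  )
  target <- tibble::tibble(mirna = bundle$mirna_index, disease = disease)
  pred <- predict(model, bundle, target)
  ranked <- dplyr::arrange(pred, dplyr::desc(.data$score), .data$mirna)
  dplyr::mutate(
    utils::head(ranked[, c("mirna", "score")], top_k),
    rank = dplyr::row_number(), .before = 1
  )
}
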