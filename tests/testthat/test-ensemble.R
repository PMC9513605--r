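make_toy_material <- function(seed = 3, ...) {
  bb <- small_bundle(seed = seed, ...)
  part <- sample_negatives(bb$bundle, k = 2, seed = seed + 100)
  list(bundle = bb$bundle, part = part, dataset = bb$dataset)
}

test_that("subsets are balanced, seeded and diverse", {
  toy <- make_toy_material(n_mirna = 20, n_disease = 15, n_positive = 50)
  subs <- make_training_subsets(positives(toy$part), negatives(toy$part),
    m = 10, seed = 4
  )
  expect_length(subs, 10L)
  for (s in subs) {
    expect_equal(sum(s$label == 1), 50L)
    expect_equal(sum(s$label == 0), 50L)
    expect_true(all(key_of(s[s$label == 0, ]) %in% key_of(negatives(toy$part))))
    expect_equal(anyDuplicated(key_of(s[s$label == 0, ])), 0L)
  }
  expect_false(identical(
    key_of(subs[[1]][subs[[1]]$label == 0, ]),
    key_of(subs[[2]][subs[[2]]$label == 0, ])
  ))
  subs2 <- make_training_subsets(positives(toy$part), negatives(toy$part),
    m = 10, seed = 4
  )
  expect_identical(subs, subs2)
})

test_that("a negative pool smaller than the positives is a hard error", {
  pos <- tibble::tibble(mirna = letters[1:5], disease = "d")
  neg <- tibble::tibble(mirna = letters[1:3], disease = "e")
  expect_error(make_training_subsets(pos, neg, m = 2, seed = 1), "smaller")
})

test_that("fraction one keeps every feature in order", {
  withr::local_seed(6)
  x <- matrix(stats::rnorm(200), 20)
  y <- rep(0:1, 10)
  sel <- select_features(x, y, fraction = 1, seed = 2)
  expect_equal(as.integer(sel), 1:10)
})

test_that("retained feature counts use half-away-from-zero rounding", {
  expect_equal(round_half_up(0.75 * 878), 659L)
  expect_equal(round_half_up(658.5), 659L)
  expect_equal(round_half_up(-658.5), -659L)
  withr::local_seed(7)
  x <- matrix(stats::rnorm(120), 15)
  y <- rep(0:1, length.out = 15)
  sel <- select_features(x, y, fraction = 0.6875, seed = 3) # 5.5 -> 6
  expect_length(sel, 6L)
  expect_equal(as.integer(sel), sort(as.integer(sel)))
})

test_that("single-class subsets cannot be feature-selected", {
  x <- matrix(stats::rnorm(40), 10)
  expect_error(select_features(x, rep(1, 10)), "both classes")
})

test_that("planted disease-block signal is preferentially selected", {
  # labels depend only on disease-block features; miRNA block is noise
  hits <- sapply(1:10, function(s) {
    withr::with_seed(s, {
      n <- 120
      x <- cbind(
        matrix(stats::rnorm(n * 5), n), # disease block (signal)
        matrix(stats::rnorm(n * 15), n) # miRNA block (noise)
      )
      y <- as.integer(rowSums(x[, 1:5]) > 0)
      sel <- select_features(x, y, fraction = 0.25, seed = s) # keep 5
      mean(sel <= 5)
    })
  })
  expect_gte(mean(hits), 0.8)
})

test_that("an m = 1 ensemble equals its single member and members stay on their own view", {
  toy <- make_toy_material(n_mirna = 20, n_disease = 15, n_positive = 50)
  subs <- make_training_subsets(positives(toy$part), negatives(toy$part),
    m = 1, seed = 9
  )
  model <- train_ensemble(toy$bundle, subs, learner = "rf", seed = 5)
  pairs <- toy$part$pairs[1:30, ]
  full <- pair_features(toy$bundle, pairs)
  ens <- predict(model, features = full)
  mem <- model$members[[1]]
  direct <- pumda:::predict_base_learner(
    mem, full[, mem$selected_features, drop = FALSE]
  )
  expect_equal(ens$score, direct, tolerance = 1e-12)
  # perturbing a non-selected feature never changes the prediction
  dropped <- setdiff(seq_len(ncol(full)), mem$selected_features)[1]
  perturbed <- full
  perturbed[, dropped] <- stats::runif(nrow(full))
  expect_equal(predict(model, features = perturbed)$score, ens$score)
})

test_that("every base learner trains and separates an easy subset", {
  toy <- make_toy_material(n_mirna = 20, n_disease = 15, n_positive = 50)
  subs <- make_training_subsets(positives(toy$part), negatives(toy$part),
    m = 2, seed = 2
  )
  for (learner in c("xgb", "rf", "adaboost", "extratrees")) {
    model <- train_ensemble(toy$bundle, subs, learner = learner, seed = 3)
    pred <- predict(model, toy$bundle, subs[[1]])
    expect_true(all(pred$score >= 0 & pred$score <= 1))
    expect_gt(auroc(subs[[1]]$label, pred$score), 0.95)
  }
})

test_that("soft voting averages member scores with a strict threshold", {
  scores <- cbind(c(0.2, 1, 0.4), c(0.8, 1, 0.4), c(0.5, 1, 0.4))
  out <- soft_vote(scores)
  expect_equal(out$score, c(0.5, 1, 0.4))
  expect_equal(out$label, c(0L, 1L, 0L)) # exactly 0.5 is NOT associated
  withr::local_seed(12)
  random <- matrix(stats::runif(60), 12)
  expect_equal(soft_vote(random)$score, rowMeans(random), tolerance = 1e-12)
})

test_that("ensemble scores are invariant under member permutation", {
  toy <- make_toy_material(n_mirna = 20, n_disease = 15, n_positive = 50)
  subs <- make_training_subsets(positives(toy$part), negatives(toy$part),
    m = 3, seed = 2
  )
  model <- train_ensemble(toy$bundle, subs, learner = "rf", seed = 3)
  shuffled <- model
  shuffled$members <- model$members[c(3, 1, 2)]
  pairs <- toy$part$pairs[1:20, ]
  expect_equal(
    predict(model, toy$bundle, pairs)$score,
    predict(shuffled, toy$bundle, pairs)$score,
    tolerance = 1e-12
  )
})

test_that("rf and extratrees ensembles are bit-reproducible under one master seed", {
  toy <- make_toy_material(n_mirna = 20, n_disease = 15, n_positive = 50)
  subs <- make_training_subsets(positives(toy$part), negatives(toy$part),
    m = 2, seed = 8
  )
  pairs <- toy$part$pairs[1:25, ]
  for (learner in c("rf", "extratrees")) {
    m1 <- train_ensemble(toy$bundle, subs, learner = learner, seed = 21)
    m2 <- train_ensemble(toy$bundle, subs, learner = learner, seed = 21)
    expect_identical(
      lapply(m1$members, `[[`, "selected_features"),
      lapply(m2$members, `[[`, "selected_features")
    )
    expect_identical(
      predict(m1, toy$bundle, pairs)$score,
      predict(m2, toy$bundle, pairs)$score
    )
  }
})

test_that("feature-length mismatches are rejected at prediction time", {
  toy <- make_toy_material(n_mirna = 20, n_disease = 15, n_positive = 50)
  subs <- make_training_subsets(positives(toy$part), negatives(toy$part),
    m = 1, seed = 1
  )
  model <- train_ensemble(toy$bundle, subs, learner = "rf", seed = 1)
  expect_error(
    predict(model, features = matrix(0, 2, 5)),
    "feature length"
  )
})
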