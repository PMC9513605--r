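test_that("well-separated blobs are recovered exactly at k = 2", {
  withr::local_seed(17)
  x <- rbind(
    matrix(stats::rnorm(80, 0, 0.5), 40),
    matrix(stats::rnorm(80, 8, 0.5), 40)
  )
  truth <- rep(1:2, each = 40)
  labels <- cluster_total_set(x, 2, n_repeats = 5, seed = 3)
  agreement <- max(mean(labels == truth), mean(labels == 3 - truth))
  expect_equal(agreement, 1)
})

test_that("k equal to the sample count gives singleton clusters, objective zero", {
  withr::local_seed(2)
  x <- matrix(stats::rnorm(30), 15)
  labels <- cluster_total_set(x, 15, n_repeats = 2, seed = 1)
  expect_equal(sort(unique(labels)), 1:15)
  expect_equal(attr(labels, "inertia"), 0)
})

test_that("clustering is deterministic under a fixed seed and matches stats::kmeans on blobs", {
  withr::local_seed(5)
  x <- rbind(
    matrix(stats::rnorm(60, 0), 30),
    matrix(stats::rnorm(60, 10), 30)
  )
  l1 <- cluster_total_set(x, 2, n_repeats = 3, seed = 7)
  l2 <- cluster_total_set(x, 2, n_repeats = 3, seed = 7)
  expect_identical(as.integer(l1), as.integer(l2))
  km <- stats::kmeans(x, 2, nstart = 5)
  agreement <- max(
    mean((l1 == 1) == (km$cluster == 1)),
    mean((l1 == 1) == (km$cluster == 2))
  )
  expect_equal(agreement, 1)
  expect_equal(attr(l1, "inertia"), km$tot.withinss, tolerance = 1e-6)
})

test_that("labels are canonical: cluster 1 is the largest", {
  withr::local_seed(9)
  x <- rbind(
    matrix(stats::rnorm(10, 0, 0.1), 5),
    matrix(stats::rnorm(60, 5, 0.1), 30)
  )
  labels <- cluster_total_set(x, 2, n_repeats = 3, seed = 2)
  expect_gt(sum(labels == 1), sum(labels == 2))
})

test_that("positive fractions count positives per cluster", {
  labels <- structure(c(1L, 1L, 1L, 1L, 2L, 2L), k = 2L)
  expect_equal(cluster_positive_fraction(labels, positive = 1L), c(0.25, 0))
  expect_equal(cluster_positive_fraction(labels, positive = 5:6), c(0, 1))
})

test_that("size-weighted positive fractions conserve the overall positive rate", {
  withr::local_seed(21)
  labels <- structure(sample.int(4, 200, replace = TRUE), k = 4L)
  positive <- sample.int(200, 37)
  p <- cluster_positive_fraction(labels, positive)
  sizes <- tabulate(labels, 4)
  expect_equal(sum(p * sizes) / 200, 37 / 200, tolerance = 1e-12)
})

test_that("empty clusters warn and are marked fully contaminated", {
  labels <- structure(c(1L, 1L, 3L), k = 3L)
  expect_warning(p <- cluster_positive_fraction(labels, 1L), "empty")
  expect_equal(p[2], 1)
})

test_that("negative harvesting follows the contamination ranking", {
  labels <- structure(c(rep(1L, 100), rep(2L, 100)), k = 2L)
  positive <- c(1L, 101:120) # p = (0.01, 0.20)
  n <- build_negative_set(labels, positive, n_select = 1)
  expect_setequal(as.integer(n), setdiff(1:100, 1L))
  expect_equal(attr(n, "selected_clusters"), 1L)
  expect_length(intersect(n, positive), 0L)
})

test_that("ties in contamination prefer the larger cluster", {
  labels <- structure(c(rep(1L, 10), rep(2L, 20)), k = 2L)
  n <- build_negative_set(labels, positive = integer(0), n_select = 1)
  expect_equal(attr(n, "selected_clusters"), 2L)
  # equal sizes fall back to the lower cluster id
  labels2 <- structure(c(rep(1L, 10), rep(2L, 10)), k = 2L)
  n2 <- build_negative_set(labels2, positive = integer(0), n_select = 1)
  expect_equal(attr(n2, "selected_clusters"), 1L)
})

test_that("an all-positive selection is a hard error", {
  labels <- structure(c(1L, 1L, 2L, 2L, 2L), k = 2L)
  expect_error(build_negative_set(labels, positive = 1:5, n_select = 1), "n_select")
})

test_that("the three-point silhouette example matches the hand computation", {
  f <- matrix(c(0, 0.1, 1), ncol = 1)
  s <- silhouette_score(f, c(1L, 1L, 2L))
  expect_equal(as.numeric(s), (0.9 + 0.8 / 0.9 + 0) / 3, tolerance = 1e-12)
  expect_equal(attr(s, "per_sample"), c(0.9, 0.8 / 0.9, 0), tolerance = 1e-12)
})

test_that("silhouette matches the brute-force oracle and the cluster package", {
  withr::local_seed(29)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    x <- matrix(stats::rnorm(n * 3), n)
    labels <- sample.int(3, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    mine <- as.numeric(silhouette_score(x, labels))
    expect_equal(mine, oracle_silhouette(x, labels), tolerance = 1e-9)
    if (requireNamespace("cluster", quietly = TRUE) && min(table(labels)) > 1) {
      ref <- mean(cluster::silhouette(labels, stats::dist(x))[, "sil_width"])
      expect_equal(mine, ref, tolerance = 1e-9)
    }
  }
})

test_that("coincident clusters score non-positive, separated blobs near one", {
  x <- matrix(rep(c(0, 0), each = 10), ncol = 1)
  expect_lte(as.numeric(silhouette_score(x, rep(1:2, each = 10))), 0)
  withr::local_seed(1)
  y <- rbind(
    matrix(stats::rnorm(40, 0, 0.01), 20),
    matrix(stats::rnorm(40, 100, 0.01), 20)
  )
  expect_gt(as.numeric(silhouette_score(y, rep(1:2, each = 20))), 0.99)
})

test_that("silhouette rejects single-cluster labelings and respects subsampling", {
  x <- matrix(stats::rnorm(20), 10)
  expect_error(silhouette_score(x, rep(1L, 10)), "two clusters")
  withr::local_seed(2)
  big <- matrix(stats::rnorm(400), 200)
  labels <- rep(1:2, 100)
  s1 <- silhouette_score(big, labels, subsample = 50, seed = 4)
  s2 <- silhouette_score(big, labels, subsample = 50, seed = 4)
  expect_identical(s1, s2)
})

test_that("silhouette-guided selection finds the planted cluster count", {
  withr::local_seed(41)
  x <- rbind(
    matrix(stats::rnorm(100, 0, 0.3), 50),
    matrix(stats::rnorm(100, 6, 0.3), 50)
  )
  ks <- select_k(x, 2:6, n_repeats = 3, seed = 5)
  expect_equal(ks$best_k, 2L)
  expect_equal(nrow(ks$curve), 5L)
  ks2 <- select_k(x, 2:6, n_repeats = 3, seed = 5)
  expect_identical(ks$curve, ks2$curve)
  # silhouette at the true K dominates silhouette at twice the true K
  sc <- ks$curve$silhouette
  expect_gte(sc[ks$curve$k == 2], sc[ks$curve$k == 4])
})

test_that("end-to-end sampling keeps the partition invariants", {
  bb <- small_bundle(seed = 3)
  part <- sample_negatives(bb$bundle, k = 2, seed = 11)
  expect_length(intersect(part$negative_idx, part$positive_idx), 0L)
  expect_equal(nrow(part$pairs), 60 * 40)
  sizes <- tabulate(part$labels, 2)
  sel <- part$selected_clusters
  n_pos_in_sel <- sum(part$labels[part$positive_idx] %in% sel)
  expect_equal(length(part$negative_idx) + n_pos_in_sel, sum(sizes[sel]))
  expect_true(all(part$p >= 0 & part$p <= 1))
})

test_that("negative sets and sidecars survive a write/read round trip", {
  bb <- small_bundle(seed = 3, n_mirna = 15, n_disease = 10, n_positive = 25)
  part <- sample_negatives(bb$bundle, k = 2, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_negatives(part, path)
  back <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  expect_equal(nrow(back), length(part$negative_idx))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$k, 2L)
  expect_equal(side$n_negatives, nrow(back))
})
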