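test_that("the three-node worked example reproduces the hand computation", {
  ont <- tiny_ontology()
  sem <- semantic_similarity(ont, c("R", "d1", "d2"), delta = 0.5)
  expect_equal(sem$SS1["d1", "d2"], 1 / 3, tolerance = 1e-12)
  expect_equal(sem$SS2["d1", "d2"], 0, tolerance = 1e-12)
  expect_equal(sem$SS["d1", "d2"], 1 / 6, tolerance = 1e-12)
  expect_equal(sem$SS1["d1", "d1"], 1)
})

test_that("semantic similarity matches the brute-force oracle on random DAGs", {
  withr::local_seed(23)
  for (rep in 1:25) {
    edges <- random_dag_edges(sample(5:15, 1))
    nodes <- sort(unique(c(edges$parent, edges$child)))
    ont <- disease_ontology(edges)
    sem <- semantic_similarity(ont, nodes, delta = 0.5)
    oracle <- oracle_semantic(edges, nodes, delta = 0.5)
    expect_equal(unname(sem$SS1), unname(oracle$SS1), tolerance = 1e-12)
    expect_equal(unname(sem$SS2), unname(oracle$SS2), tolerance = 1e-12)
    expect_equal(unname(sem$SS), unname(oracle$SS), tolerance = 1e-12)
  }
})

test_that("recursive contributions equal delta^(shortest ancestor path)", {
  withr::local_seed(31)
  for (rep in 1:10) {
    edges <- random_dag_edges(10)
    ont <- disease_ontology(edges)
    for (d in sample(ont$nodes, 3)) {
      dag <- dag_terms(ont, d)
      d1 <- pumda:::semantic_contribution_d1(ont, dag, d, 0.5)
      # shortest directed path from each term down to d, by BFS
      dist <- stats::setNames(rep(Inf, length(dag)), dag)
      dist[d] <- 0
      repeat {
        changed <- FALSE
        for (i in seq_len(nrow(edges))) {
          p <- edges$parent[i]
          k <- edges$child[i]
          if (p %in% dag && k %in% dag && dist[k] + 1 < dist[p]) {
            dist[p] <- dist[k] + 1
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      expect_equal(unname(d1[dag]), unname(0.5^dist[dag]))
    }
  }
})

test_that("diseases without a DAG get zero similarity to everything", {
  ont <- tiny_ontology()
  sem <- semantic_similarity(ont, c("d1", "d2", "unmapped disease"))
  expect_equal(unname(sem$SS[, "unmapped disease"]), rep(0, 3))
  expect_equal(unname(sem$SS["unmapped disease", ]), rep(0, 3))
})

test_that("adding a shared ancestor never decreases pairwise similarity", {
  base <- tibble::tibble(parent = c("r1", "r2"), child = c("d1", "d2"))
  more <- dplyr::bind_rows(base, tibble::tibble(parent = "top", child = c("r1", "r2")))
  s0 <- semantic_similarity(disease_ontology(base), c("d1", "d2"))$SS1["d1", "d2"]
  s1 <- semantic_similarity(disease_ontology(more), c("d1", "d2"))$SS1["d1", "d2"]
  expect_gte(s1, s0)
})

test_that("delta outside (0,1) is rejected", {
  ont <- tiny_ontology()
  expect_error(semantic_similarity(ont, "d1", delta = 1), "delta")
  expect_error(semantic_similarity(ont, "d1", delta = 0), "delta")
})

test_that("kernel similarity reproduces the hand-computed value", {
  g <- gipk_similarity(rbind(c(1, 0), c(0, 1)), gamma_prime = 1)
  expect_equal(g[1, 2], exp(-2), tolerance = 1e-12)
  expect_equal(diag(g), c(1, 1), ignore_attr = TRUE)
})

test_that("identical profiles have similarity one", {
  g <- gipk_similarity(rbind(c(1, 1, 0), c(1, 1, 0)))
  expect_equal(g[1, 2], 1)
})

test_that("doubling the bandwidth prior squares off-diagonal entries", {
  withr::local_seed(3)
  profiles <- matrix(rbinom(40, 1, 0.4), nrow = 5)
  g1 <- gipk_similarity(profiles, gamma_prime = 1)
  g2 <- gipk_similarity(profiles, gamma_prime = 2)
  expect_equal(g2, g1^2, tolerance = 1e-12)
})

test_that("kernel is equivariant under profile permutation", {
  withr::local_seed(8)
  profiles <- matrix(rbinom(60, 1, 0.3), nrow = 6)
  perm <- sample(6)
  g <- gipk_similarity(profiles)
  gp <- gipk_similarity(profiles[perm, ])
  expect_equal(unname(gp), unname(g[perm, perm]), tolerance = 1e-12)
})

test_that("degenerate all-zero profiles return the identity with a warning", {
  expect_warning(g <- gipk_similarity(matrix(0, 3, 4)), "identity")
  expect_equal(unname(g), diag(3))
})

test_that("non-binary profiles are rejected", {
  expect_error(gipk_similarity(rbind(c(0.5, 1))), "binary")
})

test_that("integration keeps the primary value and falls back on zeros", {
  primary <- rbind(c(0.4, 0), c(0, 0))
  fallback <- rbind(c(0.9, 0.9), c(0.9, 0.7))
  ids <- integrate_similarity(primary, fallback)
  expect_equal(ids[1, 1], 0.4)
  expect_equal(ids[1, 2], 0.9)
  expect_equal(ids[2, ], c(0.9, 0.7)) # all-zero primary row = fallback row
  expect_error(integrate_similarity(primary, diag(3)), "shape")
})

test_that("pair features concatenate disease block then miRNA block", {
  at <- association_table(
    tibble::tibble(mirna = c("m1", "m2"), disease = c("d1", "d2")),
    mirna_index = c("m1", "m2", "m3", "m4"),
    disease_index = c("d1", "d2", "d3")
  )
  b <- similarity_bundle(at)
  expect_equal(feature_length(b), 7L)
  f <- pair_features(b, tibble::tibble(mirna = "m2", disease = "d3"))
  expect_equal(ncol(f), 7L)
  expect_equal(unname(f[1, 1:3]), unname(b$IDS["d3", ]))
  expect_equal(unname(f[1, 4:7]), unname(b$IMS["m2", ]))
  expect_true(startsWith(colnames(f)[1], "d:"))
  expect_true(startsWith(colnames(f)[4], "m:"))
})

test_that("all similarity matrices are symmetric with entries in [0,1]", {
  bb <- small_bundle(seed = 13)
  b <- bb$bundle
  for (nm in c("SS", "GD", "GM", "IDS", "IMS")) {
    m <- b[[nm]]
    expect_lt(max(abs(m - t(m))), 1e-12)
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("similarity matrices survive a CSV round trip", {
  bb <- small_bundle(seed = 19, n_mirna = 12, n_disease = 8, n_positive = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_similarity_matrix(bb$bundle$IDS, path)
  back <- read_similarity_matrix(path)
  expect_equal(back, bb$bundle$IDS, tolerance = 1e-12)
})
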