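#' Disease semantic similarity over MeSH-style DAGs
#'
#' Implements the two classical semantic-similarity models and their
#' average. Model 1 assigns each term `t` in a disease's DAG a
#' contribution that decays by a factor `delta` per generation away from
#' the disease (computed by the recursive max rule over children, which on
#' a general DAG is a dynamic program over topological order). Model 2
#' weights a term by how rare it is across all modeled diseases' DAGs:
#' `-log(n DAGs containing t / Nd)`. Each model scores a disease pair by
#' the contributions of shared DAG terms relative to the two diseases'
#' total semantic values; the final score is the elementwise mean of the
#' two models. Diseases absent from the ontology have empty DAGs and get
#' all-zero rows.
#'
#' @param ontology a [disease_ontology()].
#' @param diseases character vector: the Nd modeled diseases (also the
#'   denominator of model 2's rarity term, not the ontology node count).
#' @param delta semantic contribution decay factor, in (0, 1). Default 0.5,
#'   the convention of the method this model follows.
#' @param log_base base of the logarithm in model 2; natural log by default.
#' @return an object of class `semantic_similarity`: list with Nd x Nd
#'   matrices `SS1`, `SS2`, `SS`, semantic values `DV1`, `DV2`, the
#'   per-disease contribution maps `D1` (named list), and `delta`.
#' @export
semantic_similarity <- function(ontology, diseases, delta = 0.5,
                                log_base = exp(1)) {
  stopifnot_scalar_number(delta, "delta")
  if (delta <= 0 || delta >= 1) rlang::abort("`delta` must lie in (0, 1)")
  diseases <- as.character(diseases)
  nd <- length(diseases)

  dags <- lapply(diseases, function(d) dag_terms(ontology, d))
  names(dags) <- diseases
  d1 <- lapply(diseases, function(d) semantic_contribution_d1(ontology, dags[[d]], d, delta))
  names(d1) <- diseases

  terms <- unlist(dags)
  terms <- if (is.null(terms)) character(0) else sort(unique(terms), method = "radix")
  presence <- matrix(0, length(terms), nd, dimnames = list(terms, diseases))
  contrib1 <- presence
  for (j in seq_len(nd)) {
    t_j <- dags[[j]]
    if (length(t_j) == 0L) next
    presence[t_j, j] <- 1
    contrib1[t_j, j] <- d1[[j]][t_j]
  }
  # Model 2 contribution of a term is disease-independent: rarity across
  # the modeled diseases' DAGs.
  n_dags_with_term <- rowSums(presence)
  d2_term <- -log(n_dags_with_term / nd, base = log_base)
  contrib2 <- presence * d2_term

  dv1 <- colSums(contrib1)
  dv2 <- colSums(contrib2)

  ss1 <- pairwise_shared_score(contrib1, presence, dv1)
  ss2 <- pairwise_shared_score(contrib2, presence, dv2)
  ss <- (ss1 + ss2) / 2
  structure(
    list(
      SS1 = ss1, SS2 = ss2, SS = ss,
      DV1 = dv1, DV2 = dv2, D1 = d1,
      D2_term = stats::setNames(as.numeric(d2_term), terms),
      delta = delta, diseases = diseases
    ),
    class = "semantic_similarity"
  )
}

# Recursive max rule: contribution of the disease itself is 1; any other
# DAG term contributes delta times the best contribution among its
# children inside the DAG. Solved by fixed-point iteration (terminates in
# at most |T(D)| sweeps because contributions only propagate upward).
semantic_contribution_d1 <- function(ontology, dag, disease, delta) {
  if (length(dag) == 0L) return(stats::setNames(numeric(0), character(0)))
  key <- match_term(ontology, disease)
  vals <- stats::setNames(rep(0, length(dag)), dag)
  vals[key] <- 1
  edges <- ontology$edges
  edges <- edges[edges$parent %in% dag & edges$child %in% dag, , drop = FALSE]
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      cand <- delta * vals[[edges$child[i]]]
      if (cand > vals[[edges$parent[i]]]) {
        vals[[edges$parent[i]]] <- cand
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  vals
}

# Score(i, j) = sum over shared terms of (contrib[, i] + contrib[, j]),
# normalized by DV[i] + DV[j]. Sharing is decided by DAG membership, not
# by nonzero contribution (model 2 contributions can legitimately be 0).
pairwise_shared_score <- function(contrib, presence, dv) {
  a <- crossprod(contrib, presence) # a[i, j] = sum_t contrib[t, i] * [t in T(j)]
  num <- a + t(a)
  den <- outer(dv, dv, "+")
  out <- ifelse(den > 0, num / den, 0)
  dimnames(out) <- dimnames(a)
  out
}

#' Gaussian interaction profile kernel similarity
#'
#' Similarity between binary association profiles:
#' `exp(-gamma * ||IP(i) - IP(j)||^2)`, with the bandwidth `gamma`
#' normalized by the mean squared profile norm so that a prior bandwidth
#' `gamma_prime = 1` adapts to the density of the association matrix.
#' Used for diseases (profiles = columns of the association matrix) and
#' miRNAs (profiles = rows) alike.
#'
#' @param profiles matrix with one binary profile per row.
#' @param gamma_prime positive bandwidth prior; default 1.
#' @return symmetric kernel matrix with unit diagonal.
#' @export
gipk_similarity <- function(profiles, gamma_prime = 1) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 1L) rlang::abort("need at least one profile")
  if (!all(profiles %in% c(0, 1))) rlang::abort("profiles must be binary (0/1)")
  stopifnot_scalar_number(gamma_prime, "gamma_prime")
  if (gamma_prime <= 0) rlang::abort("`gamma_prime` must be positive")
  norms <- rowSums(profiles^2)
  if (all(norms == 0)) {
    rlang::warn("all profiles are all-zero; kernel bandwidth undefined, returning identity")
    out <- diag(nrow(profiles))
    dimnames(out) <- list(rownames(profiles), rownames(profiles))
    return(out)
  }
  gamma <- gamma_prime / mean(norms)
  sq <- outer(norms, norms, "+") - 2 * tcrossprod(profiles)
  sq[sq < 0] <- 0
  out <- exp(-gamma * sq)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- list(rownames(profiles), rownames(profiles))
  out
}

#' Integrate a primary similarity with a kernel fallback
#'
#' Elementwise selection: where the primary similarity (semantic for
#' diseases, functional for miRNAs) is nonzero it is kept; where it is
#' zero — e.g. disease pairs with no shared DAG terms, or diseases absent
#' from the ontology — the interaction-profile kernel value fills in.
#'
#' @param primary,fallback matrices of identical shape.
#' @return matrix of the same shape.
#' @export
integrate_similarity <- function(primary, fallback) {
  if (!identical(dim(primary), dim(fallback))) {
    rlang::abort("`primary` and `fallback` must have identical shape")
  }
  out <- ifelse(primary != 0, primary, fallback)
  dimnames(out) <- dimnames(fallback)
  out
}

#' Compute the full similarity bundle for a dataset
#'
#' One call that builds the association matrix and all similarity
#' matrices: disease semantic similarity `SS` (zero matrix when no
#' ontology is given), interaction-profile kernels `GD` (diseases) and
#' `GM` (miRNAs), the supplied miRNA functional similarity `FS` (zero
#' matrix when absent, so the integrated miRNA similarity falls back to
#' the kernel), and the integrated matrices `IDS` and `IMS` that the
#' pair features are drawn from.
#'
#' @param associations an [association_table()].
#' @param ontology optional [disease_ontology()].
#' @param functional_sim optional miRNA functional-similarity matrix with
#'   id dimnames; rows/columns are aligned to the miRNA index, ids absent
#'   from the matrix get zero similarity (kernel fallback).
#' @param delta,log_base passed to [semantic_similarity()].
#' @param gamma_prime passed to [gipk_similarity()].
#' @return an object of class `similarity_bundle`.
#' @export
similarity_bundle <- function(associations, ontology = NULL,
                              functional_sim = NULL, delta = 0.5,
                              log_base = exp(1), gamma_prime = 1) {
  md <- build_association_matrix(associations)
  mi <- rownames(md)
  di <- colnames(md)
  gd <- gipk_similarity(t(md), gamma_prime = gamma_prime)
  gm <- gipk_similarity(md, gamma_prime = gamma_prime)
  if (is.null(ontology)) {
    ss <- matrix(0, length(di), length(di), dimnames = list(di, di))
    sem <- NULL
  } else {
    sem <- semantic_similarity(ontology, di, delta = delta, log_base = log_base)
    ss <- sem$SS
  }
  fs <- matrix(0, length(mi), length(mi), dimnames = list(mi, mi))
  if (!is.null(functional_sim)) {
    functional_sim <- as.matrix(functional_sim)
    common <- intersect(mi, rownames(functional_sim))
    fs[common, common] <- functional_sim[common, common]
  }
  structure(
    list(
      MD = md, SS = ss, GD = gd, GM = gm, FS = fs,
      IDS = integrate_similarity(ss, gd),
      IMS = integrate_similarity(fs, gm),
      semantic = sem,
      mirna_index = mi, disease_index = di,
      delta = delta, gamma_prime = gamma_prime
    ),
    class = "similarity_bundle"
  )
}

#' @export
print.similarity_bundle <- function(x, ...) {
  cat(sprintf(
    "# Similarity bundle: %d miRNAs, %d diseases, feature length %d\n",
    length(x$mirna_index), length(x$disease_index), feature_length(x)
  ))
  invisible(x)
}

#' Length of a pair feature vector
#'
#' A miRNA-disease pair is represented by the concatenation of its
#' disease's integrated-similarity row (length Nd) and its miRNA's
#' integrated-similarity row (length Nm), so the feature length is
#' Nd + Nm.
#'
#' @param bundle a [similarity_bundle()].
#' @return integer.
#' @export
feature_length <- function(bundle) {
  length(bundle$disease_index) + length(bundle$mirna_index)
}

#' Pair feature matrix
#'
#' Builds feature vectors `F(d, m) = (FD(d), FM(m))` for the requested
#' pairs: the disease block first (row of `IDS`), then the miRNA block
#' (row of `IMS`).
#'
#' @param bundle a [similarity_bundle()].
#' @param pairs tibble with columns `mirna` and `disease`; `NULL` means
#'   every pair of the grid in pair-index order (miRNA-major).
#' @return numeric matrix, one row per pair, with column names prefixed
#'   `d:` / `m:` by block.
#' @export
pair_features <- function(bundle, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- pair_grid(bundle$mirna_index, bundle$disease_index)
  }
  i_d <- match(pairs$disease, bundle$disease_index)
  i_m <- match(pairs$mirna, bundle$mirna_index)
  if (anyNA(i_d) || anyNA(i_m)) rlang::abort("pair id not found in bundle indices")
  out <- cbind(bundle$IDS[i_d, , drop = FALSE], bundle$IMS[i_m, , drop = FALSE])
  dimnames(out) <- list(
    pair_key(pairs$mirna, pairs$disease),
    c(paste0("d:", bundle$disease_index), paste0("m:", bundle$mirna_index))
  )
  out
}

#' Write / read a similarity matrix as CSV with id headers
#'
#' First row and first column carry the entity ids; values use `.` as the
#' decimal mark.
#'
#' @param m matrix with id dimnames.
#' @param path file path.
#' @return `path` (writer, invisibly) or the matrix (reader).
#' @export
write_similarity_matrix <- function(m, path) {
  df <- tibble::as_tibble(as.data.frame(m), rownames = "id")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
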