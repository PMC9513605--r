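#' Specify a synthetic miRNA-disease benchmark
#'
#' The generator emulates the three inputs of the real pipeline — a curated
#' association list, a MeSH-style disease ontology, and a miRNA functional
#' similarity matrix — at configurable scale, with planted structure:
#'
#' * entities carry heavy-tailed (Zipf) activity weights, as in curated
#'   association databases where a few hub miRNAs account for most records;
#' * miRNAs and diseases belong to latent blocks (disease blocks are the
#'   subtrees under the ontology root), and positives fall preferentially
#'   in block-matched pairs, so similar diseases share miRNAs and the
#'   interaction-profile kernels are informative;
#' * a known fraction of unlabeled pairs are "hidden positives": unlabeled
#'   pairs whose miRNA and disease are each already active, which places
#'   them near true positives in feature space — exactly the contamination
#'   that clustering-based negative sampling is meant to avoid. The ground
#'   truth list is returned so sampler purity is testable.
#'
#' @param n_mirna,n_disease entity counts.
#' @param n_positive number of verified associations to plant.
#' @param ontology_depth maximum depth of the random disease tree (root at
#'   depth 0).
#' @param ontology_branching maximum children per ontology node.
#' @param contamination_rate fraction of unlabeled pairs that are hidden
#'   positives; must lie in \[0, 1).
#' @param seed integer seed; the whole dataset is a pure function of the spec.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_mirna = 60, n_disease = 40, n_positive = 150,
                           ontology_depth = 4, ontology_branching = 3,
                           contamination_rate = 0.05, seed = 1) {
  spec <- list(
    n_mirna = as.integer(n_mirna), n_disease = as.integer(n_disease),
    n_positive = as.integer(n_positive),
    ontology_depth = as.integer(ontology_depth),
    ontology_branching = as.integer(ontology_branching),
    contamination_rate = contamination_rate, seed = as.integer(seed)
  )
  if (spec$n_mirna < 1L || spec$n_disease < 1L) {
    rlang::abort("need at least one miRNA and one disease")
  }
  if (spec$n_positive > spec$n_mirna * spec$n_disease) {
    rlang::abort("requested positives exceed the miRNA x disease grid")
  }
  assert_prob(spec$contamination_rate, "contamination_rate", open_right = TRUE)
  if (spec$ontology_depth < 1L || spec$ontology_branching < 1L) {
    rlang::abort("ontology depth and branching must be >= 1")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic dataset with known structure
#'
#' @param spec a [synthetic_spec()].
#' @return a list of class `synthetic_dataset` with elements
#'   `associations` (an [association_table()] over the full entity
#'   indices), `ontology` (a [disease_ontology()] covering every
#'   disease), `functional_similarity` (block-structured miRNA similarity
#'   matrix, synthetic stand-in for a MISIM-style resource),
#'   `hidden_positives` (tibble of unlabeled pairs that are secretly
#'   positive-like), and `spec`.
#' @export
generate_synthetic_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  withr::with_seed(spec$seed, generate_synthetic_impl(spec))
}

generate_synthetic_impl <- function(spec) {
  nm <- spec$n_mirna
  nd <- spec$n_disease
  mirna_ids <- sprintf("mir-%04d", seq_len(nm))
  disease_ids <- sprintf("disease-%04d", seq_len(nd))

  ont <- random_disease_tree(disease_ids, spec$ontology_depth, spec$ontology_branching)
  disease_block <- ont$block
  n_block <- max(disease_block)
  mirna_block <- sample.int(n_block, nm, replace = TRUE)

  # Zipf(1) activity weights over a random entity permutation: hub entities
  # collect most associations, tail entities may stay inactive.
  w_m <- 1 / sample.int(nm)
  w_d <- 1 / sample.int(nd)
  block_match <- outer(mirna_block, disease_block, "==")
  w_pair <- outer(w_m, w_d) * ifelse(block_match, 1, 0.1)
  pos_idx <- sample.int(nm * nd, spec$n_positive, prob = as.vector(w_pair))
  pos <- arrayInd(pos_idx, c(nm, nd))
  associations <- association_table(
    tibble::tibble(mirna = mirna_ids[pos[, 1]], disease = disease_ids[pos[, 2]]),
    mirna_index = mirna_ids, disease_index = disease_ids
  )

  # Hidden positives: uncurated true associations. Drawn from the same
  # planted pair-weight distribution as the verified positives, restricted
  # to unlabeled pairs both of whose endpoints already have at least one
  # verified association — pairs sitting in the same feature-space region
  # as the positives.
  is_pos <- logical(nm * nd)
  is_pos[pos_idx] <- TRUE
  n_unlabeled <- nm * nd - spec$n_positive
  n_hidden <- round_half_up(spec$contamination_rate * n_unlabeled)
  active_m <- mirna_block * 0L
  active_m[unique(pos[, 1])] <- 1L
  active_d <- disease_block * 0L
  active_d[unique(pos[, 2])] <- 1L
  eligible <- which(!is_pos & as.vector(outer(active_m == 1L, active_d == 1L, "&")))
  if (length(eligible) < n_hidden) {
    rlang::warn("fewer eligible unlabeled pairs than requested hidden positives; topping up uniformly")
    extra <- setdiff(which(!is_pos), eligible)
    hidden_idx <- c(eligible, sample(extra, n_hidden - length(eligible)))
  } else {
    hidden_idx <- sort(sample(eligible, n_hidden, prob = as.vector(w_pair)[eligible]))
  }
  hid <- arrayInd(hidden_idx, c(nm, nd))
  hidden_positives <- tibble::tibble(
    mirna = mirna_ids[hid[, 1]], disease = disease_ids[hid[, 2]]
  )

  # Synthetic MISIM-style functional similarity, derived the way the real
  # resource is: best-match-average of disease semantic similarity over the
  # two miRNAs' planted disease sets. miRNAs without any association have
  # no defined functional similarity (zero row, kernel fallback downstream).
  sem <- semantic_similarity(ont$ontology, disease_ids)
  fs <- wang_functional_similarity(
    build_association_matrix(associations), sem$SS
  )

  structure(
    list(
      associations = associations,
      ontology = ont$ontology,
      functional_similarity = fs,
      hidden_positives = hidden_positives,
      mirna_block = stats::setNames(mirna_block, mirna_ids),
      disease_block = stats::setNames(disease_block, disease_ids),
      spec = spec
    ),
    class = "synthetic_dataset"
  )
}

# Best-match-average functional similarity between miRNAs: each disease
# associated with one miRNA is matched to its most semantically similar
# disease of the other miRNA, and the matches are averaged both ways.
# Pairs where either miRNA has no associations score 0.
wang_functional_similarity <- function(md, ss) {
  nm <- nrow(md)
  sizes <- rowSums(md)
  active <- which(sizes > 0)
  # maxsim[d, j] = best semantic similarity between disease d and any
  # disease associated with miRNA j
  maxsim <- matrix(0, ncol(md), nm)
  for (j in active) {
    maxsim[, j] <- do.call(pmax, as.data.frame(ss[, md[j, ] == 1L, drop = FALSE]))
  }
  bma <- md %*% maxsim # bma[i, j] = sum of best matches of i's diseases in j
  fs <- (bma + t(bma)) / outer(sizes, sizes, "+")
  fs[sizes == 0, ] <- 0
  fs[, sizes == 0] <- 0
  diag(fs) <- as.numeric(sizes > 0)
  dimnames(fs) <- list(rownames(md), rownames(md))
  fs
}

# Random disease forest: `branching` disjoint category trees (the planted
# blocks, mirroring the disjoint top-level category trees of MeSH — disease
# pairs across categories share no ancestors, so their semantic similarity
# is exactly zero and integration falls back to the interaction-profile
# kernel). Within a category each term attaches to a uniformly chosen node
# that still has child capacity and depth < max depth.
random_disease_tree <- function(disease_ids, depth, branching) {
  n <- length(disease_ids)
  order_ids <- sample(disease_ids)
  n_cat <- min(branching, n)
  category <- stats::setNames(rep_len(seq_len(n_cat), n), order_ids)
  parent <- stats::setNames(rep(NA_character_, n), order_ids)
  node_depth <- stats::setNames(rep(0L, n), order_ids)
  n_children <- stats::setNames(rep(0L, n), order_ids)
  for (cat in seq_len(n_cat)) {
    members <- order_ids[category[order_ids] == cat]
    for (i in seq_along(members)[-1]) {
      placed <- members[seq_len(i - 1L)]
      open <- placed[n_children[placed] < branching & node_depth[placed] < depth]
      if (length(open) == 0L) open <- placed[n_children[placed] < branching]
      if (length(open) == 0L) open <- placed
      p <- if (length(open) == 1L) open else sample(open, 1L)
      parent[[members[i]]] <- p
      node_depth[[members[i]]] <- node_depth[[p]] + 1L
      n_children[[p]] <- n_children[[p]] + 1L
    }
  }
  child_ids <- names(parent)[!is.na(parent)]
  parent_ids <- unname(parent[!is.na(parent)])
  edges <- tibble::tibble(parent = parent_ids, child = child_ids)
  ontology <- disease_ontology(edges, nodes = disease_ids)
  list(ontology = ontology, block = unname(category[disease_ids]))
}
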