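# Independent brute-force oracles and small fixture builders. These are
# deliberately written in plain-loop style, sharing no code with the
# package implementation they check.

# --- semantic similarity oracle ------------------------------------------

# Ancestor set by naive repeated expansion over the edge list.
oracle_dag_terms <- function(edges, node) {
  if (!node %in% c(edges$parent, edges$child)) {
    return(node)
  }
  terms <- node
  repeat {
    more <- edges$parent[edges$child %in% terms]
    new_terms <- union(terms, more)
    if (length(new_terms) == length(terms)) {
      return(new_terms)
    }
    terms <- new_terms
  }
}

# Memoized recursion straight from the contribution definition.
oracle_d1 <- function(edges, dag, disease, delta) {
  memo <- new.env()
  rec <- function(d) {
    if (!is.null(memo[[d]])) {
      return(memo[[d]])
    }
    val <- if (d == disease) {
      1
    } else {
      kids <- edges$child[edges$parent == d]
      kids <- kids[kids %in% dag]
      if (length(kids) == 0L) 0 else max(sapply(kids, function(k) delta * rec(k)))
    }
    memo[[d]] <- val
    val
  }
  sapply(stats::setNames(dag, dag), rec)
}

# Full semantic-similarity oracle over a disease set.
oracle_semantic <- function(edges, diseases, delta = 0.5) {
  nd <- length(diseases)
  dags <- lapply(diseases, function(d) {
    t_d <- oracle_dag_terms(edges, d)
    if (length(t_d) == 1L && !d %in% c(edges$parent, edges$child)) character(0) else t_d
  })
  names(dags) <- diseases
  d1 <- lapply(diseases, function(d) {
    if (length(dags[[d]]) == 0L) {
      return(numeric(0))
    }
    oracle_d1(edges, dags[[d]], d, delta)
  })
  names(d1) <- diseases
  count_in_dags <- function(t) sum(sapply(dags, function(s) t %in% s))
  d2_of <- function(t) -log(count_in_dags(t) / nd)
  dv1 <- sapply(d1, sum)
  dv2 <- sapply(dags, function(s) if (length(s) == 0L) 0 else sum(sapply(s, d2_of)))
  ss1 <- ss2 <- matrix(0, nd, nd, dimnames = list(diseases, diseases))
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      shared <- intersect(dags[[i]], dags[[j]])
      if (length(shared) == 0L) next
      num1 <- sum(d1[[i]][shared]) + sum(d1[[j]][shared])
      den1 <- dv1[[i]] + dv1[[j]]
      if (den1 > 0) ss1[i, j] <- num1 / den1
      num2 <- sum(sapply(shared, d2_of)) + sum(sapply(shared, d2_of))
      den2 <- dv2[[i]] + dv2[[j]]
      if (den2 > 0) ss2[i, j] <- num2 / den2
    }
  }
  list(SS1 = ss1, SS2 = ss2, SS = (ss1 + ss2) / 2)
}

# Random DAG edge list: node i may take parents among nodes 1..i-1.
# Always contains at least the edge n01 -> n02 so the node set is nonempty.
random_dag_edges <- function(n_nodes, p_edge = 0.3) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  parent <- ids[1]
  child <- ids[2]
  for (i in 2:n_nodes) {
    for (j in 1:(i - 1)) {
      if (stats::runif(1) < p_edge && !(i == 2 && j == 1)) {
        parent <- c(parent, ids[j])
        child <- c(child, ids[i])
      }
    }
  }
  tibble::tibble(parent = parent, child = child)
}

# --- silhouette oracle ----------------------------------------------------

oracle_silhouette <- function(x, labels, p = 2) {
  x <- as.matrix(x)
  n <- nrow(x)
  dist_of <- function(i, j) sum(abs(x[i, ] - x[j, ])^p)^(1 / p)
  sc <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) {
      sc[i] <- 0
      next
    }
    a <- mean(sapply(setdiff(own, i), function(j) dist_of(i, j)))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      members <- which(labels == cl)
      b <- min(b, mean(sapply(members, function(j) dist_of(i, j))))
    }
    sc[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(sc)
}

# --- ranking oracle -------------------------------------------------------

oracle_concordance_auroc <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (sp in pos) {
    for (sn in neg) {
      total <- total + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  total / (length(pos) * length(neg))
}

# --- shared fixtures ------------------------------------------------------

# The three-node worked example: root R with children d1, d2; all three
# modeled diseases.
tiny_ontology <- function() {
  disease_ontology(tibble::tibble(parent = c("R", "R"), child = c("d1", "d2")))
}

small_dataset <- function(seed = 42, ...) {
  generate_synthetic_dataset(synthetic_spec(seed = seed, ...))
}

small_bundle <- function(seed = 42, ...) {
  ds <- small_dataset(seed = seed, ...)
  list(
    dataset = ds,
    bundle = similarity_bundle(ds$associations, ds$ontology, ds$functional_similarity)
  )
}

key_of <- function(pairs) paste(pairs$mirna, pairs$disease, sep = "\r")
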