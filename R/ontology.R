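#' Construct a disease ontology
#'
#' A rooted-DAG vocabulary of disease terms (MeSH-style). Each modeled
#' disease `D` owns a per-disease DAG: `D` together with all of its
#' ancestors, written `T(D)` in the semantic-similarity literature. The
#' constructor verifies acyclicity and fails loudly, naming one cycle,
#' when the edge relation is not a DAG.
#'
#' @param edges data frame with character columns `parent` and `child`.
#' @param nodes optional character vector of terms; defaults to all ids
#'   seen in `edges`. Isolated terms (no edges) may be added here.
#' @return an object of class `disease_ontology`.
#' @export
disease_ontology <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0L && !all(c("parent", "child") %in% names(edges))) {
    rlang::abort("`edges` needs columns `parent` and `child`")
  }
  if (nrow(edges) == 0L) {
    edges <- tibble::tibble(parent = character(), child = character())
  }
  edges <- dplyr::distinct(
    dplyr::transmute(edges,
      parent = as.character(.data$parent),
      child = as.character(.data$child)
    )
  )
  nodes <- sort(unique(c(nodes, edges$parent, edges$child)), method = "radix")
  cyc <- find_cycle(edges, nodes)
  if (!is.null(cyc)) {
    rlang::abort(sprintf(
      "ontology edges contain a cycle: %s", paste(cyc, collapse = " -> ")
    ))
  }
  anc <- ancestor_closure(edges, nodes)
  structure(
    list(nodes = nodes, edges = edges, ancestors = anc),
    class = "disease_ontology"
  )
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat(sprintf(
    "# Disease ontology: %d terms, %d parent->child edges\n",
    length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

# Depth-first search for a directed cycle; returns the cycle as a node
# sequence or NULL when the edge relation is acyclic.
find_cycle <- function(edges, nodes) {
  adj <- split(edges$child, factor(edges$parent, levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 open, 2 done
  stack <- character(0)
  visit <- function(v) {
    state[[v]] <<- 1L
    stack <<- c(stack, v)
    for (w in adj[[v]]) {
      if (state[[w]] == 1L) {
        i <- match(w, stack)
        return(c(stack[i:length(stack)], w))
      }
      if (state[[w]] == 0L) {
        res <- visit(w)
        if (!is.null(res)) return(res)
      }
    }
    state[[v]] <<- 2L
    stack <<- stack[-length(stack)]
    NULL
  }
  for (v in nodes) {
    if (state[[v]] == 0L) {
      res <- visit(v)
      if (!is.null(res)) return(res)
    }
  }
  NULL
}

# Named list: for every node, the set T(node) = node plus all ancestors,
# computed by propagating parent sets in reverse topological order.
ancestor_closure <- function(edges, nodes) {
  parents <- split(edges$parent, factor(edges$child, levels = nodes))
  closure <- stats::setNames(vector("list", length(nodes)), nodes)
  get <- function(v) {
    if (!is.null(closure[[v]])) return(closure[[v]])
    acc <- v
    for (p in parents[[v]]) acc <- union(acc, get(p))
    closure[[v]] <<- acc
    acc
  }
  for (v in nodes) get(v)
  closure
}

#' Per-disease DAG node set
#'
#' Returns `T(D)`: the term itself plus every ancestor in the ontology.
#' A term absent from the ontology has an empty DAG (length-0 result);
#' its semantic-similarity rows are zero and integration falls back to
#' the interaction-profile kernel.
#'
#' @param ontology a [disease_ontology()].
#' @param term character term id (matched exactly after lowercasing and
#'   whitespace collapse, mirroring how association-table disease names
#'   are mapped onto ontology terms).
#' @return character vector of terms (possibly empty).
#' @export
dag_terms <- function(ontology, term) {
  key <- match_term(ontology, term)
  if (is.na(key)) return(character(0))
  ontology$ancestors[[key]]
}

# Exact match after lowercasing + whitespace collapse.
match_term <- function(ontology, term) {
  norm <- function(x) stringr::str_squish(tolower(x))
  i <- match(norm(term), norm(ontology$nodes))
  if (is.na(i)) NA_character_ else ontology$nodes[[i]]
}

#' Read a disease ontology
#'
#' Two dialects are supported: `edge_list`, a TSV of (parent, child)
#' term pairs; and `mesh_tree_numbers`, a TSV of (term, dot-separated
#' tree code) rows in which ancestry is derived by truncating the last
#' code segment (e.g. `C04.111` is a child of the term owning `C04`). A
#' tree code whose parent code is owned by no term raises a warning and
#' the node is kept as a root.
#'
#' @param path file path (TSV, header auto-detected for `term`/`parent`
#'   style names).
#' @param dialect `"edge_list"` or `"mesh_tree_numbers"`.
#' @return a [disease_ontology()].
#' @export
read_ontology <- function(path, dialect = c("edge_list", "mesh_tree_numbers")) {
  dialect <- match.arg(dialect)
  df <- readr::read_tsv(
    path,
    col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(df) == 0L) rlang::abort(sprintf("empty ontology file: %s", path))
  if (ncol(df) < 2L) rlang::abort("ontology file needs two columns")
  header_names <- c("parent", "child", "term", "code", "tree_number", "disease")
  if (all(tolower(unlist(df[1, 1:2])) %in% header_names)) df <- df[-1, ]
  if (dialect == "edge_list") {
    return(disease_ontology(tibble::tibble(parent = df[[1]], child = df[[2]])))
  }
  codes <- tibble::tibble(term = df[[1]], code = df[[2]])
  owner <- stats::setNames(codes$term, codes$code)
  parent_code <- sub("\\.[^.]*$", "", codes$code)
  has_parent <- parent_code != codes$code
  parent_term <- ifelse(has_parent, unname(owner[parent_code]), NA_character_)
  orphan <- has_parent & is.na(parent_term)
  if (any(orphan)) {
    rlang::warn(sprintf(
      "%d orphan tree code(s) (no term owns the parent code); kept as roots: %s",
      sum(orphan), paste(utils::head(codes$code[orphan], 5), collapse = ", ")
    ))
  }
  keep <- has_parent & !is.na(parent_term)
  disease_ontology(
    tibble::tibble(parent = parent_term[keep], child = codes$term[keep]),
    nodes = unique(codes$term)
  )
}

#' Write an ontology edge list as TSV
#'
#' @param ontology a [disease_ontology()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  readr::write_tsv(ontology$edges, path, col_names = FALSE)
  invisible(path)
}
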