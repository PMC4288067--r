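# Independent oracles and random-case generators shared across the suite.
# Oracles deliberately bypass the package's index machinery: distances come
# from igraph BFS, path sets from exhaustive simple-path enumeration, and
# DAG levels from recursive longest-path search.

# random sparse undirected concept graph (Erdos-Renyi flavored, leaf types)
random_test_graph <- function(n, p = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(p)) p <- min(1, 2 / n + stats::runif(1, 0, 2 / n))
  ids <- sprintf("V%03d", seq_len(n))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- if (any(keep)) {
    tibble::tibble(
      id_a = ids[pairs[keep, 1]], id_b = ids[pairs[keep, 2]],
      relations = "rel", vocabularies = "TST"
    )
  } else {
    NULL
  }
  concept_graph(
    tibble::tibble(id = ids, name = ids, semantic_types = "TTOY"),
    edges
  )
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[c("id_a", "id_b")],
    directed = FALSE,
    vertices = graph$concepts["id"]
  )
}

# BFS distance oracle: full matrix of true hop distances
bfs_distance_oracle <- function(graph) {
  igraph::distances(as_igraph(graph))
}

# exhaustive simple-path enumeration oracle (small graphs only)
all_simple_paths_oracle <- function(graph, u, v, min_edges = 0) {
  ig <- as_igraph(graph)
  ps <- igraph::all_simple_paths(ig, from = u, to = v, mode = "all")
  ps <- lapply(ps, function(p) names(p))
  ps[lengths(ps) - 1 >= min_edges]
}

# random semantic-type DAG: edges only from later to earlier ranks (acyclic)
random_test_dag <- function(n_types, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n_types))
  edges <- NULL
  if (n_types >= 2) {
    pairs <- t(utils::combn(n_types, 2))
    keep <- stats::runif(nrow(pairs)) < 2 / n_types
    if (any(keep)) {
      # child has the larger rank; parent the smaller => child -> parent DAG
      edges <- tibble::tibble(
        child = ids[pairs[keep, 2]], parent = ids[pairs[keep, 1]]
      )
    }
  }
  isolated <- setdiff(ids, c(edges$child, edges$parent))
  list(edges = edges, isolated = isolated, ids = ids)
}

# longest child-ward path to a leaf, by plain recursion
dag_level_oracle <- function(edges, ids) {
  children_of <- if (is.null(edges)) {
    list()
  } else {
    split(edges$child, edges$parent)
  }
  memo <- new.env()
  level <- function(t) {
    if (!is.null(memo[[t]])) {
      return(memo[[t]])
    }
    kids <- children_of[[t]]
    out <- if (is.null(kids) || length(kids) == 0) {
      1L
    } else {
      1L + max(vapply(kids, level, integer(1)))
    }
    memo[[t]] <- out
    out
  }
  stats::setNames(vapply(ids, level, integer(1)), ids)
}

# brute-force fold enrichment straight from the printed formula
fold_enrichment_oracle <- function(t_pairs, s_pairs, alpha) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tk <- key(t_pairs$id_a, t_pairs$id_b)
  sk <- unique(key(s_pairs$id_a, s_pairs$id_b))
  sp <- intersect(sk, tk)
  m <- max(1, floor(alpha * length(tk) / 100 + 0.5))
  hits <- length(intersect(sp, tk[seq_len(m)]))
  (hits / length(sp)) / (m / length(tk))
}

# bare relationship-matrix object for threshold/export tests
new_rel_matrix_for_test <- function(values, measure = "closeness") {
  if (is.null(dimnames(values))) {
    dimnames(values) <- list(
      paste0("r", seq_len(nrow(values))), paste0("c", seq_len(ncol(values)))
    )
  }
  structure(list(values = values, measure = measure),
            class = "relationship_matrix")
}
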