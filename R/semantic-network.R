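# Semantic-type DAG: reverse-topological levels and the concept weight g.

#' Construct a semantic-type network
#'
#' Semantic types (e.g. "Disease or Syndrome", TUI-style ids in the UMLS)
#' are organized in a directed acyclic graph from abstract roots down to
#' concrete leaves. Each type gets a reverse topological level `h`: leaves
#' have level 1, and iteratively removing all current leaves increments the
#' level — equivalently, `h(t)` is one plus the longest child-ward path from
#' `t` to a leaf. The level feeds the concept weight `g = 1/h` used by the
#' closeness measure, so concrete types weigh more than abstract ones.
#'
#' @param child_parent_edges A data frame with columns `child` and `parent`
#'   (the child is the more concrete type), or `NULL` for an edgeless
#'   network.
#' @param isolated_types Character vector of type ids that take part in no
#'   edge (all become leaves at level 1).
#' @return An object of class `semantic_type_network`: list with `type_ids`,
#'   the `edges` tibble, and `levels`, a named integer vector of `h` values.
#' @examples
#' net <- semantic_type_network(
#'   tibble::tibble(child = c("S", "M"), parent = c("M", "R"))
#' )
#' net$levels # S=1, M=2, R=3
#' @export
semantic_type_network <- function(child_parent_edges = NULL,
                                  isolated_types = character()) {
  if (is.null(child_parent_edges)) {
    edges <- tibble::tibble(child = character(), parent = character())
  } else {
    edges <- tibble::as_tibble(child_parent_edges)
    if (!all(c("child", "parent") %in% names(edges))) {
      rlang::abort("`child_parent_edges` needs columns `child` and `parent`.")
    }
    edges <- dplyr::distinct(edges, .data$child, .data$parent)
  }
  type_ids <- sort(unique(c(edges$child, edges$parent, isolated_types)))
  if (length(type_ids) == 0) {
    rlang::abort("semantic-type network must contain at least one type")
  }
  net <- structure(
    list(type_ids = type_ids, edges = edges, levels = NULL),
    class = "semantic_type_network"
  )
  net$levels <- compute_reverse_topological_levels(net)
  net
}

#' @export
print.semantic_type_network <- function(x, ...) {
  cat(sprintf(
    "<semantic_type_network> %d types, %d child->parent edges, max level %d\n",
    length(x$type_ids), nrow(x$edges), max(x$levels)
  ))
  invisible(x)
}

#' Read a semantic-type network from TSV
#'
#' Expects a two-column TSV (`child`, `parent`, header row) and optionally a
#' plain list of isolated type ids, one per line.
#'
#' @param edge_path Path to the child/parent TSV.
#' @param isolated_path Optional path to a one-id-per-line text file.
#' @return A [semantic_type_network()].
#' @export
load_type_network <- function(edge_path, isolated_path = NULL) {
  if (!file.exists(edge_path)) {
    rlang::abort(sprintf("file not found: %s", edge_path))
  }
  edges <- readr::read_tsv(
    edge_path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(c("child", "parent"), names(edges))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s: missing column(s) %s", edge_path, paste(missing, collapse = ", ")
    ))
  }
  isolated <- character()
  if (!is.null(isolated_path)) {
    isolated <- readr::read_lines(isolated_path, progress = FALSE)
    isolated <- isolated[nzchar(isolated)]
  }
  semantic_type_network(edges, isolated)
}

#' Reverse topological levels by iterative leaf removal
#'
#' All types with no remaining children receive the current level, are
#' removed, and the level increments; a type's level therefore equals one
#' plus the length of the longest child-ward path from it to a leaf.
#'
#' @param network A `semantic_type_network` (its `levels` field is ignored;
#'   this is the function that produces it).
#' @return Named integer vector mapping each type id to its level `h >= 1`.
#' @export
compute_reverse_topological_levels <- function(network) {
  ids <- network$type_ids
  levels <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  # children remaining per type
  n_children <- stats::setNames(integer(length(ids)), ids)
  if (nrow(network$edges) > 0) {
    cnt <- table(network$edges$parent)
    n_children[names(cnt)] <- as.integer(cnt)
  }
  parents_of <- split(network$edges$parent, network$edges$child)
  level <- 1L
  frontier <- names(n_children)[n_children == 0]
  while (length(frontier) > 0) {
    levels[frontier] <- level
    removed_parents <- unlist(parents_of[frontier], use.names = FALSE)
    if (length(removed_parents) > 0) {
      cnt <- table(removed_parents)
      n_children[names(cnt)] <- n_children[names(cnt)] - as.integer(cnt)
    }
    frontier <- names(n_children)[n_children == 0 & is.na(levels)]
    level <- level + 1L
  }
  if (anyNA(levels)) {
    cyclic <- names(levels)[is.na(levels)][1]
    rlang::abort(sprintf(
      "cycle in semantic-type network involving type %s", cyclic
    ))
  }
  levels
}

#' Semantic weight of a concept
#'
#' For a concept with semantic types at levels `h_1, ..., h_m`, the weight is
#' `1 / min(h_i)`: when a concept carries several types, the type closest to
#' the leaves (most concrete) is used. Leaf-typed concepts get weight 1;
#' abstract concepts get progressively smaller weights.
#'
#' @param semantic_types Character vector of the concept's semantic-type ids.
#' @param network A [semantic_type_network()].
#' @return A weight in `(0, 1]`.
#' @export
concept_weight <- function(semantic_types, network) {
  if (length(semantic_types) == 0) {
    rlang::abort("concept has no semantic types")
  }
  unknown <- setdiff(semantic_types, names(network$levels))
  if (length(unknown) > 0) {
    rlang::abort(sprintf(
      "unknown semantic type(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  1 / min(network$levels[semantic_types])
}

# named vector of weights for every concept in a graph; UNTYPED maps to
# level 1 when the network does not define it
graph_concept_weights <- function(graph, network) {
  levels <- network$levels
  if (!"UNTYPED" %in% names(levels)) {
    levels <- c(levels, UNTYPED = 1L)
  }
  vapply(graph$concepts$semantic_types, function(tt) {
    unknown <- setdiff(tt, names(levels))
    if (length(unknown) > 0) {
      rlang::abort(sprintf(
        "unknown semantic type(s): %s", paste(unknown, collapse = ", ")
      ))
    }
    1 / min(levels[tt])
  }, numeric(1)) |>
    stats::setNames(graph$concepts$id)
}
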