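# Code-generated fixtures: the fold-enrichment worked example and the toy
# graphs used throughout the test suite and documentation.

#' Worked fold-enrichment example
#'
#' A small hypothetical disease-pair study: a ranked list `t` of ten
#' unordered pairs over concepts A..F (descending synthetic weights 10..1
#' encode the rank order) and a reference set `s` of six confirmed pairs,
#' two of which involve concepts absent from the ranking. The intersection
#' has four pairs, the fold enrichment at alpha = 20 is 1.25, and at
#' alpha = 100 it is exactly 1.
#'
#' @return A list with elements `t` ([ranked_relations()]) and `s`
#'   ([relation_set()]).
#' @examples
#' ex <- worked_example()
#' fold_enrichment(ex$t, ex$s, 20)
#' @export
worked_example <- function() {
  t_raw <- tibble::tibble(
    id_a = c("A", "A", "B", "E", "A", "B", "B", "D", "D", "C"),
    id_b = c("B", "C", "D", "F", "E", "C", "E", "E", "F", "D"),
    weight = 10:1
  )
  s_raw <- tibble::tibble(
    id_a = c("A", "B", "A", "E", "H", "E"),
    id_b = c("C", "D", "E", "F", "G", "H")
  )
  list(t = ranked_relations(t_raw), s = relation_set(s_raw))
}

#' Toy concept graphs
#'
#' Small canonical graphs used for worked examples and tests: a star
#' (center `c`, leaves `l1`..`l3`), a path `a-b-c`, a 4-cycle ("square")
#' `a-b-c-d-a`, and a two-component graph (an edge `a-b` plus isolated `z`).
#' All concepts carry the single leaf-level semantic type of
#' [toy_type_network()], so every concept weight is 1.
#'
#' @return Named list of [concept_graph()] objects: `star`, `path`,
#'   `square`, `two_component`.
#' @export
toy_graphs <- function() {
  mk <- function(ids, from, to) {
    concept_graph(
      tibble::tibble(
        id = ids, name = paste("toy", ids), semantic_types = "TTOY"
      ),
      if (length(from)) {
        tibble::tibble(
          id_a = from, id_b = to,
          relations = "associated_with", vocabularies = "TOY"
        )
      } else {
        NULL
      }
    )
  }
  list(
    star = mk(
      c("c", "l1", "l2", "l3"), c("c", "c", "c"), c("l1", "l2", "l3")
    ),
    path = mk(c("a", "b", "c"), c("a", "b"), c("b", "c")),
    square = mk(
      c("a", "b", "c", "d"), c("a", "b", "c", "a"), c("b", "c", "d", "d")
    ),
    two_component = mk(c("a", "b", "z"), "a", "b")
  )
}

#' Toy semantic-type networks
#'
#' `toy_type_network()` is a single leaf type `TTOY` (level 1, weight 1
#' everywhere). `fixture_type_network()` is a ten-type, three-level DAG
#' shaped like a miniature thesaurus type system: six leaves under three
#' mid-level types under one root (plus one isolated leaf type).
#'
#' @return A [semantic_type_network()].
#' @export
toy_type_network <- function() {
  semantic_type_network(NULL, isolated_types = "TTOY")
}

#' @rdname toy_type_network
#' @export
fixture_type_network <- function() {
  semantic_type_network(
    tibble::tibble(
      child = c("T101", "T102", "T103", "T104", "T105", "T106",
                "T201", "T202", "T203"),
      parent = c("T201", "T201", "T202", "T202", "T203", "T203",
                 "T301", "T301", "T301")
    ),
    isolated_types = "T107"
  )
}
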