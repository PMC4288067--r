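# Concept-graph container, loaders and the synthetic power-law generator.

#' Construct a concept graph
#'
#' A concept graph models a biomedical thesaurus such as the UMLS
#' Metathesaurus: every concept (CUI) is a vertex and every semantic
#' association between two concepts is an undirected labeled edge. This is
#' the object the hub-labeling index ([build_index()]) and all downstream
#' relationship machinery operate on.
#'
#' Parallel input edges between the same unordered concept pair are collapsed
#' into a single edge whose relation-label and vocabulary sets are merged.
#' Self-loops are rejected: the path semantics of the index require a simple
#' graph.
#'
#' @param concepts A data frame with columns `id` (unique concept identifier,
#'   CUI-style), `name` (preferred display string) and `semantic_types`
#'   (either a list column of character vectors or a `";"`-joined string);
#'   every concept must carry at least one semantic type.
#' @param edges A data frame with columns `id_a`, `id_b` and optionally
#'   `relations` / `vocabularies` (list columns of character vectors, or
#'   plain character columns). Endpoints must appear in `concepts`.
#' @return An object of class `concept_graph`: a list with tibbles `concepts`
#'   and `edges` (endpoints stored sorted, one row per unordered pair) and a
#'   named adjacency list `adj` mapping each id to its lexicographically
#'   sorted neighbor ids.
#' @examples
#' g <- concept_graph(
#'   tibble::tibble(
#'     id = c("C1", "C2"), name = c("Aspirin", "Pain"),
#'     semantic_types = c("T121", "T184")
#'   ),
#'   tibble::tibble(id_a = "C1", id_b = "C2", relations = "may_treat")
#' )
#' n_concepts(g)
#' @export
concept_graph <- function(concepts, edges = NULL) {
  concepts <- tibble::as_tibble(concepts)
  if (!all(c("id", "name") %in% names(concepts))) {
    rlang::abort("`concepts` needs columns `id` and `name`.")
  }
  if (anyDuplicated(concepts$id)) {
    dup <- concepts$id[duplicated(concepts$id)][1]
    rlang::abort(sprintf("duplicate concept id: %s", dup))
  }
  if (!"semantic_types" %in% names(concepts)) {
    rlang::abort("`concepts` needs a `semantic_types` column.")
  }
  if (!is.list(concepts$semantic_types)) {
    concepts$semantic_types <- stringr::str_split(concepts$semantic_types, ";")
  }
  concepts$semantic_types <- purrr::map(concepts$semantic_types, function(x) {
    x <- unique(x[!is.na(x) & nzchar(x)])
    sort(x)
  })
  if (any(lengths(concepts$semantic_types) == 0)) {
    bad <- concepts$id[lengths(concepts$semantic_types) == 0]
    rlang::abort(sprintf(
      "concept(s) without semantic types: %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  concepts <- dplyr::arrange(concepts, .data$id)

  if (is.null(edges) || nrow(tibble::as_tibble(edges)) == 0) {
    edges <- tibble::tibble(
      id_a = character(), id_b = character(),
      relations = list(), vocabularies = list()
    )
  } else {
    edges <- tibble::as_tibble(edges)
    if (!all(c("id_a", "id_b") %in% names(edges))) {
      rlang::abort("`edges` needs columns `id_a` and `id_b`.")
    }
    if (!"relations" %in% names(edges)) edges$relations <- "unknown"
    if (!"vocabularies" %in% names(edges)) edges$vocabularies <- "unknown"
    if (!is.list(edges$relations)) edges$relations <- as.list(edges$relations)
    if (!is.list(edges$vocabularies)) {
      edges$vocabularies <- as.list(edges$vocabularies)
    }
    if (any(edges$id_a == edges$id_b)) {
      bad <- edges$id_a[edges$id_a == edges$id_b][1]
      rlang::abort(sprintf("self-loop on concept %s is not allowed", bad))
    }
    known <- edges$id_a %in% concepts$id & edges$id_b %in% concepts$id
    if (!all(known)) {
      miss <- unique(c(edges$id_a, edges$id_b))
      miss <- setdiff(miss, concepts$id)
      rlang::abort(sprintf(
        "edge endpoint(s) not in concept table: %s",
        paste(utils::head(miss, 5), collapse = ", ")
      ))
    }
    # canonical unordered storage, then merge parallel edges
    lo <- pmin(edges$id_a, edges$id_b)
    hi <- pmax(edges$id_a, edges$id_b)
    edges$id_a <- lo
    edges$id_b <- hi
    edges <- edges |>
      dplyr::group_by(.data$id_a, .data$id_b) |>
      dplyr::summarise(
        relations = list(clean_labels(unlist(.data$relations))),
        vocabularies = list(clean_labels(unlist(.data$vocabularies))),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$id_a, .data$id_b)
  }

  structure(
    list(
      concepts = concepts,
      edges = edges,
      adj = build_adjacency(concepts$id, edges)
    ),
    class = "concept_graph"
  )
}

clean_labels <- function(x) {
  x <- unique(x[!is.na(x) & nzchar(x)])
  if (length(x) == 0) x <- "unknown"
  sort(x)
}

build_adjacency <- function(ids, edges) {
  adj <- stats::setNames(vector("list", length(ids)), ids)
  adj[] <- list(character())
  if (nrow(edges) > 0) {
    ends <- c(edges$id_a, edges$id_b)
    nbrs <- c(edges$id_b, edges$id_a)
    sp <- split(nbrs, ends)
    adj[names(sp)] <- lapply(sp, function(v) sort(unique(v)))
  }
  adj
}

#' @export
print.concept_graph <- function(x, ...) {
  cat(sprintf(
    "<concept_graph> %d concepts, %d edges\n",
    n_concepts(x), n_edges(x)
  ))
  invisible(x)
}

#' Number of concepts / edges in a concept graph
#' @param graph A `concept_graph`.
#' @return An integer count.
#' @export
n_concepts <- function(graph) nrow(graph$concepts)

#' @rdname n_concepts
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Relation labels on the edge joining two concepts
#'
#' @param graph A `concept_graph`.
#' @param u,v Concept ids.
#' @return Character vector of relation labels, or `character(0)` when the
#'   pair is not adjacent.
#' @export
edge_relations <- function(graph, u, v) {
  lo <- min(u, v)
  hi <- max(u, v)
  i <- which(graph$edges$id_a == lo & graph$edges$id_b == hi)
  if (length(i) == 0) {
    return(character())
  }
  graph$edges$relations[[i]]
}

#' Read a concept graph from the generic TSV dialect
#'
#' The generic dialect is two UTF-8 TSV files with header rows: a concept
#' table with columns `id`, `name`, `semantic_types` (semicolon-joined) and
#' an edge table with columns `id_a`, `id_b`, `relation_label`,
#' `vocabulary`. Duplicate undirected pairs are merged; an edge mentioning a
#' concept absent from the concept table is an error.
#'
#' @param concept_table_path,edge_table_path Paths to the two TSV files.
#' @return A [concept_graph()].
#' @seealso [write_edge_list()] for the inverse, [load_rrf()] for UMLS RRF
#'   input.
#' @export
load_edge_list <- function(concept_table_path, edge_table_path) {
  for (p in c(concept_table_path, edge_table_path)) {
    if (!file.exists(p)) rlang::abort(sprintf("file not found: %s", p))
  }
  concepts <- read_tsv_checked(
    concept_table_path, c("id", "name", "semantic_types")
  )
  edges <- read_tsv_checked(
    edge_table_path, c("id_a", "id_b", "relation_label", "vocabulary")
  )
  edges <- dplyr::rename(
    edges, relations = "relation_label", vocabularies = "vocabulary"
  )
  concept_graph(concepts, edges)
}

read_tsv_checked <- function(path, cols) {
  tbl <- suppressWarnings(readr::read_tsv(
    path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s: missing column(s) %s", path, paste(missing, collapse = ", ")
    ))
  }
  bad <- which(rowSums(is.na(tbl[cols[1:2]])) > 0)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "%s: malformed row at line %d", path, bad[1] + 1L
    ))
  }
  tbl
}

#' Write a concept graph in the generic TSV dialect
#'
#' @param graph A `concept_graph`.
#' @param concept_table_path,edge_table_path Output paths.
#' @return The graph, invisibly. `load_edge_list()` on the written files
#'   reproduces the graph (canonical ordering).
#' @export
write_edge_list <- function(graph, concept_table_path, edge_table_path) {
  concepts <- graph$concepts |>
    dplyr::mutate(
      semantic_types = purrr::map_chr(
        .data$semantic_types, paste, collapse = ";"
      )
    )
  readr::write_tsv(concepts, concept_table_path, progress = FALSE)
  edges <- graph$edges |>
    dplyr::mutate(
      relation_label = purrr::map_chr(.data$relations, paste, collapse = ";"),
      vocabulary = purrr::map_chr(.data$vocabularies, paste, collapse = ";")
    ) |>
    dplyr::select("id_a", "id_b", "relation_label", "vocabulary")
  readr::write_tsv(edges, edge_table_path, progress = FALSE)
  invisible(graph)
}

#' Read a concept graph from a UMLS RRF subset
#'
#' Parses the pipe-delimited Rich Release Format files of a UMLS
#' Metathesaurus subset: `MRCONSO.RRF` (one vertex per CUI; the display name
#' is the first English preferred atom, falling back to the first atom seen),
#' `MRSTY.RRF` (semantic-type TUIs per CUI; CUIs without a row receive the
#' sentinel type `"UNTYPED"`) and `MRREL.RRF` (edges; the specific `RELA`
#' label is used when present, otherwise the generic `REL`). Only the
#' standard column positions named here are read.
#'
#' @param mrconso_path,mrrel_path,mrsty_path Paths to the three RRF files.
#' @param vocab_filter Optional character vector of source-vocabulary codes
#'   (`SAB`); when given, only atoms and relations from those vocabularies
#'   are retained.
#' @return A [concept_graph()]. MRREL rows naming a CUI absent from MRCONSO
#'   are skipped with a warning (licensed subsets are routinely partial), as
#'   are self-relations.
#' @export
load_rrf <- function(mrconso_path, mrrel_path, mrsty_path,
                     vocab_filter = NULL) {
  for (p in c(mrconso_path, mrrel_path, mrsty_path)) {
    if (!file.exists(p)) rlang::abort(sprintf("file not found: %s", p))
  }
  conso <- read_rrf(mrconso_path, min_cols = 15)
  if (!is.null(vocab_filter)) {
    conso <- conso[conso[[12]] %in% vocab_filter, , drop = FALSE]
  }
  if (nrow(conso) == 0) rlang::abort("MRCONSO yields no concepts")
  cui <- conso[[1]]
  pref <- conso[[2]] == "ENG" & conso[[3]] == "P"
  # first English preferred atom per CUI; fallback: first atom of any kind
  ord <- order(!pref, seq_len(nrow(conso)))
  first <- !duplicated(cui[ord])
  names_tbl <- tibble::tibble(id = cui[ord][first], name = conso[[15]][ord][first])

  sty <- read_rrf(mrsty_path, min_cols = 2, allow_empty = TRUE)
  types <- stats::setNames(vector("list", nrow(names_tbl)), names_tbl$id)
  types[] <- list(character())
  if (nrow(sty) > 0) {
    sp <- split(sty[[2]], sty[[1]])
    keep <- intersect(names(sp), names_tbl$id)
    types[keep] <- sp[keep]
  }
  untyped <- lengths(types) == 0
  if (any(untyped)) {
    rlang::inform(sprintf(
      "%d concept(s) without an MRSTY row; assigned sentinel type UNTYPED",
      sum(untyped)
    ))
    types[untyped] <- list("UNTYPED")
  }
  concepts <- names_tbl
  concepts$semantic_types <- unname(types[concepts$id])

  rel <- read_rrf(mrrel_path, min_cols = 11, allow_empty = TRUE)
  edges <- NULL
  if (nrow(rel) > 0) {
    if (!is.null(vocab_filter)) {
      rel <- rel[rel[[11]] %in% vocab_filter, , drop = FALSE]
    }
    known <- rel[[1]] %in% concepts$id & rel[[5]] %in% concepts$id
    if (any(!known)) {
      rlang::warn(sprintf(
        "skipping %d MRREL row(s) naming CUIs absent from MRCONSO",
        sum(!known)
      ))
      rel <- rel[known, , drop = FALSE]
    }
    rel <- rel[rel[[1]] != rel[[5]], , drop = FALSE]
    if (nrow(rel) > 0) {
      label <- ifelse(nzchar(rel[[8]]) & !is.na(rel[[8]]), rel[[8]], rel[[4]])
      edges <- tibble::tibble(
        id_a = rel[[1]], id_b = rel[[5]],
        relations = label, vocabularies = rel[[11]]
      )
    }
  }
  concept_graph(concepts, edges)
}

read_rrf <- function(path, min_cols, allow_empty = FALSE) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    if (allow_empty) {
      return(tibble::as_tibble(
        matrix(character(), 0, min_cols), .name_repair = "unique_quiet"
      ))
    }
    rlang::abort(sprintf("%s: empty RRF file", path))
  }
  parts <- stringr::str_split(lines, stringr::fixed("|"))
  short <- which(lengths(parts) < min_cols)
  if (length(short) > 0) {
    rlang::abort(sprintf(
      "%s: line %d has %d field(s); expected at least %d",
      path, short[1], lengths(parts)[short[1]], min_cols
    ))
  }
  cols <- lapply(seq_len(min_cols), function(i) {
    vapply(parts, `[[`, character(1), i)
  })
  tibble::as_tibble(
    stats::setNames(cols, paste0("V", seq_len(min_cols)))
  )
}

#' Generate a synthetic power-law concept graph
#'
#' Builds a sparse random graph with a heavy-tailed degree distribution by
#' preferential attachment, mimicking the degree structure of real concept
#' thesauri (a few massive hub concepts, many near-leaves) on which the
#' hub-removal index is effective. Each concept receives one or two semantic
#' types sampled from `type_network`, and each edge a relation label drawn
#' from a small generic vocabulary. The same seed always yields the same
#' graph.
#'
#' @param n_vertices Number of concepts (at least 2).
#' @param mean_degree Target mean degree; the realized edge count is
#'   `round(n_vertices * mean_degree / 2)`.
#' @param type_network A [semantic_type_network()] supplying the semantic
#'   types to sample from.
#' @param seed Integer seed.
#' @return A [concept_graph()] with ids `K0000001`, `K0000002`, ...
#' @export
generate_synthetic_graph <- function(n_vertices, mean_degree, type_network,
                                     seed = 1L) {
  if (!is.numeric(n_vertices) || n_vertices < 2) {
    rlang::abort("`n_vertices` must be at least 2")
  }
  if (length(type_network$type_ids) < 1) {
    rlang::abort("`type_network` must contain at least one type")
  }
  n <- as.integer(n_vertices)
  n_edges <- max(n - 1L, round(n * mean_degree / 2))
  withr_seed(seed, {
    # out-degree sequence: vertex 1 brings no edges, later vertices split
    # n_edges as evenly as possible so the realized count hits the target
    out_seq <- integer(n)
    base <- n_edges %/% (n - 1L)
    extra <- n_edges %% (n - 1L)
    out_seq[2:n] <- base
    if (extra > 0) out_seq[1L + seq_len(extra)] <- base + 1L
    # cap out-degree at the number of earlier vertices
    cap <- pmin(out_seq, seq_len(n) - 1L)
    deficit <- sum(out_seq - cap)
    out_seq <- cap
    while (deficit > 0) {
      room <- which(out_seq < seq_len(n) - 1L)
      take <- utils::head(room, deficit)
      out_seq[take] <- out_seq[take] + 1L
      deficit <- deficit - length(take)
    }
    ig <- igraph::sample_pa(
      n, power = 1, out.seq = out_seq, directed = FALSE,
      algorithm = "psumtree"
    )
    el <- igraph::as_edgelist(ig, names = FALSE)
    ids <- sprintf("K%07d", seq_len(n))
    n_types <- 1L + (stats::runif(n) < 0.3)
    type_pool <- sort(type_network$type_ids)
    sem <- purrr::map(n_types, function(k) {
      sample(type_pool, min(k, length(type_pool)))
    })
    relations <- sample(
      c("associated_with", "related_to", "co_occurs_with", "isa"),
      nrow(el), replace = TRUE
    )
    concept_graph(
      tibble::tibble(
        id = ids,
        name = paste("synthetic concept", seq_len(n)),
        semantic_types = sem
      ),
      tibble::tibble(
        id_a = ids[el[, 1]], id_b = ids[el[, 2]],
        relations = relations, vocabularies = "SYNTH"
      )
    )
  })
}

# run code under a local RNG state seeded deterministically
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' @export
tidy.concept_graph <- function(x, ...) {
  x$edges |>
    dplyr::mutate(
      relations = purrr::map_chr(.data$relations, paste, collapse = ";"),
      vocabularies = purrr::map_chr(.data$vocabularies, paste, collapse = ";")
    )
}

#' @export
glance.concept_graph <- function(x, ...) {
  deg <- lengths(x$adj)
  tibble::tibble(
    n_concepts = n_concepts(x),
    n_edges = n_edges(x),
    mean_degree = mean(deg),
    max_degree = if (length(deg)) max(deg) else 0L
  )
}
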