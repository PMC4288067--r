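# Semantic-weighted closeness R(u,v), relationship/distance matrices,
# thresholding, shared-neighbor weighting and percentile threshold transfer.

#' Semantic-weighted closeness between two concepts
#'
#' The closeness is
#' \deqn{R(u,v) = \sum_{p \in P(u,v)} \prod_{x \in p} g(x)}
#' where `P(u,v)` is the collection of simple paths between `u` and `v`
#' discovered by the kDLS index, excluding paths of length 1 (a lone direct
#' edge is existing knowledge, not a transitive association), and
#' `g(x) = 1/h` is the semantic weight of each vertex on the path, endpoints
#' included. Many short paths through concrete (leaf-level) concepts yield a
#' high closeness; paths through abstract types are down-weighted.
#'
#' @param index A [build_index()] result.
#' @param graph The [concept_graph()] the index was built on.
#' @param network A [semantic_type_network()] supplying levels for `g`.
#' @param u,v Distinct concept ids.
#' @return A non-negative number; 0 when no path of length >= 2 is found.
#' @export
closeness <- function(index, graph, network, u, v) {
  check_indexed(index, c(u, v))
  if (u == v) rlang::abort("closeness is undefined for u == v")
  w <- graph_concept_weights(graph, network)
  closeness_impl(index, u, v, w)
}

closeness_impl <- function(index, u, v, weights) {
  paths <- discover_paths(index, u, v)
  total <- 0
  for (p in paths) {
    if (length(p) >= 3) total <- total + prod(weights[p])
  }
  total
}

new_relationship_matrix <- function(values, measure) {
  structure(list(values = values, measure = measure),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf(
    "<relationship_matrix> %s, %d x %d\n",
    x$measure, nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' @export
dim.relationship_matrix <- function(x) dim(x$values)

#' Relationship matrix between two concept sets
#'
#' Computes the closeness `R` for every pair drawn from `set_a` (rows) and
#' `set_b` (columns). Cells pairing a concept with itself are marked SELF
#' (stored as `NA`) and excluded from thresholding; the measure does not
#' define self-closeness.
#'
#' @inheritParams closeness
#' @param set_a,set_b Non-empty character vectors of concept ids.
#' @return A `relationship_matrix` with `measure = "closeness"`.
#' @export
relationship_matrix <- function(index, graph, network, set_a, set_b) {
  if (length(set_a) == 0 || length(set_b) == 0) {
    rlang::abort("concept sets must be non-empty")
  }
  check_indexed(index, c(set_a, set_b))
  w <- graph_concept_weights(graph, network)
  values <- matrix(
    0, length(set_a), length(set_b), dimnames = list(set_a, set_b)
  )
  for (i in seq_along(set_a)) {
    for (j in seq_along(set_b)) {
      if (set_a[i] == set_b[j]) {
        values[i, j] <- NA_real_ # SELF
      } else {
        values[i, j] <- closeness_impl(index, set_a[i], set_b[j], w)
      }
    }
  }
  new_relationship_matrix(values, "closeness")
}

#' Distance matrix between two concept sets
#'
#' Index-reported hop distances for every pair; unreachable pairs are `Inf`.
#'
#' @inheritParams relationship_matrix
#' @return A `relationship_matrix` with `measure = "distance"`.
#' @export
distance_matrix <- function(index, set_a, set_b) {
  if (length(set_a) == 0 || length(set_b) == 0) {
    rlang::abort("concept sets must be non-empty")
  }
  check_indexed(index, c(set_a, set_b))
  values <- matrix(
    0, length(set_a), length(set_b), dimnames = list(set_a, set_b)
  )
  for (i in seq_along(set_a)) {
    for (j in seq_along(set_b)) {
      values[i, j] <- query_distance(index, set_a[i], set_b[j])
    }
  }
  new_relationship_matrix(values, "distance")
}

#' Convert a closeness matrix to a 0-1 relationship matrix
#'
#' A cell becomes 1 when its closeness is at least `delta` (inclusive);
#' SELF and unreachable cells become 0.
#'
#' @param matrix A closeness-valued `relationship_matrix`.
#' @param delta Threshold.
#' @return A `relationship_matrix` with `measure = "binary"`.
#' @export
binarize <- function(matrix, delta) {
  if (!inherits(matrix, "relationship_matrix") ||
      matrix$measure != "closeness") {
    rlang::abort("`binarize()` needs a closeness-valued relationship matrix")
  }
  v <- matrix$values
  out <- ifelse(!is.na(v) & is.finite(v) & v >= delta, 1, 0)
  new_relationship_matrix(out, "binary")
}

#' Shared-neighbor weighted relations from a 0-1 matrix
#'
#' For every pair of rows (e.g. diseases) of a binary relationship matrix,
#' the weight is the number of columns (e.g. genes) both rows link to. Pairs
#' sharing nothing are omitted; the result is sorted by weight descending
#' with lexicographic tie-break, ready for fold-enrichment validation.
#'
#' @param binary A `relationship_matrix` with `measure = "binary"`.
#' @return A [ranked_relations()] tibble with columns `id_a`, `id_b`,
#'   `weight`.
#' @export
shared_neighbor_weights <- function(binary) {
  if (!inherits(binary, "relationship_matrix") || binary$measure != "binary") {
    rlang::abort("`shared_neighbor_weights()` needs a binary matrix")
  }
  b <- binary$values
  ids <- rownames(b)
  cross <- b %*% t(b)
  pairs <- which(upper.tri(cross) & cross > 0, arr.ind = TRUE)
  ranked_relations(tibble::tibble(
    id_a = ids[pairs[, 1]],
    id_b = ids[pairs[, 2]],
    weight = cross[pairs]
  ))
}

matrix_entries <- function(m) {
  v <- as.vector(m$values)
  v[!is.na(v) & is.finite(v)]
}

#' Transfer a threshold between matrices by percentile matching
#'
#' Finds the threshold for `target` that passes the same fraction of
#' entries as `delta_ref` passes in `reference` — the device used to
#' compare matrices produced by differently scaled closeness measures at
#' equivalent stringency. SELF cells are excluded on both sides.
#'
#' @param reference,target Closeness-valued `relationship_matrix` objects.
#' @param delta_ref Threshold applied to `reference`.
#' @return The matched threshold: the m-th largest target entry where
#'   `m = round(frac * n_target)` and `frac` is the passing fraction in the
#'   reference; when no entry should pass, `max(target) + 1`.
#' @export
percentile_match_threshold <- function(reference, delta_ref, target) {
  for (m in list(reference, target)) {
    if (!inherits(m, "relationship_matrix") || m$measure != "closeness") {
      rlang::abort("both matrices must be closeness-valued")
    }
  }
  ref <- matrix_entries(reference)
  tgt <- matrix_entries(target)
  if (length(ref) == 0 || length(tgt) == 0) {
    rlang::abort("matrices must contain at least one non-SELF entry")
  }
  frac <- mean(ref >= delta_ref)
  m <- round_half_up(frac * length(tgt))
  if (m == 0) {
    return(max(tgt) + 1)
  }
  sort(tgt, decreasing = TRUE)[m]
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' @export
tidy.relationship_matrix <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    row = rep(rownames(v), times = ncol(v)),
    col = rep(colnames(v), each = nrow(v)),
    value = as.vector(v),
    self = rep(rownames(v), times = ncol(v)) ==
      rep(colnames(v), each = nrow(v))
  ) |>
    dplyr::mutate(measure = x$measure)
}

#' @export
glance.relationship_matrix <- function(x, ...) {
  e <- matrix_entries(x)
  tibble::tibble(
    measure = x$measure,
    n_rows = nrow(x$values),
    n_cols = ncol(x$values),
    n_entries = length(e),
    max_value = if (length(e)) max(e) else NA_real_,
    mean_value = if (length(e)) mean(e) else NA_real_
  )
}

#' Export a relationship matrix
#'
#' CSV: row/column ids as headers, unreachable cells as `"inf"`, SELF cells
#' empty — the flat "heatmap" artifact, renderable with any standard
#' heatmap tool. JSON: values plus `measure` metadata.
#'
#' @param matrix A `relationship_matrix`.
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_matrix <- function(matrix, path, format = c("csv", "json")) {
  format <- match.arg(format)
  v <- matrix$values
  if (format == "csv") {
    chr <- matrix(as.character(v), nrow(v), ncol(v))
    chr[is.na(v)] <- ""
    chr[is.infinite(v)] <- "inf"
    df <- as.data.frame(chr, stringsAsFactors = FALSE)
    names(df) <- colnames(v)
    df <- cbind(id = rownames(v), df)
    readr::write_csv(tibble::as_tibble(df), path, progress = FALSE)
  } else {
    jsonlite::write_json(
      list(
        measure = matrix$measure,
        row_ids = rownames(v),
        col_ids = colnames(v),
        values = apply(v, 1, function(r) {
          lapply(r, function(x) {
            if (is.na(x)) "SELF" else if (is.infinite(x)) "inf" else x
          })
        }, simplify = FALSE)
      ),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Heatmap of a relationship or distance matrix
#'
#' @param object A `relationship_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relationship_matrix <- function(object, ...) {
  df <- tidy(object)
  df$value[is.infinite(df$value)] <- NA
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(
      x = NULL, y = NULL, fill = object$measure,
      title = sprintf("%s matrix", object$measure)
    ) +
    ggplot2::theme_minimal()
}
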