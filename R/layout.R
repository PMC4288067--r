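# Deterministic layered coordinates for the shortest-path network between
# two query concepts.

#' Layered layout of a shortest-path collection
#'
#' All paths in the input must have equal length `L` (apply
#' [shortest_subset()] first). Layer `k` collects every vertex at position
#' `k` on any path — i.e. at distance `k` from the source along the
#' shortest paths — and is drawn on a vertical line at `x = k`, members
#' spread at unit spacing, ordered lexicographically and centered at 0.
#' A vertex shared by several paths is drawn once, so shared vertices and
#' edges of the path network are visible.
#'
#' @param shortest A non-empty `path_collection` of equal-length paths.
#' @return An object of class `layered_layout`: list with `source`,
#'   `target`, `layers` (list of id vectors), `nodes` (tibble `id`, `x`,
#'   `y`) and `edges` (tibble `from`, `to`, `relations`).
#' @export
layered_layout <- function(shortest) {
  if (!inherits(shortest, "path_collection")) {
    rlang::abort("`shortest` must be a path_collection")
  }
  if (length(shortest$paths) == 0) {
    rlang::abort("cannot lay out an empty path collection")
  }
  len <- lengths(shortest$paths)
  if (length(unique(len)) != 1) {
    rlang::abort(
      "paths have mixed lengths; apply shortest_subset() before layout"
    )
  }
  n_pos <- len[1]
  layers <- lapply(seq_len(n_pos), function(pos) {
    sort(unique(vapply(shortest$paths, `[[`, character(1), pos)))
  })
  nodes <- purrr::imap_dfr(layers, function(members, pos) {
    m <- length(members)
    tibble::tibble(
      id = members,
      x = pos - 1,
      y = seq_len(m) - (m + 1) / 2
    )
  })
  edge_rows <- purrr::imap_dfr(shortest$paths, function(p, pi) {
    steps <- seq_len(length(p) - 1L)
    tibble::tibble(
      from = p[steps],
      to = p[steps + 1L],
      relations = vapply(
        shortest$relations[[pi]], paste, character(1), collapse = ";"
      )
    )
  })
  edges <- dplyr::distinct(edge_rows) |>
    dplyr::arrange(.data$from, .data$to)
  structure(
    list(
      source = shortest$source, target = shortest$target,
      layers = layers, nodes = nodes, edges = edges
    ),
    class = "layered_layout"
  )
}

#' @export
print.layered_layout <- function(x, ...) {
  cat(sprintf(
    "<layered_layout> %s -> %s: %d layers, %d nodes, %d edges\n",
    x$source, x$target, length(x$layers), nrow(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Serialize a layered layout
#'
#' JSON carries nodes with coordinates and edges with relation labels in a
#' fixed key order (so serializing a parsed layout is byte-identical); DOT
#' is a rank-constrained digraph renderable by Graphviz.
#'
#' @param layout A [layered_layout()].
#' @param format `"json"` or `"dot"`.
#' @return A single string.
#' @export
export_layout <- function(layout, format = c("json", "dot")) {
  format <- match.arg(format)
  if (format == "json") {
    as.character(jsonlite::toJSON(
      list(
        source = layout$source,
        target = layout$target,
        layers = layout$layers,
        nodes = layout$nodes,
        edges = layout$edges
      ),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    ))
  } else {
    lines <- c(
      "digraph shortest_paths {",
      "  rankdir=LR;",
      "  node [shape=box];"
    )
    for (i in seq_along(layout$layers)) {
      members <- paste(sprintf("\"%s\";", layout$layers[[i]]), collapse = " ")
      lines <- c(lines, sprintf("  { rank=same; %s }", members))
    }
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [label=\"%s\"];",
      layout$edges$from, layout$edges$to, layout$edges$relations
    ))
    paste(c(lines, "}", ""), collapse = "\n")
  }
}

#' Parse a JSON-serialized layered layout
#'
#' @param json A string produced by [export_layout()] with
#'   `format = "json"`.
#' @return A [layered_layout()].
#' @export
layout_from_json <- function(json) {
  parsed <- tryCatch(
    jsonlite::fromJSON(json, simplifyVector = TRUE),
    error = function(e) rlang::abort("not a valid layout JSON document")
  )
  needed <- c("source", "target", "layers", "nodes", "edges")
  if (!all(needed %in% names(parsed))) {
    rlang::abort("layout JSON is missing required fields")
  }
  structure(
    list(
      source = parsed$source,
      target = parsed$target,
      layers = lapply(parsed$layers, as.character),
      nodes = tibble::as_tibble(parsed$nodes),
      edges = tibble::as_tibble(parsed$edges)
    ),
    class = "layered_layout"
  )
}

#' @export
tidy.layered_layout <- function(x, ...) x$nodes

#' Plot a layered shortest-path network
#'
#' @param object A [layered_layout()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.layered_layout <- function(object, ...) {
  coords <- object$nodes
  seg <- object$edges |>
    dplyr::left_join(coords, by = c(from = "id")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(coords, by = c(to = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y),
      color = "grey60"
    ) +
    ggplot2::geom_label(
      data = coords,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id)
    ) +
    ggplot2::labs(
      x = "distance from source", y = NULL,
      title = sprintf("Shortest paths %s → %s", object$source, object$target)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid.minor = ggplot2::element_blank()
    )
}
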