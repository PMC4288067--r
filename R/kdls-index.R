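# Hub-removal k-neighborhood distance labeling (kDLS): index construction
# and label-based distance / path queries.

#' Hub removal order
#'
#' The indexing algorithm repeatedly removes the vertex with the highest
#' residual degree (ties broken by lexicographically smallest id) — the
#' "hubs" of a power-law graph go first, which is what makes the labeling
#' compact on thesaurus-like graphs.
#'
#' @param graph A [concept_graph()].
#' @return Character vector: all concept ids in removal order.
#' @export
hub_removal_order <- function(graph) {
  ids <- graph$concepts$id
  n <- length(ids)
  if (n == 0) {
    return(character())
  }
  adj <- adjacency_int(graph)
  deg <- lengths(adj)
  active <- rep(TRUE, n)
  order_out <- integer(n)
  for (step in seq_len(n)) {
    deg_masked <- ifelse(active, deg, -1L)
    hub <- which.max(deg_masked) # first max = lexicographically smallest id
    order_out[step] <- hub
    active[hub] <- FALSE
    nb <- adj[[hub]]
    nb <- nb[active[nb]]
    deg[nb] <- deg[nb] - 1L
  }
  ids[order_out]
}

# integer adjacency in lexicographic id order (ids are stored sorted, so
# integer order coincides with lexicographic order)
adjacency_int <- function(graph) {
  ids <- graph$concepts$id
  lapply(graph$adj[ids], function(v) match(v, ids))
}

#' Build a kDLS index
#'
#' For each hub in removal order, a breadth-first traversal of depth at most
#' `k` runs in the current residual graph (the hub itself still present) and
#' writes a record `(hub, distance, predecessor)` into the label of every
#' vertex reached — including the hub's own self-record at distance 0. The
#' hub is then deleted from the residual graph and the next hub broadcasts.
#' Neighbor expansion is in lexicographic id order, so predecessors (the
#' BFS-tree neighbor one step closer to the hub) are deterministic.
#'
#' Because the first vertex of any shortest path to be removed broadcasts
#' while the whole path is still intact, comparing two labels recovers the
#' exact graph distance whenever it is at most `k`, and at least one
#' reconstructed path attains it.
#'
#' @param graph A [concept_graph()].
#' @param k Neighborhood radius (hops) of each broadcast; default 6.
#' @return An object of class `kdls_index`: list with `k`, `ids`,
#'   `removal_order` and `labels` (per-vertex lists with parallel vectors
#'   `hub`, `distance`, `predecessor`).
#' @seealso [query_distance()], [query_paths()], [save_index()].
#' @export
build_index <- function(graph, k = 6L) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    rlang::abort("`k` must be a positive integer")
  }
  k <- as.integer(k)
  ids <- graph$concepts$id
  n <- length(ids)
  if (n == 0) rlang::abort("graph is empty")
  adj <- adjacency_int(graph)
  deg <- lengths(adj)
  active <- rep(TRUE, n)
  removal <- integer(n)

  rec_owner <- vector("list", n)
  rec_dist <- vector("list", n)
  rec_pred <- vector("list", n)
  stamp <- integer(n) # BFS visit marker, avoids reallocating a seen-vector

  for (step in seq_len(n)) {
    deg_masked <- ifelse(active, deg, -1L)
    hub <- which.max(deg_masked)
    removal[step] <- hub

    # BFS of depth <= k from the hub in the residual graph
    owners <- hub
    dists <- 0L
    preds <- NA_integer_
    stamp[hub] <- step
    frontier <- hub
    depth <- 0L
    while (depth < k && length(frontier) > 0) {
      nb <- unlist(adj[frontier], use.names = FALSE)
      pr <- rep.int(frontier, lengths(adj[frontier]))
      keep <- active[nb] & stamp[nb] != step
      nb <- nb[keep]
      pr <- pr[keep]
      if (length(nb) == 0) break
      first <- !duplicated(nb) # frontier sorted => lexicographic predecessor
      nb <- nb[first]
      pr <- pr[first]
      ord <- order(nb)
      nb <- nb[ord]
      pr <- pr[ord]
      stamp[nb] <- step
      depth <- depth + 1L
      owners <- c(owners, nb)
      dists <- c(dists, rep.int(depth, length(nb)))
      preds <- c(preds, pr)
      frontier <- nb
    }
    rec_owner[[step]] <- owners
    rec_dist[[step]] <- dists
    rec_pred[[step]] <- preds

    # delete the hub from the residual graph
    active[hub] <- FALSE
    nbh <- adj[[hub]]
    nbh <- nbh[active[nbh]]
    deg[nbh] <- deg[nbh] - 1L
  }

  owner_all <- unlist(rec_owner, use.names = FALSE)
  hub_all <- rep.int(removal, lengths(rec_owner))
  dist_all <- unlist(rec_dist, use.names = FALSE)
  pred_all <- unlist(rec_pred, use.names = FALSE)

  ord <- order(owner_all, hub_all)
  owner_all <- owner_all[ord]
  hub_all <- hub_all[ord]
  dist_all <- dist_all[ord]
  pred_all <- pred_all[ord]

  idx_split <- split(seq_along(owner_all), factor(owner_all, levels = seq_len(n)))
  labels <- lapply(idx_split, function(i) {
    list(
      hub = ids[hub_all[i]],
      distance = dist_all[i],
      predecessor = ids_or_na(ids, pred_all[i])
    )
  })
  names(labels) <- ids

  structure(
    list(k = k, ids = ids, removal_order = ids[removal], labels = labels),
    class = "kdls_index"
  )
}

ids_or_na <- function(ids, i) {
  out <- rep(NA_character_, length(i))
  ok <- !is.na(i)
  out[ok] <- ids[i[ok]]
  out
}

#' @export
print.kdls_index <- function(x, ...) {
  cat(sprintf(
    "<kdls_index> k = %d, %d vertices, %d label records\n",
    x$k, length(x$ids), sum(vapply(x$labels, function(l) length(l$hub), 1L))
  ))
  invisible(x)
}

#' @export
tidy.kdls_index <- function(x, ...) {
  tibble::tibble(
    owner = rep(x$ids, vapply(x$labels, function(l) length(l$hub), 1L)),
    hub = unlist(lapply(x$labels, `[[`, "hub"), use.names = FALSE),
    distance = unlist(lapply(x$labels, `[[`, "distance"), use.names = FALSE),
    predecessor = unlist(
      lapply(x$labels, `[[`, "predecessor"),
      use.names = FALSE
    )
  )
}

#' @export
glance.kdls_index <- function(x, ...) {
  sizes <- vapply(x$labels, function(l) length(l$hub), 1L)
  tibble::tibble(
    k = x$k,
    n_vertices = length(x$ids),
    n_records = sum(sizes),
    mean_label_size = mean(sizes),
    max_label_size = max(sizes)
  )
}

check_indexed <- function(index, ids) {
  unknown <- setdiff(ids, index$ids)
  if (length(unknown) > 0) {
    rlang::abort(sprintf(
      "concept id(s) not in index: %s",
      paste(utils::head(unknown, 5), collapse = ", ")
    ))
  }
}

#' Distance query by label comparison
#'
#' Returns the minimum over shared hubs `w` of `d(u, w) + d(w, v)`. The
#' answer is always an upper bound on the true graph distance and equals it
#' whenever the true distance is at most the index's `k`.
#'
#' @param index A [build_index()] result.
#' @param u,v Concept ids.
#' @return Hop count (numeric), or `Inf` when the labels share no hub
#'   (unreachable within the index's guarantee).
#' @export
query_distance <- function(index, u, v) {
  check_indexed(index, c(u, v))
  lu <- index$labels[[u]]
  lv <- index$labels[[v]]
  m <- match(lu$hub, lv$hub)
  hit <- which(!is.na(m))
  if (length(hit) == 0) {
    return(Inf)
  }
  min(lu$distance[hit] + lv$distance[m[hit]])
}

# reconstruct the walk from `from` to hub `w` by following predecessors
walk_to_hub <- function(index, from, w) {
  walk <- from
  cur <- from
  repeat {
    lab <- index$labels[[cur]]
    i <- match(w, lab$hub)
    if (is.na(i)) {
      return(NULL)
    }
    if (lab$distance[i] == 0L) {
      return(walk)
    }
    cur <- lab$predecessor[i]
    walk <- c(walk, cur)
  }
}

# simple deduplicated vertex sequences u -> ... -> v, one per shared hub
discover_paths <- function(index, u, v) {
  lu <- index$labels[[u]]
  lv <- index$labels[[v]]
  shared <- intersect(lu$hub, lv$hub)
  out <- list()
  seen <- character()
  for (w in shared) {
    wu <- walk_to_hub(index, u, w)
    wv <- walk_to_hub(index, v, w)
    if (is.null(wu) || is.null(wv)) next
    path <- c(wu, rev(wv)[-1])
    if (anyDuplicated(path) > 0) next # non-simple concatenation
    key <- paste(path, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- path
  }
  out
}

#' Path queries by label comparison
#'
#' For every hub shared by the two labels, the walk from `u` to the hub and
#' the reversed walk from `v` to the hub are concatenated. Non-simple
#' concatenations are discarded and duplicate vertex sequences removed; each
#' step carries the relation labels of the traversed edge.
#'
#' @param index A [build_index()] result.
#' @param graph The [concept_graph()] the index was built on (source of the
#'   edge relation labels).
#' @param u,v Distinct concept ids.
#' @return An object of class `path_collection`: list with `source`,
#'   `target`, `paths` (list of vertex-id vectors) and `relations` (per
#'   path, a list of per-step relation-label vectors).
#' @export
query_paths <- function(index, graph, u, v) {
  check_indexed(index, c(u, v))
  if (u == v) {
    return(path_collection(u, v, list(), list()))
  }
  paths <- discover_paths(index, u, v)
  relations <- lapply(paths, function(p) {
    lapply(seq_len(length(p) - 1L), function(i) {
      edge_relations(graph, p[i], p[i + 1L])
    })
  })
  path_collection(u, v, paths, relations)
}

path_collection <- function(source, target, paths, relations) {
  structure(
    list(source = source, target = target, paths = paths,
         relations = relations),
    class = "path_collection"
  )
}

#' @export
print.path_collection <- function(x, ...) {
  cat(sprintf(
    "<path_collection> %s -> %s: %d path(s)\n",
    x$source, x$target, length(x$paths)
  ))
  invisible(x)
}

#' @export
length.path_collection <- function(x) length(x$paths)

#' @export
tidy.path_collection <- function(x, ...) {
  if (length(x$paths) == 0) {
    return(tibble::tibble(
      path_id = integer(), step = integer(),
      from = character(), to = character(), relations = character()
    ))
  }
  purrr::imap_dfr(x$paths, function(p, i) {
    steps <- seq_len(length(p) - 1L)
    tibble::tibble(
      path_id = i,
      step = steps,
      from = p[steps],
      to = p[steps + 1L],
      relations = vapply(
        x$relations[[i]], paste, character(1), collapse = ";"
      )
    )
  })
}

#' Shortest sub-collection of a path collection
#'
#' Keeps the paths whose edge count equals the minimum over the collection
#' (the set rendered by the layered layout).
#'
#' @param paths A `path_collection`.
#' @return A `path_collection` containing only the minimum-length paths.
#' @export
shortest_subset <- function(paths) {
  if (length(paths$paths) == 0) {
    return(paths)
  }
  len <- lengths(paths$paths) - 1L
  keep <- which(len == min(len))
  path_collection(
    paths$source, paths$target, paths$paths[keep], paths$relations[keep]
  )
}

#' Persist / restore a kDLS index
#'
#' The on-disk format is versioned gzip-compressed JSON lines: a header
#' record carrying `k`, the vertex count and the removal order, then one
#' line per vertex label. `load_index(save_index(x, f))` restores an
#' identical index.
#'
#' @param index A `kdls_index`.
#' @param path Output file.
#' @return `save_index()` returns `path` invisibly; `load_index()` returns
#'   the restored `kdls_index`.
#' @export
save_index <- function(index, path) {
  con <- gzfile(path, open = "wb")
  on.exit(close(con))
  header <- jsonlite::toJSON(
    list(
      format = "kdls-index", version = 1L, k = index$k,
      n = length(index$ids), removal_order = index$removal_order
    ),
    auto_unbox = FALSE
  )
  writeLines(header, con)
  for (id in index$ids) {
    lab <- index$labels[[id]]
    writeLines(jsonlite::toJSON(
      list(
        id = id, hub = lab$hub, distance = lab$distance,
        predecessor = lab$predecessor
      ),
      auto_unbox = FALSE, null = "null", na = "null"
    ), con)
  }
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  con <- gzfile(path, open = "rb")
  on.exit(close(con))
  lines <- tryCatch(
    readLines(con),
    error = function(e) rlang::abort(sprintf("corrupt index file: %s", path)),
    warning = function(w) rlang::abort(sprintf("corrupt index file: %s", path))
  )
  if (length(lines) < 1) rlang::abort(sprintf("corrupt index file: %s", path))
  header <- parse_index_line(lines[1], path)
  header[c("format", "version", "k", "n", "removal_order")] <-
    lapply(header[c("format", "version", "k", "n", "removal_order")], unlist)
  if (!identical(header$format, "kdls-index") ||
      !identical(as.integer(header$version), 1L)) {
    rlang::abort(sprintf("not a kdls index file: %s", path))
  }
  n <- as.integer(header$n)
  if (length(lines) != n + 1L) {
    rlang::abort(sprintf("corrupt index file (truncated): %s", path))
  }
  labels <- vector("list", n)
  ids <- character(n)
  for (i in seq_len(n)) {
    rec <- parse_index_line(lines[i + 1L], path)
    ids[i] <- as.character(unlist(rec$id))
    labels[[i]] <- list(
      hub = as.character(unlist(rec$hub)),
      distance = as.integer(unlist(rec$distance)),
      predecessor = vapply(rec$predecessor, function(p) {
        if (is.null(p)) NA_character_ else as.character(p)
      }, character(1))
    )
  }
  names(labels) <- ids
  structure(
    list(
      k = as.integer(header$k), ids = ids,
      removal_order = as.character(unlist(header$removal_order)),
      labels = labels
    ),
    class = "kdls_index"
  )
}

parse_index_line <- function(line, path) {
  tryCatch(
    jsonlite::fromJSON(line, simplifyVector = FALSE),
    error = function(e) rlang::abort(sprintf("corrupt index file: %s", path))
  )
}
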