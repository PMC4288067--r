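test_that("hub removal follows maximum residual degree with id tie-break", {
  g <- toy_graphs()
  single <- concept_graph(
    tibble::tibble(id = "x", name = "x", semantic_types = "TTOY")
  )
  expect_equal(hub_removal_order(single), "x")
  # star: the center goes first
  expect_equal(hub_removal_order(g$star)[1], "c")
  # square a-b-c-d: all degree 2, so a by tie-break; then c has residual
  # degree 2 while b and d have 1
  expect_equal(hub_removal_order(g$square)[1:2], c("a", "c"))
})

test_that("build_index reproduces the hand-simulated path-graph labels", {
  g <- toy_graphs()$path
  idx <- build_index(g, k = 2)
  expect_equal(idx$removal_order[1], "b")
  expect_equal(sort(idx$labels[["a"]]$hub), c("a", "b"))
  expect_equal(idx$labels[["a"]]$distance[idx$labels[["a"]]$hub == "b"], 1L)
  expect_equal(sort(idx$labels[["c"]]$hub), c("b", "c"))
  expect_equal(idx$labels[["b"]]$hub, "b")
  expect_equal(idx$labels[["b"]]$distance, 0L)
  expect_true(is.na(idx$labels[["b"]]$predecessor))
  expect_error(build_index(g, k = 0), "positive")
})

test_that("label invariants hold: one record per hub, self-records, k cap", {
  for (seed in 1:10) {
    g <- random_test_graph(sample(5:30, 1), seed = seed)
    k <- sample(c(2, 3, 6), 1)
    idx <- build_index(g, k = k)
    expect_setequal(idx$removal_order, g$concepts$id)
    for (id in g$concepts$id) {
      lab <- idx$labels[[id]]
      expect_lte(length(lab$hub), n_concepts(g))
      expect_equal(anyDuplicated(lab$hub), 0)
      self <- match(id, lab$hub)
      expect_false(is.na(self))
      expect_equal(lab$distance[self], 0L)
      expect_true(all(lab$distance <= k))
      # predecessor set iff distance > 0, and adjacent to the owner
      expect_equal(is.na(lab$predecessor), lab$distance == 0L)
      preds <- lab$predecessor[!is.na(lab$predecessor)]
      expect_true(all(preds %in% g$adj[[id]]))
    }
  }
})

test_that("query_distance answers identity, star and disconnected cases", {
  g <- toy_graphs()
  idx_star <- build_index(g$star, k = 6)
  expect_equal(query_distance(idx_star, "l1", "l1"), 0)
  expect_equal(query_distance(idx_star, "l1", "l2"), 2)
  idx_two <- build_index(g$two_component, k = 6)
  expect_equal(query_distance(idx_two, "a", "z"), Inf)
  expect_error(query_distance(idx_star, "c", "nope"), "not in index")
})

test_that("query_paths finds exactly the two square paths and direct edges", {
  g <- toy_graphs()
  idx <- build_index(g$square, k = 6)
  pc <- query_paths(idx, g$square, "b", "d")
  expect_setequal(
    vapply(pc$paths, paste, character(1), collapse = "-"),
    c("b-a-d", "b-c-d")
  )
  expect_equal(pc$relations[[1]][[1]], "associated_with")

  # two-vertex graph: the direct edge is discovered here (its exclusion is
  # the closeness measure's job)
  pair <- concept_graph(
    tibble::tibble(id = c("u", "v"), name = c("u", "v"),
                   semantic_types = "TTOY"),
    tibble::tibble(id_a = "u", id_b = "v", relations = "rel",
                   vocabularies = "X")
  )
  idx_pair <- build_index(pair, k = 6)
  pc_pair <- query_paths(idx_pair, pair, "u", "v")
  expect_equal(pc_pair$paths, list(c("u", "v")))

  idx_two <- build_index(g$two_component, k = 6)
  expect_length(query_paths(idx_two, g$two_component, "a", "z"), 0)
  expect_length(query_paths(idx_two, g$two_component, "a", "a"), 0)
})

test_that("shortest_subset keeps exactly the minimum-length paths", {
  mk <- function(...) {
    paths <- list(...)
    structure(
      list(source = "u", target = "v", paths = paths,
           relations = lapply(paths, function(p) {
             rep(list("rel"), length(p) - 1)
           })),
      class = "path_collection"
    )
  }
  both <- shortest_subset(mk(c("b", "a", "d"), c("b", "c", "d")))
  expect_length(both, 2)
  one <- shortest_subset(mk(c("u", "x", "v"), c("u", "x", "y", "v")))
  expect_equal(one$paths, list(c("u", "x", "v")))
  empty <- shortest_subset(mk())
  expect_length(empty, 0)
})

test_that("distance queries are exact within k and never undershoot", {
  # the hub-labeling guarantee: the first-removed vertex on a shortest path
  # broadcasts exact sub-distances before leaving the residual graph
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(8:50, 1)
    g <- random_test_graph(n)
    k <- c(2, 3, 6)[(seed %% 3) + 1]
    idx <- build_index(g, k = k)
    true_d <- bfs_distance_oracle(g)
    ids <- g$concepts$id
    pairs <- t(utils::combn(n, 2))
    d_hat <- vapply(
      seq_len(nrow(pairs)),
      function(r) query_distance(idx, ids[pairs[r, 1]], ids[pairs[r, 2]]),
      numeric(1)
    )
    d_true <- true_d[cbind(ids[pairs[, 1]], ids[pairs[, 2]])]
    expect_true(all(d_hat >= d_true))
    within_k <- is.finite(d_true) & d_true <= k
    expect_equal(d_hat[within_k], d_true[within_k])
  }
})

test_that("returned paths are valid, simple, and include a shortest witness", {
  for (seed in 1:15) {
    set.seed(100 + seed)
    n <- sample(6:25, 1)
    g <- random_test_graph(n)
    k <- c(2, 3, 6)[(seed %% 3) + 1]
    idx <- build_index(g, k = k)
    true_d <- bfs_distance_oracle(g)
    ids <- g$concepts$id
    pick <- utils::head(sample(ids), 6)
    for (u in pick) {
      for (v in setdiff(pick, u)) {
        pc <- query_paths(idx, g, u, v)
        lens <- integer()
        for (p in pc$paths) {
          expect_equal(p[1], u)
          expect_equal(p[length(p)], v)
          expect_equal(anyDuplicated(p), 0)
          for (s in seq_len(length(p) - 1)) {
            expect_true(p[s + 1] %in% g$adj[[p[s]]])
          }
          lens <- c(lens, length(p) - 1L)
        }
        expect_equal(
          anyDuplicated(vapply(pc$paths, paste, character(1), collapse = "-")),
          0
        )
        if (is.finite(true_d[u, v]) && true_d[u, v] <= k) {
          expect_true(min(lens) == true_d[u, v])
        }
      }
    }
  }
})

test_that("index save/load round-trips and re-answers queries", {
  g <- toy_graphs()
  idx <- build_index(g$square, k = 6)
  f <- withr::local_tempfile(fileext = ".json.gz")
  save_index(idx, f)
  idx2 <- load_index(f)
  expect_equal(idx2, idx)

  idx_path <- build_index(g$path, k = 6)
  f2 <- withr::local_tempfile(fileext = ".json.gz")
  save_index(idx_path, f2)
  expect_equal(query_distance(load_index(f2), "a", "c"), 2)

  # truncated file is a format error
  raw_lines <- readLines(gzfile(f))
  f3 <- withr::local_tempfile(fileext = ".json.gz")
  con <- gzfile(f3, "wb")
  writeLines(raw_lines[1:2], con)
  close(con)
  expect_error(load_index(f3), "corrupt|truncated")
  f4 <- withr::local_tempfile()
  writeLines("not json at all", f4)
  expect_error(load_index(f4), "corrupt|kdls")
})
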