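leafy_square <- function() {
  g <- toy_graphs()$square
  list(graph = g, index = build_index(g, k = 6), net = toy_type_network())
}

test_that("closeness excludes direct edges and matches hand computations", {
  fx <- leafy_square()
  # only a direct edge between u and v -> R = 0
  pair <- concept_graph(
    tibble::tibble(id = c("u", "v"), name = c("u", "v"),
                   semantic_types = "TTOY"),
    tibble::tibble(id_a = "u", id_b = "v", relations = "rel",
                   vocabularies = "X")
  )
  idx_pair <- build_index(pair, k = 6)
  expect_equal(closeness(idx_pair, pair, fx$net, "u", "v"), 0)

  # square at leaf level: two 2-edge paths, product 1 each
  expect_equal(closeness(fx$index, fx$graph, fx$net, "b", "d"), 2)
  # symmetry in undirected mode
  expect_equal(closeness(fx$index, fx$graph, fx$net, "d", "b"), 2)
  expect_error(closeness(fx$index, fx$graph, fx$net, "b", "b"), "undefined")
})

test_that("closeness weights abstract concepts down by 1/h", {
  # same square but concept a carries a level-2 type: path b-a-d contributes
  # 1 * 0.5 * 1, path b-c-d contributes 1
  net <- semantic_type_network(
    tibble::tibble(child = "TTOY", parent = "TABS")
  )
  concepts <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    name = c("a", "b", "c", "d"),
    semantic_types = list("TABS", "TTOY", "TTOY", "TTOY")
  )
  g <- concept_graph(concepts, toy_graphs()$square$edges)
  idx <- build_index(g, k = 6)
  expect_equal(closeness(idx, g, net, "b", "d"), 1.5)
})

test_that("closeness equals the discovered simple-path count at leaf level", {
  for (seed in 1:8) {
    g <- random_test_graph(sample(6:16, 1), seed = 400 + seed)
    idx <- build_index(g, k = 6)
    net <- toy_type_network()
    ids <- g$concepts$id
    u <- ids[1]
    v <- ids[length(ids)]
    pc <- query_paths(idx, g, u, v)
    n_long <- sum(lengths(pc$paths) >= 3)
    expect_equal(closeness(idx, g, net, u, v), n_long)
    # every discovered path exists in the exhaustive enumeration
    if (length(pc$paths) > 0) {
      all_paths <- all_simple_paths_oracle(g, u, v)
      keys <- vapply(all_paths, paste, character(1), collapse = "-")
      got <- vapply(pc$paths, paste, character(1), collapse = "-")
      expect_true(all(got %in% keys))
    }
  }
})

test_that("relationship matrix fills closeness with a SELF diagonal", {
  fx <- leafy_square()
  m <- relationship_matrix(fx$index, fx$graph, fx$net, c("b", "d"), c("b", "d"))
  expect_equal(m$measure, "closeness")
  expect_true(all(is.na(diag(m$values))))
  expect_equal(m$values["b", "d"], 2)
  expect_equal(m$values["d", "b"], 2)

  # transpose symmetry over distinct sets
  m2 <- relationship_matrix(fx$index, fx$graph, fx$net, c("a", "b"), c("c", "d"))
  m2t <- relationship_matrix(fx$index, fx$graph, fx$net, c("c", "d"), c("a", "b"))
  expect_equal(m2$values, t(m2t$values))
  expect_error(
    relationship_matrix(fx$index, fx$graph, fx$net, "b", "nope"), "not in index"
  )
})

test_that("distance matrix propagates identity and unreachable markers", {
  g <- toy_graphs()
  idx_star <- build_index(g$star, k = 6)
  m <- distance_matrix(idx_star, c("l1", "l2"), c("l1", "l2"))
  expect_equal(m$values["l1", "l2"], 2)
  expect_equal(m$values["l1", "l1"], 0)
  idx_two <- build_index(g$two_component, k = 6)
  expect_equal(distance_matrix(idx_two, "a", "z")$values[1, 1], Inf)
})

test_that("binarize thresholds inclusively and zeroes SELF/unreachable", {
  m <- new_rel_matrix_for_test(matrix(c(1.2, 0.3), 1, 2))
  b <- binarize(m, 1.1)
  expect_equal(unname(b$values), matrix(c(1, 0), 1, 2))
  expect_equal(b$measure, "binary")

  m2 <- new_rel_matrix_for_test(matrix(c(NA, 2, 2, NA), 2, 2))
  expect_equal(unname(binarize(m2, 1)$values), matrix(c(0, 1, 1, 0), 2, 2))
  expect_true(all(binarize(m, 99)$values == 0))
  expect_error(binarize(binarize(m, 1), 1), "closeness")

  # ones-count is non-increasing along any delta sweep
  set.seed(42)
  for (rep in 1:5) {
    vals <- new_rel_matrix_for_test(matrix(runif(30, 0, 3), 5, 6))
    ones <- vapply(
      seq(0, 3, by = 0.25),
      function(d) sum(binarize(vals, d)$values),
      numeric(1)
    )
    expect_true(all(diff(ones) <= 0))
  }
})

test_that("shared-neighbor weights count common columns, sorted and ranked", {
  b <- new_rel_matrix_for_test(
    matrix(
      c(
        1, 1, 0, 0, # d1: g1, g2
        0, 1, 1, 0, # d2: g2, g3
        1, 1, 0, 0, # d3: g1, g2
        0, 0, 0, 1  # d4: g4 only
      ),
      4, 4, byrow = TRUE,
      dimnames = list(paste0("d", 1:4), paste0("g", 1:4))
    ),
    measure = "binary"
  )
  t <- shared_neighbor_weights(b)
  expect_s3_class(t, "ranked_relations")
  key <- paste(t$id_a, t$id_b)
  expect_equal(t$weight[key == "d1 d2"], 1)
  expect_equal(t$weight[key == "d1 d3"], 2)
  expect_false("d1 d4" %in% key) # disjoint supports omitted
  expect_equal(t$weight, sort(t$weight, decreasing = TRUE))
  expect_error(shared_neighbor_weights(new_rel_matrix_for_test(b$values)),
               "binary")
})

test_that("percentile threshold transfer preserves the passing fraction", {
  ref <- new_rel_matrix_for_test(matrix(1:4, 2, 2))
  tgt <- new_rel_matrix_for_test(matrix(c(10, 20, 30, 40), 2, 2))
  expect_equal(percentile_match_threshold(ref, 3, tgt), 30)
  # self-consistency
  expect_equal(percentile_match_threshold(ref, 3, ref), 3)
  # nothing passes in the reference -> nothing passes in the target
  expect_equal(percentile_match_threshold(ref, 99, tgt), 41)

  set.seed(7)
  for (rep in 1:10) {
    ref <- new_rel_matrix_for_test(matrix(runif(48, 0, 2), 6, 8))
    tgt <- new_rel_matrix_for_test(matrix(rexp(35), 5, 7))
    delta_ref <- runif(1, 0, 2)
    delta_tgt <- percentile_match_threshold(ref, delta_ref, tgt)
    n_ref <- sum(binarize(ref, delta_ref)$values)
    frac_ref <- n_ref / length(ref$values)
    n_tgt <- sum(binarize(tgt, delta_tgt)$values)
    expect_lte(abs(n_tgt - frac_ref * length(tgt$values)), 1)
  }
})

test_that("matrix export writes SELF as empty and unreachable as inf", {
  m <- new_rel_matrix_for_test(
    matrix(c(NA, 1.5, Inf, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "c")))
  )
  f <- withr::local_tempfile(fileext = ".csv")
  export_matrix(m, f)
  lines <- readLines(f)
  expect_equal(lines[1], "id,a,c")
  expect_equal(lines[2], "a,,inf")
  expect_equal(lines[3], "b,1.5,0")
  fj <- withr::local_tempfile(fileext = ".json")
  export_matrix(m, fj, format = "json")
  parsed <- jsonlite::fromJSON(fj)
  expect_equal(parsed$measure, "closeness")
  expect_equal(parsed$values[[1]][[1]], "SELF")
})
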