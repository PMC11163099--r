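test_that("vertex degrees equal incident-edge counts", {
  g <- path_graph(3)
  expect_equal(vertex_degrees(g)$degree, c(1L, 2L, 1L))

  g2 <- molecular_graph(data.frame(from = "a", to = "b"))
  expect_equal(vertex_degrees(g2)$degree, c(1L, 1L))

  g3 <- random_molecular_graph(12, seed = 101)
  deg <- vertex_degrees(g3)
  expect_equal(stats::setNames(deg$degree, deg$vertex), incidence_degrees(g3))
})

test_that("malformed graphs are rejected with the offending element named", {
  expect_error(molecular_graph(data.frame(from = "a", to = "a")),
               "Self-loop.*'a'", class = "tiqspr_error_graph")
  expect_error(molecular_graph(data.frame(from = c("a", "b"), to = c("b", "a"))),
               "Duplicate edge", class = "tiqspr_error_graph")
  expect_error(molecular_graph(data.frame(from = "a", to = "b"),
                               vertices = c("a", "b", "z")),
               "Isolated vertex 'z'", class = "tiqspr_error_graph")
  expect_error(molecular_graph(data.frame(from = c("a", "c"), to = c("b", "d"))),
               "connected", class = "tiqspr_error_graph")
})

test_that("edge partitions tally canonical degree pairs and sum to m", {
  p6 <- edge_partition(cycle_graph(6))
  expect_equal(as.data.frame(p6), data.frame(du = 2L, dv = 2L, count = 6L))

  p3 <- edge_partition(path_graph(3))
  expect_equal(as.data.frame(p3), data.frame(du = 1L, dv = 2L, count = 2L))

  g <- random_molecular_graph(15, seed = 202)
  p <- edge_partition(g)
  # exhaustive per-edge tally, independent of the implementation
  d <- incidence_degrees(g)
  pairs <- vapply(seq_len(nrow(g$edges)), function(i) {
    ab <- sort(c(d[[g$edges$from[i]]], d[[g$edges$to[i]]]))
    sprintf("%d,%d", ab[1], ab[2])
  }, character(1))
  tallied <- table(pairs)
  expect_equal(sum(p$count), nrow(g$edges))
  for (k in seq_len(nrow(p))) {
    key <- sprintf("%d,%d", p$du[k], p$dv[k])
    expect_equal(p$count[k], as.integer(tallied[[key]]))
  }
})

test_that("partitions are invariant under vertex relabeling", {
  withr::with_seed(7, {
    g <- random_molecular_graph(14)
    perm <- sample(g$vertices)
  })
  relab <- stats::setNames(perm, g$vertices)
  g2 <- molecular_graph(data.frame(from = relab[g$edges$from],
                                   to = relab[g$edges$to]))
  expect_equal(as.data.frame(edge_partition(g)), as.data.frame(edge_partition(g2)))
})

test_that("handshake identity holds on fixtures and random graphs", {
  for (seed in 1:5) {
    g <- random_molecular_graph(10 + seed, seed = seed)
    expect_equal(sum(vertex_degrees(g)$degree), 2L * nrow(g$edges))
  }
  cmp <- sulfonamide_compounds()
  expect_equal(purrr::map_int(cmp$partition, ~ sum(.x$count)),
               c(27L, 36L, 33L, 30L, 32L))
})

test_that("validate_partition summarises and rejects bad entries", {
  cmp <- sulfonamide_compounds()
  expect_equal(validate_partition(cmp$partition[[1]])$n_edges, 27L)
  expect_equal(validate_partition(cmp$partition[[5]])$n_edges, 32L)
  expect_equal(validate_partition(data.frame(du = 1, dv = 1, count = 1))$n_edges, 1L)
  expect_error(validate_partition(data.frame(du = 0, dv = 2, count = 1)),
               class = "tiqspr_error_partition")
  expect_error(validate_partition(data.frame(du = 1, dv = 2, count = 0)),
               class = "tiqspr_error_partition")
  expect_error(validate_partition(data.frame(du = numeric(), dv = numeric(),
                                             count = numeric())),
               class = "tiqspr_error_partition")
})

test_that("as_edge_partition canonicalises pair order and merges duplicates", {
  p <- as_edge_partition(data.frame(du = c(3, 1, 2), dv = c(1, 3, 2),
                                    count = c(2, 1, 4)))
  expect_equal(as.data.frame(p),
               data.frame(du = c(1L, 2L), dv = c(3L, 2L), count = c(3L, 4L)))
  expect_true(all(p$du <= p$dv))
})

test_that("packaged sulfonamide records match the published study inputs", {
  cmp <- sulfonamide_compounds()
  expect_equal(nrow(cmp), 5L)
  expect_equal(cmp$melting_point[1], 191)
  expect_equal(cmp$formula_weight[1], 366.25)
  expect_equal(cmp$melting_point[5], 148)
  expect_equal(cmp$formula_weight[5], 307.35)
})

test_that("compound JSON round-trips partitions and properties exactly", {
  cmp <- sulfonamide_compounds()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_compounds(cmp, tmp)
  back <- read_compounds(tmp)
  expect_equal(back$compound, cmp$compound)
  expect_identical(back$melting_point, cmp$melting_point)
  expect_identical(back$formula_weight, cmp$formula_weight)
  expect_equal(purrr::map(back$partition, as.data.frame),
               purrr::map(cmp$partition, as.data.frame))

  # graphs survive too, and graph-partition consistency is enforced on read
  sc <- synth_compounds(sim_config(n_compounds = 2, n_vertices_range = c(6, 9), seed = 3))
  tmp2 <- withr::local_tempfile(fileext = ".json")
  write_compounds(sc, tmp2)
  back2 <- read_compounds(tmp2)
  expect_equal(purrr::map(back2$partition, as.data.frame),
               purrr::map(sc$partition, as.data.frame))
})

test_that("schema violations are reported with the record index", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines("[]", tmp)
  expect_error(read_compounds(tmp), class = "tiqspr_error_schema")

  writeLines('[{"name": "x", "properties": {"melting_point_C": 1, "formula_weight": 2}}]', tmp)
  expect_error(read_compounds(tmp), "Record 1", class = "tiqspr_error_schema")

  writeLines(paste0('[{"name": "x", "partition": [{"du": 1, "dv": 2, "count": 2}],',
                    '"properties": {"formula_weight": 2}}]'), tmp)
  expect_error(read_compounds(tmp), "melting_point", class = "tiqspr_error_schema")

  # stored partition disagreeing with graph_edges is a validation error
  writeLines(paste0('[{"name": "x", "partition": [{"du": 1, "dv": 1, "count": 1}],',
                    '"properties": {"melting_point_C": 1, "formula_weight": 2},',
                    '"graph_edges": [["a","b"],["b","c"]]}]'), tmp)
  expect_error(read_compounds(tmp), "disagrees", class = "tiqspr_error_partition")
})

test_that("plain-text edge lists load as molecular graphs", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# a triangle with a tail", "a b", "b c", "c a", "c d"), tmp)
  g <- read_edgelist(tmp)
  expect_equal(sort(vertex_degrees(g)$degree), c(1L, 2L, 2L, 3L))
  writeLines("a", tmp)
  expect_error(read_edgelist(tmp), "Line 1", class = "tiqspr_error_schema")
})
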