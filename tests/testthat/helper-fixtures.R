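# Shared builders for tests; everything is generated in code.

path_graph <- function(n) {
  v <- sprintf("p%02d", seq_len(n))
  molecular_graph(data.frame(from = v[-n], to = v[-1]))
}

cycle_graph <- function(n) {
  v <- sprintf("c%02d", seq_len(n))
  molecular_graph(data.frame(from = v, to = v[c(2:n, 1)]))
}

# independent per-vertex incidence count, straight off the edge list
incidence_degrees <- function(graph) {
  ends <- c(graph$edges$from, graph$edges$to)
  counts <- table(ends)
  out <- as.integer(counts[graph$vertices])
  names(out) <- graph$vertices
  out
}

# descriptor table joined with properties for the packaged sulfonamides
fixture_data <- function() {
  cmp <- sulfonamide_compounds()
  dplyr::left_join(compute_indices(cmp),
                   cmp[c("compound", "melting_point", "formula_weight")],
                   by = "compound")
}

# per-edge oracle weights, written independently of edge_weight()
oracle_weight <- function(index, a, b) {
  switch(index,
    M1 = a + b, M2 = a * b, mM2 = 1 / (a + b), H = 2 / (a + b),
    HM = (a + b)^2, F = a^2 + b^2, RR = sqrt(a * b), RA = 1 / sqrt(a * b),
    S = 1 / sqrt(a + b), GA = 2 * sqrt(a * b) / (a + b),
    ABC = sqrt((a + b - 2) / (a * b))
  )
}

# oracle index value from a graph: loop edges, look degrees up by counting
oracle_index <- function(graph, index) {
  d <- incidence_degrees(graph)
  total <- 0
  for (i in seq_len(nrow(graph$edges))) {
    a <- d[[graph$edges$from[i]]]
    b <- d[[graph$edges$to[i]]]
    total <- total + oracle_weight(index, a, b)
  }
  total
}
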