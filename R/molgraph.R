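#' Construct a hydrogen-suppressed molecular graph
#'
#' A molecular graph represents the heavy-atom skeleton of a compound: vertices
#' are heavy atoms, edges are covalent bonds, hydrogens are suppressed. The
#' graph must be simple (no self-loops, no duplicate bonds), connected, and
#' free of isolated atoms.
#'
#' @param edges A two-column data frame or matrix of vertex labels, one edge
#'   per row. Labels are opaque strings.
#' @param vertices Optional character vector of vertex labels. Defaults to the
#'   labels appearing in `edges`; supplying extra labels that carry no bond is
#'   an error (every atom must have degree at least 1).
#' @param elements Optional named character vector annotating vertices with
#'   element symbols. Informational only; never used in any computation.
#'
#' @return An object of class `molecular_graph`: a list with components
#'   `vertices` (character) and `edges` (a tibble with columns `from`, `to`).
#' @examples
#' g <- molecular_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
#' vertex_degrees(g)
#' @export
molecular_graph <- function(edges, vertices = NULL, elements = NULL) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || ncol(edges) < 2 || nrow(edges) == 0) {
    rlang::abort("`edges` must be a data frame or matrix with two columns and at least one row.",
                 class = "tiqspr_error_graph")
  }
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])

  loops <- from == to
  if (any(loops)) {
    rlang::abort(
      sprintf("Self-loop on vertex '%s': molecular graphs are simple.", from[which(loops)[1]]),
      class = "tiqspr_error_graph"
    )
  }
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    i <- which(dup)[1]
    rlang::abort(
      sprintf("Duplicate edge {%s, %s}: molecular graphs are simple.", from[i], to[i]),
      class = "tiqspr_error_graph"
    )
  }

  seen <- unique(c(from, to))
  if (is.null(vertices)) {
    vertices <- seen
  } else {
    vertices <- as.character(vertices)
    isolated <- setdiff(vertices, seen)
    if (length(isolated) > 0) {
      rlang::abort(
        sprintf("Isolated vertex '%s': every atom must have degree >= 1.", isolated[1]),
        class = "tiqspr_error_graph"
      )
    }
    unknown <- setdiff(seen, vertices)
    if (length(unknown) > 0) {
      rlang::abort(
        sprintf("Edge endpoint '%s' is not in `vertices`.", unknown[1]),
        class = "tiqspr_error_graph"
      )
    }
  }

  g <- structure(
    list(
      vertices = vertices,
      edges = tibble::tibble(from = from, to = to),
      elements = elements
    ),
    class = "molecular_graph"
  )
  ig <- as_igraph(g)
  if (!igraph::is_connected(ig)) {
    rlang::abort("Molecular graph must be connected.", class = "tiqspr_error_graph")
  }
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf(
    "<molecular_graph> %d vertices, %d edges, max degree %d\n",
    length(x$vertices), nrow(x$edges), max(vertex_degrees(x)$degree)
  ))
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = graph$vertices)
}

#' Vertex degrees of a molecular graph
#'
#' The degree of an atom is the number of bonds incident to it (its valence in
#' the hydrogen-suppressed skeleton).
#'
#' @param graph A [molecular_graph()].
#' @return A tibble with columns `vertex` and `degree`, in the graph's vertex
#'   order. Degrees always satisfy the handshake identity
#'   \eqn{\sum_v d_v = 2m}.
#' @export
vertex_degrees <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  d <- igraph::degree(as_igraph(graph))
  tibble::tibble(vertex = names(d), degree = as.integer(d))
}

#' Degree-pair edge partition
#'
#' Groups the edges of a molecular graph by the unordered pair of endpoint
#' degrees \eqn{(d_u, d_v)}, the sole input every degree-based topological
#' index needs. Pairs are stored canonically with \eqn{d_u \le d_v}.
#'
#' For a data frame input (columns `du`, `dv`, `count`) the entries are
#' canonicalised, merged and validated rather than derived.
#'
#' @param x A [molecular_graph()] or a data frame with columns `du`, `dv`,
#'   `count`.
#' @return An `edge_partition`: a tibble with integer columns `du`, `dv`,
#'   `count`, sorted by `(du, dv)`, with `sum(count)` equal to the number of
#'   edges.
#' @examples
#' g <- molecular_graph(cbind(letters[1:5], letters[c(2:5, 1)])) # 5-cycle
#' edge_partition(g)
#' @export
edge_partition <- function(x) UseMethod("edge_partition")

#' @export
edge_partition.molecular_graph <- function(x) {
  deg <- vertex_degrees(x)
  d <- stats::setNames(deg$degree, deg$vertex)
  du <- pmin(d[x$edges$from], d[x$edges$to])
  dv <- pmax(d[x$edges$from], d[x$edges$to])
  tibble::tibble(du = as.integer(du), dv = as.integer(dv)) |>
    dplyr::count(.data$du, .data$dv, name = "count") |>
    new_edge_partition()
}

#' @export
edge_partition.data.frame <- function(x) {
  as_edge_partition(x)
}

new_edge_partition <- function(tbl) {
  tbl <- dplyr::arrange(tbl, .data$du, .data$dv)
  structure(tbl, class = c("edge_partition", class(tibble::tibble())))
}

#' Coerce and validate a degree-pair edge partition
#'
#' @param x A data frame with columns `du`, `dv`, `count`; pairs may be given
#'   in either order and duplicated pairs are merged.
#' @return An `edge_partition` (see [edge_partition()]).
#' @export
as_edge_partition <- function(x) {
  if (inherits(x, "edge_partition")) return(x)
  if (!is.data.frame(x) || !all(c("du", "dv", "count") %in% names(x))) {
    rlang::abort("An edge partition needs columns `du`, `dv`, `count`.",
                 class = "tiqspr_error_partition")
  }
  if (nrow(x) == 0) {
    rlang::abort("An edge partition must contain at least one entry.",
                 class = "tiqspr_error_partition")
  }
  du <- x$du; dv <- x$dv; count <- x$count
  bad_num <- !is.finite(du) | !is.finite(dv) | !is.finite(count) |
    du != round(du) | dv != round(dv) | count != round(count)
  if (any(bad_num)) {
    rlang::abort("Degrees and counts must be finite integers.",
                 class = "tiqspr_error_partition")
  }
  if (any(du < 1 | dv < 1)) {
    rlang::abort(sprintf("Non-positive degree in pair (%s, %s).",
                         du[which(du < 1 | dv < 1)[1]], dv[which(du < 1 | dv < 1)[1]]),
                 class = "tiqspr_error_partition")
  }
  if (any(count < 1)) {
    rlang::abort(sprintf("Non-positive count %s for pair (%s, %s).",
                         count[which(count < 1)[1]], du[which(count < 1)[1]], dv[which(count < 1)[1]]),
                 class = "tiqspr_error_partition")
  }
  lo <- pmin(du, dv)
  hi <- pmax(du, dv)
  tibble::tibble(du = as.integer(lo),
                 dv = as.integer(hi),
                 count = as.integer(count)) |>
    dplyr::summarise(count = sum(.data$count), .by = c("du", "dv")) |>
    new_edge_partition()
}

#' Summarise and validate an edge partition
#'
#' Checks partition invariants (positive integer degrees and counts) and
#' returns the aggregate quantities used in consistency checks: the edge count
#' \eqn{m = \sum \text{count}} and the degree-sum
#' \eqn{\sum \text{count} \cdot (d_u + d_v)}, which equals
#' \eqn{\sum_v d_v^2} when a graph underlies the partition.
#'
#' @param partition Anything [as_edge_partition()] accepts.
#' @return A one-row tibble with columns `n_pairs`, `n_edges`, `degree_sum`.
#' @export
validate_partition <- function(partition) {
  p <- as_edge_partition(partition)
  tibble::tibble(
    n_pairs = nrow(p),
    n_edges = sum(p$count),
    degree_sum = sum(p$count * (p$du + p$dv))
  )
}

#' Read a plain-text edge list
#'
#' One edge per line: two whitespace-separated vertex labels. Blank lines and
#' lines starting with `#` are ignored.
#'
#' @param path Path to the edge-list file.
#' @return A [molecular_graph()].
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    rlang::abort("Edge-list file contains no edges.", class = "tiqspr_error_schema")
  }
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(toks) != 2)
  if (length(bad) > 0) {
    rlang::abort(sprintf("Line %d: expected two vertex labels.", bad[1]),
                 class = "tiqspr_error_schema")
  }
  m <- do.call(rbind, toks)
  molecular_graph(data.frame(from = m[, 1], to = m[, 2]))
}

# ---- compound records ----------------------------------------------------

#' Read compound records from JSON
#'
#' The schema is an array of records
#' `{"name", "partition": [{"du","dv","count"}, ...],
#'   "properties": {"melting_point_C", "formula_weight"},
#'   "graph_edges": optional [[label, label], ...]}`.
#' When `graph_edges` is present the partition derived from the graph must
#' equal the stored one.
#'
#' @param path Path to a compound JSON file.
#' @return A tibble with one row per compound: columns `compound`,
#'   `melting_point` (degrees C), `formula_weight`, and list-columns
#'   `partition` (each an `edge_partition`) and `graph` (each a
#'   `molecular_graph` or `NULL`).
#' @seealso [sulfonamide_compounds()], [write_compounds()]
#' @export
read_compounds <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw) || length(raw) == 0) {
    rlang::abort("Compound file must contain at least one record.",
                 class = "tiqspr_error_schema")
  }
  recs <- purrr::imap(raw, function(rec, i) {
    fail <- function(msg) {
      rlang::abort(sprintf("Record %d: %s", i, msg), class = "tiqspr_error_schema")
    }
    if (!is.list(rec)) fail("not an object.")
    if (!is.character(rec$name %||% NULL) || !nzchar(rec$name)) fail("missing `name`.")
    if (is.null(rec$partition)) fail("missing `partition`.")
    part_df <- tryCatch(
      dplyr::bind_rows(purrr::map(rec$partition, tibble::as_tibble)),
      error = function(e) fail("malformed `partition` entries.")
    )
    if (!all(c("du", "dv", "count") %in% names(part_df))) {
      fail("partition entries need fields `du`, `dv`, `count`.")
    }
    partition <- as_edge_partition(part_df)
    props <- rec$properties
    mp <- props$melting_point_C %||% NULL
    fw <- props$formula_weight %||% NULL
    if (!is.numeric(mp) || !is.finite(mp)) fail("missing or non-finite `melting_point_C`.")
    if (!is.numeric(fw) || !is.finite(fw)) fail("missing or non-finite `formula_weight`.")
    graph <- NULL
    if (!is.null(rec$graph_edges)) {
      em <- do.call(rbind, purrr::map(rec$graph_edges, function(e) c(e[[1]], e[[2]])))
      graph <- molecular_graph(data.frame(from = em[, 1], to = em[, 2]))
      derived <- edge_partition(graph)
      if (!identical(as.data.frame(derived), as.data.frame(partition))) {
        rlang::abort(
          sprintf("Record %d: partition derived from `graph_edges` disagrees with the stored partition.", i),
          class = "tiqspr_error_partition"
        )
      }
    }
    tibble::tibble(
      compound = rec$name,
      melting_point = as.numeric(mp),
      formula_weight = as.numeric(fw),
      partition = list(partition),
      graph = list(graph)
    )
  })
  dplyr::bind_rows(recs)
}

#' Write compound records to JSON
#'
#' Inverse of [read_compounds()]: emits the same schema, so written files are
#' drop-in pipeline inputs. Round-trips partitions and properties exactly.
#'
#' @param compounds A compound tibble as returned by [read_compounds()] or
#'   [synth_compounds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(compounds, path) {
  recs <- purrr::pmap(
    list(compounds$compound, compounds$partition,
         compounds$melting_point, compounds$formula_weight,
         compounds$graph %||% rep(list(NULL), nrow(compounds))),
    function(name, part, mp, fw, graph) {
      rec <- list(
        name = name,
        partition = purrr::pmap(
          list(part$du, part$dv, part$count),
          function(du, dv, count) list(du = du, dv = dv, count = count)
        ),
        properties = list(melting_point_C = mp, formula_weight = fw)
      )
      if (!is.null(graph)) {
        rec$graph_edges <- purrr::map2(graph$edges$from, graph$edges$to, ~ list(.x, .y))
      }
      rec
    }
  )
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The five sulfonamide study compounds
#'
#' Loads the packaged records of five anticancer sulfonamide derivatives:
#' degree-pair edge partitions of their hydrogen-suppressed molecular graphs
#' together with melting point (degrees C) and formula weight.
#'
#' @return A compound tibble (see [read_compounds()]) with five rows.
#' @examples
#' sulfonamide_compounds()
#' @export
sulfonamide_compounds <- function() {
  read_compounds(system.file("extdata", "sulfonamides.json", package = "tiqspr",
                             mustWork = TRUE))
}
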