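#' Configuration for synthetic compound generation
#'
#' Bundles and validates the knobs of the generator: how many compounds, the
#' size and degree bound of their random molecular graphs, and the linear
#' property model \eqn{P = A + B \cdot TI + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2)}.
#'
#' Defaults mirror the sulfonamide study conditions: five compounds, heavy-atom
#' skeletons of 22 to 32 atoms with maximum degree 4, and a melting-point model
#' on the first Zagreb index with the study-scale intercept, slope and residual
#' spread.
#'
#' @param n_compounds Number of compounds to generate.
#' @param n_vertices_range Integer interval (length 2) for the number of heavy
#'   atoms per graph; lower bound at least 2.
#' @param max_degree Maximum vertex degree (valence cap); at least 2,
#'   default 4.
#' @param index The topological index driving the target property.
#' @param property Which property the linear model generates
#'   (`"melting_point"` or `"formula_weight"`); the other property is drawn
#'   independently of structure.
#' @param A,B Intercept and slope of the generating model, in property units.
#' @param sigma Residual standard deviation (same units); `>= 0`.
#' @param seed Integer seed; the whole generation is a deterministic function
#'   of the configuration.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_compounds = 5,
                       n_vertices_range = c(22, 32),
                       max_degree = 4,
                       index = "M1",
                       property = c("melting_point", "formula_weight"),
                       A = 401.74, B = -1.4579, sigma = 21,
                       seed = 1L) {
  property <- match.arg(property)
  match_index(index)
  bad <- function(msg) rlang::abort(msg, class = "tiqspr_error_config")
  if (!is.numeric(n_compounds) || n_compounds < 1 || n_compounds != round(n_compounds)) {
    bad("`n_compounds` must be a positive integer.")
  }
  if (length(n_vertices_range) != 2 || any(n_vertices_range != round(n_vertices_range)) ||
        n_vertices_range[1] < 2 || n_vertices_range[2] < n_vertices_range[1]) {
    bad("`n_vertices_range` must be an increasing integer interval with lower bound >= 2.")
  }
  if (!is.numeric(max_degree) || max_degree < 2 || max_degree != round(max_degree)) {
    bad("`max_degree` must be an integer >= 2.")
  }
  if (!is.numeric(sigma) || sigma < 0) bad("`sigma` must be >= 0.")
  if (!is.numeric(A) || !is.numeric(B) || !is.finite(A) || !is.finite(B)) {
    bad("`A` and `B` must be finite numbers.")
  }
  if (!is.numeric(seed) || seed != round(seed)) bad("`seed` must be an integer.")
  structure(
    list(n_compounds = as.integer(n_compounds),
         n_vertices_range = as.integer(n_vertices_range),
         max_degree = as.integer(max_degree),
         index = index, property = property,
         A = A, B = B, sigma = sigma, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Random connected molecular graph with bounded degree
#'
#' Grows a random spanning tree that respects the degree cap (each new vertex
#' attaches to a uniformly chosen existing vertex with spare valence), then
#' adds extra random edges between non-adjacent vertex pairs while the cap
#' allows, emulating rings in molecular skeletons. The result is always
#' simple, connected, and has every degree in `[1, max_degree]`.
#'
#' @param n_vertices Number of vertices; at least 2.
#' @param max_degree Maximum degree; at least 2.
#' @param n_extra_edges Number of non-tree edges to attempt; defaults to a
#'   random count up to one fifth of the vertices (molecules have few rings).
#'   Fewer are added if the degree cap leaves no candidate pair.
#' @param seed Optional integer; when supplied the draw is a deterministic
#'   function of the arguments and the caller's RNG state is untouched.
#' @return A [molecular_graph()].
#' @examples
#' random_molecular_graph(12, seed = 7)
#' @export
random_molecular_graph <- function(n_vertices, max_degree = 4,
                                   n_extra_edges = NULL, seed = NULL) {
  if (n_vertices < 2) {
    rlang::abort("`n_vertices` must be at least 2.", class = "tiqspr_error_config")
  }
  if (max_degree < 2) {
    rlang::abort("`max_degree` must be at least 2.", class = "tiqspr_error_config")
  }
  draw <- function() {
    labels <- sprintf("v%03d", seq_len(n_vertices))
    deg <- stats::setNames(integer(n_vertices), labels)
    from <- character(0); to <- character(0)
    for (i in seq(2, n_vertices)) {
      open <- labels[seq_len(i - 1)][deg[seq_len(i - 1)] < max_degree]
      # a cap >= 2 always leaves the chain, so `open` is never empty
      parent <- if (length(open) == 1) open else sample(open, 1)
      from <- c(from, parent); to <- c(to, labels[i])
      deg[parent] <- deg[parent] + 1L
      deg[labels[i]] <- deg[labels[i]] + 1L
    }
    adj_key <- paste(pmin(from, to), pmax(from, to))
    k <- if (is.null(n_extra_edges)) sample(0:max(0L, n_vertices %/% 5L), 1) else n_extra_edges
    for (j in seq_len(k)) {
      spare <- labels[deg < max_degree]
      if (length(spare) < 2) break
      pairs <- utils::combn(spare, 2)
      keys <- paste(pmin(pairs[1, ], pairs[2, ]), pmax(pairs[1, ], pairs[2, ]))
      ok <- which(!keys %in% adj_key)
      if (length(ok) == 0) break
      pick <- if (length(ok) == 1) ok else sample(ok, 1)
      u <- pairs[1, pick]; v <- pairs[2, pick]
      from <- c(from, u); to <- c(to, v)
      deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
      adj_key <- c(adj_key, keys[pick])
    }
    molecular_graph(data.frame(from = from, to = to), vertices = labels)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate synthetic compound records
#'
#' Draws `n_compounds` random degree-bounded molecular graphs, derives their
#' edge partitions, and fills both properties: the configured target property
#' follows the linear model \eqn{P = A + B \cdot TI + N(0, \sigma^2)} on the
#' configured index, while the other property is drawn independently of
#' structure (normal around study-scale typical values), so that
#' index-property correlation tables exercise both a strong and a
#' near-null regime.
#'
#' Output has the same shape as [read_compounds()], so synthetic sets are
#' drop-in pipeline inputs; [write_compounds()] serialises them to the same
#' JSON schema. Same configuration (including seed) gives bit-identical
#' output.
#'
#' @param config A [sim_config()].
#' @return A compound tibble with `n_compounds` rows, including the `graph`
#'   list-column.
#' @examples
#' synth_compounds(sim_config(n_compounds = 3, seed = 42))
#' @export
synth_compounds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    recs <- purrr::map(seq_len(config$n_compounds), function(i) {
      nv <- sample(seq(config$n_vertices_range[1], config$n_vertices_range[2]), 1)
      graph <- random_molecular_graph(nv, config$max_degree)
      part <- edge_partition(graph)
      ti <- index_value(part, config$index)
      target <- config$A + config$B * ti + stats::rnorm(1, 0, config$sigma)
      # the structure-independent property: normal at the scale typical of
      # small-molecule melting points / formula weights
      other <- if (config$property == "melting_point") {
        stats::rnorm(1, mean = 350, sd = 35) # formula weight
      } else {
        stats::rnorm(1, mean = 165, sd = 30) # melting point, degrees C
      }
      mp <- if (config$property == "melting_point") target else other
      fw <- if (config$property == "formula_weight") target else other
      tibble::tibble(
        compound = sprintf("synthetic-%03d", i),
        melting_point = mp, formula_weight = fw,
        partition = list(part), graph = list(graph)
      )
    })
    dplyr::bind_rows(recs)
  })
}
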