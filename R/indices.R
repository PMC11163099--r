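#' Identifiers of the supported topological indices
#'
#' The eleven degree-based indices: first Zagreb (M1), second Zagreb (M2),
#' modified second Zagreb (mM2), harmonic (H), hyper-Zagreb (HM), forgotten
#' (F), reciprocal Randic (RR), Randic (RA), sum-connectivity (S),
#' geometric-arithmetic (GA) and atom-bond connectivity (ABC).
#'
#' @return Character vector of the eleven index identifiers, in report order.
#' @export
index_ids <- function() {
  c("M1", "M2", "mM2", "H", "HM", "F", "RR", "RA", "S", "GA", "ABC")
}

#' Per-edge weight of a degree-based topological index
#'
#' Every supported index is a sum over edges of a weight `f(du, dv)` depending
#' only on the endpoint degrees:
#' \describe{
#'   \item{M1}{\eqn{d_u + d_v}}
#'   \item{M2}{\eqn{d_u d_v}}
#'   \item{mM2}{\eqn{1/(d_u + d_v)} (`"reported"` variant) or
#'     \eqn{1/(d_u d_v)} (`"literature"` variant; see Details)}
#'   \item{H}{\eqn{2/(d_u + d_v)}}
#'   \item{HM}{\eqn{(d_u + d_v)^2}}
#'   \item{F}{\eqn{d_u^2 + d_v^2}}
#'   \item{RR}{\eqn{\sqrt{d_u d_v}}}
#'   \item{RA}{\eqn{1/\sqrt{d_u d_v}}}
#'   \item{S}{\eqn{1/\sqrt{d_u + d_v}}}
#'   \item{GA}{\eqn{2\sqrt{d_u d_v}/(d_u + d_v)}}
#'   \item{ABC}{\eqn{\sqrt{(d_u + d_v - 2)/(d_u d_v)}}; zero (not an error)
#'     when \eqn{d_u = d_v = 1}}
#' }
#'
#' @details The modified second Zagreb index is defined in the literature as
#'   \eqn{\sum 1/(d_u d_v)}, but the source study this package reproduces
#'   consistently computes \eqn{\sum 1/(d_u + d_v)} (exactly half the harmonic
#'   index). The `"reported"` variant (default) reproduces that convention;
#'   `"literature"` selects the standard definition.
#'
#' @param index One of [index_ids()].
#' @param du,dv Positive integer endpoint degrees (vectorised).
#' @param mm2_variant `"reported"` or `"literature"`; only affects `mM2`.
#' @return Numeric vector of edge weights; symmetric in `(du, dv)`.
#' @examples
#' edge_weight("M1", 1, 3) # 4
#' edge_weight("GA", 3, 3) # 1
#' @export
edge_weight <- function(index, du, dv, mm2_variant = c("reported", "literature")) {
  index <- match_index(index)
  mm2_variant <- match.arg(mm2_variant)
  if (any(!is.finite(du) | !is.finite(dv) | du < 1 | dv < 1 |
            du != round(du) | dv != round(dv))) {
    rlang::abort("Degrees must be positive integers.", class = "tiqspr_error_partition")
  }
  du <- as.numeric(du); dv <- as.numeric(dv)
  switch(index,
    M1  = du + dv,
    M2  = du * dv,
    mM2 = if (mm2_variant == "reported") 1 / (du + dv) else 1 / (du * dv),
    H   = 2 / (du + dv),
    HM  = (du + dv)^2,
    F   = du^2 + dv^2,
    RR  = sqrt(du * dv),
    RA  = 1 / sqrt(du * dv),
    S   = 1 / sqrt(du + dv),
    GA  = 2 * sqrt(du * dv) / (du + dv),
    ABC = sqrt((du + dv - 2) / (du * dv))
  )
}

match_index <- function(index) {
  if (!is.character(index) || length(index) != 1 || !index %in% index_ids()) {
    rlang::abort(
      sprintf("Unknown index '%s'; expected one of %s.",
              paste(index, collapse = ","), paste(index_ids(), collapse = ", ")),
      class = "tiqspr_error_index"
    )
  }
  index
}

#' Value of a topological index from an edge partition
#'
#' Computes \eqn{\sum_{(d_u,d_v)} \text{count} \cdot f(d_u, d_v)} over the
#' partition entries. For M1, M2, HM and F with integer degrees the result is
#' an exact integer.
#'
#' @param partition Anything [as_edge_partition()] accepts.
#' @inheritParams edge_weight
#' @return A single non-negative number.
#' @examples
#' p <- data.frame(du = 2, dv = 2, count = 6) # 6-cycle
#' index_value(p, "H") # 6
#' @export
index_value <- function(partition, index, mm2_variant = c("reported", "literature")) {
  p <- as_edge_partition(partition)
  sum(p$count * edge_weight(index, p$du, p$dv, mm2_variant = mm2_variant))
}

#' Descriptor table for a set of compounds
#'
#' Computes all (or a subset of) the eleven indices for each compound from its
#' stored edge partition.
#'
#' @param compounds A compound tibble (see [read_compounds()]).
#' @param indices Character vector of index identifiers; defaults to all
#'   eleven in report order.
#' @inheritParams edge_weight
#' @return A tibble with one row per compound, in input order: column
#'   `compound` followed by one numeric column per index.
#' @examples
#' compute_indices(sulfonamide_compounds())
#' @export
compute_indices <- function(compounds, indices = index_ids(),
                            mm2_variant = c("reported", "literature")) {
  stopifnot(is.data.frame(compounds), nrow(compounds) >= 1)
  mm2_variant <- match.arg(mm2_variant)
  purrr::walk(indices, match_index)
  vals <- purrr::map(compounds$partition, function(p) {
    tibble::as_tibble(purrr::map(
      stats::setNames(indices, indices),
      ~ index_value(p, .x, mm2_variant = mm2_variant)
    ))
  })
  dplyr::bind_cols(tibble::tibble(compound = compounds$compound),
                   dplyr::bind_rows(vals))
}

#' Topological index by direct edge iteration
#'
#' Computes an index by walking the graph's edges one at a time and summing
#' the per-edge weights, never building an edge partition. This is an
#' independent route to the same value as
#' `index_value(edge_partition(graph), index)`; the two serve as mutual
#' cross-checks.
#'
#' @param graph A [molecular_graph()].
#' @inheritParams edge_weight
#' @return A single non-negative number.
#' @export
edgewise_index <- function(graph, index, mm2_variant = c("reported", "literature")) {
  stopifnot(inherits(graph, "molecular_graph"))
  index <- match_index(index)
  mm2_variant <- match.arg(mm2_variant)
  deg <- vertex_degrees(graph)
  d <- stats::setNames(deg$degree, deg$vertex)
  total <- 0
  for (i in seq_len(nrow(graph$edges))) {
    a <- d[[graph$edges$from[i]]]
    b <- d[[graph$edges$to[i]]]
    total <- total + edge_weight(index, min(a, b), max(a, b), mm2_variant = mm2_variant)
  }
  total
}
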