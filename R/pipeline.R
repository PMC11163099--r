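#' Originally reported descriptor table for the sulfonamide compounds
#'
#' The descriptor values as printed in the source study for the five
#' sulfonamide derivatives (floats at two decimal places, with its rounding
#' and arithmetic slips intact). Used only for the discrepancy audit
#' ([reported_deltas()]); all analysis in this package recomputes descriptors
#' from the edge partitions.
#'
#' @return A tibble shaped like [compute_indices()] output: `compound` plus
#'   the eleven index columns.
#' @export
reported_descriptors <- function() {
  tibble::tibble(
    compound = sulfonamide_names(),
    M1 = c(136, 186, 172, 150, 170),
    M2 = c(162, 222, 204, 180, 211),
    mM2 = c(5.58, 7.19, 6.54, 6.33, 6.35),
    H = c(11.18, 14.39, 13.09, 12.49, 12.71),
    HM = c(714, 996, 930, 780, 954),
    F = c(390, 552, 522, 420, 532),
    RR = c(64.17, 87.09, 79.67, 72.66, 78.86),
    RA = c(12.01, 15.56, 14.4, 13.2, 13.98),
    S = c(12.22, 16.03, 14.63, 13.67, 14.21),
    GA = c(25.38, 33.61, 30.38, 28.62, 29.5),
    ABC = c(19.82, 26.67, 24.76, 21.82, 23.94)
  )
}

sulfonamide_names <- function() {
  c("4-[(2,4-dichlorophenylsulfonamido)methyl]cyclohexanecarboxylic acid",
    "ethyl 4-[(naphthalene-2-sulfonamido)methyl]cyclohexanecarboxylate",
    "ethyl 4-[(2,5-dichlorophenylsulfonamido)methyl]cyclohexanecarboxylate",
    "4-[(naphthalene-2-sulfonamido)methyl]cyclohexane-1-carboxylic acid",
    "(2S)-3-methyl-2-(naphthalene-1-sulfonamido)-butanoic acid")
}

#' Audit recomputed descriptors against reported values
#'
#' Compares a recomputed descriptor table cell-by-cell with a reference table
#' of originally reported values and lists every divergent cell with both
#' values — so no discrepancy is ever silent. Indices whose exact value is an
#' integer (M1, M2, HM, F) are compared exactly; the remaining indices, which
#' the reference reports rounded to two decimals, are compared at `tol`.
#'
#' @param computed Descriptor table from [compute_indices()].
#' @param reference Reference table with the same columns; defaults to
#'   [reported_descriptors()].
#' @param tol Tolerance for non-integer-valued indices. The default 0.015
#'   allows half-ULP rounding of two-decimal values plus truncation-style
#'   rounding seen in the reference.
#' @return A tibble with columns `compound`, `index`, `computed`, `reported`,
#'   `difference`, one row per divergent cell (zero rows if all agree).
#' @export
reported_deltas <- function(computed, reference = reported_descriptors(), tol = 0.015) {
  idx <- intersect(index_ids(), intersect(names(computed), names(reference)))
  long <- function(tbl, val) {
    tidyr::pivot_longer(tbl[c("compound", idx)], -"compound",
                        names_to = "index", values_to = val)
  }
  merged <- dplyr::inner_join(long(computed, "computed"), long(reference, "reported"),
                              by = c("compound", "index"))
  integer_idx <- c("M1", "M2", "HM", "F")
  compound_order <- computed$compound
  merged |>
    dplyr::mutate(difference = .data$computed - .data$reported) |>
    dplyr::filter(abs(.data$difference) >
                    ifelse(.data$index %in% integer_idx, 0, tol)) |>
    dplyr::arrange(match(.data$index, index_ids()),
                   match(.data$compound, !!compound_order))
}

#' Run the full QSPR analysis
#'
#' Orchestrates every stage: load (or accept) compound records, compute the
#' descriptor table, the index-property correlation table, all
#' property-by-index linear models with inference statistics, the
#' standard-error table, and the actual-versus-predicted table for each
#' property; optionally audits the descriptors against a reference table and
#' writes every table as CSV.
#'
#' Any stage failure is reported with the stage name, and partially written
#' output files are removed. The result is a pure function of the input
#' records and options.
#'
#' @param compounds A compound tibble (see [read_compounds()]) or a path to a
#'   compound JSON file.
#' @param output_dir Optional directory; when given, writes
#'   `index_table.csv`, `correlations.csv`, `stats_table.csv`,
#'   `standard_errors.csv`, `predictions_mp.csv`, `predictions_fw.csv` and
#'   `reported_deltas.csv` (full precision; round only for display).
#' @param mm2_variant Passed to [compute_indices()].
#' @param reference Optional reference descriptor table for the discrepancy
#'   audit (e.g. [reported_descriptors()] when analysing the packaged
#'   sulfonamides); `NULL` skips the audit.
#' @param indices_only If `TRUE`, stop after the descriptor table (allows
#'   fewer than 3 compounds).
#' @return A `qspr_report` object: a list with tibbles `descriptors`,
#'   `correlations`, `models`, `standard_errors`, `predictions` (named list
#'   with one table per property) and `deltas`.
#' @examples
#' rep <- run_qspr(sulfonamide_compounds(), reference = reported_descriptors())
#' rep$correlations
#' @export
run_qspr <- function(compounds, output_dir = NULL,
                     mm2_variant = c("reported", "literature"),
                     reference = NULL, indices_only = FALSE) {
  mm2_variant <- match.arg(mm2_variant)
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      rlang::abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
                   class = "tiqspr_error_stage", parent = e)
    })
  }

  compounds <- stage("load", {
    if (is.character(compounds)) read_compounds(compounds) else {
      stopifnot(is.data.frame(compounds), nrow(compounds) >= 1)
      compounds
    }
  })

  descriptors <- stage("indices", compute_indices(compounds, mm2_variant = mm2_variant))
  deltas <- stage("delta_audit", {
    if (is.null(reference)) {
      tibble::tibble(compound = character(), index = character(),
                     computed = numeric(), reported = numeric(),
                     difference = numeric())
    } else {
      reported_deltas(descriptors, reference)
    }
  })

  if (indices_only) {
    bundle <- new_qspr_report(descriptors, NULL, NULL, NULL, NULL, deltas, mm2_variant)
    write_report_csvs(bundle, output_dir)
    return(bundle)
  }

  if (nrow(compounds) < 3) {
    rlang::abort(
      sprintf("Stage 'regression' needs at least 3 compounds (got %d); use `indices_only = TRUE` below that.",
              nrow(compounds)),
      class = "tiqspr_error_insufficient_data"
    )
  }

  data <- dplyr::left_join(
    descriptors,
    compounds[c("compound", "melting_point", "formula_weight")],
    by = "compound"
  )
  correlations <- stage("correlations", correlation_table(data))
  models <- stage("regression", fit_qspr_models(data))
  ses <- stage("standard_errors", standard_error_table(models))
  predictions <- stage("predictions", list(
    melting_point = prediction_table(models, data, "melting_point"),
    formula_weight = prediction_table(models, data, "formula_weight")
  ))

  bundle <- new_qspr_report(descriptors, correlations, models, ses, predictions,
                            deltas, mm2_variant)
  stage("write", {
    written <<- write_report_csvs(bundle, output_dir)
  })
  bundle
}

new_qspr_report <- function(descriptors, correlations, models, standard_errors,
                            predictions, deltas, mm2_variant) {
  structure(
    list(descriptors = descriptors, correlations = correlations,
         models = models, standard_errors = standard_errors,
         predictions = predictions, deltas = deltas,
         mm2_variant = mm2_variant),
    class = "qspr_report"
  )
}

write_report_csvs <- function(bundle, output_dir) {
  if (is.null(output_dir)) return(character(0))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(tbl, file) {
    if (is.null(tbl)) return()
    path <- file.path(output_dir, file)
    readr::write_csv(tbl, path)
    written <<- c(written, path)
  }
  put(bundle$descriptors, "index_table.csv")
  put(bundle$correlations, "correlations.csv")
  if (!is.null(bundle$models)) {
    stats_tbl <- bundle$models |>
      dplyr::select(-"fit") |>
      dplyr::rename(N = "n", r = "r_abs", `F` = "f_stat", p = "p_value") |>
      dplyr::mutate(indicator = ifelse(.data$significant, "Significant", "Non-Significant")) |>
      dplyr::select(-"significant", -"se_estimate")
    put(stats_tbl, "stats_table.csv")
  }
  put(bundle$standard_errors, "standard_errors.csv")
  put(bundle$predictions$melting_point, "predictions_mp.csv")
  put(bundle$predictions$formula_weight, "predictions_fw.csv")
  put(bundle$deltas, "reported_deltas.csv")
  written
}

#' @export
print.qspr_report <- function(x, ...) {
  cat(sprintf("<qspr_report> %d compounds, mM2 variant '%s'\n",
              nrow(x$descriptors), x$mm2_variant))
  cat("Descriptors (rounded to 2 d.p.):\n")
  print(dplyr::mutate(x$descriptors,
                      dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2))))
  if (!is.null(x$models)) {
    sig <- dplyr::filter(x$models, .data$significant)
    cat(sprintf("\n%d of %d models significant at p < 0.05", nrow(sig), nrow(x$models)))
    if (nrow(sig) > 0) {
      cat(": ", paste(sprintf("%s ~ %s (p = %.4f)", sig$property, sig$index, sig$p_value),
                      collapse = ", "), sep = "")
    }
    cat("\n")
  }
  if (!is.null(x$deltas) && nrow(x$deltas) > 0) {
    cat(sprintf("%d descriptor cells differ from the reported reference (see $deltas).\n",
                nrow(x$deltas)))
  }
  invisible(x)
}
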