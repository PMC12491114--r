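#' Incremental cost-effectiveness comparison
#'
#' Computes incremental cost and effect of an intervention over a comparator
#' on unrounded totals, classifies the cost-effectiveness plane quadrant, and
#' reports either the ICER (north-east and south-west quadrants) or a
#' dominance label: `"dominant"` when the intervention is cheaper and more
#' effective, `"dominated"` when it is costlier and less effective.
#'
#' @param intervention,comparator `econ_outcome` objects (see [accrue()]),
#'   run under the same configuration.
#' @param labels Length-2 character vector naming intervention and comparator
#'   in reports.
#' @return An `incremental_result`: list with `delta_cost`, `delta_effect`,
#'   `icer` (`NA` when a label applies), `label` (`NA_character_` when the
#'   ICER is numeric), and `quadrant` (`"NE"`, `"NW"`, `"SE"`, `"SW"`).
#' @examples
#' a <- structure(list(total_cost = 30000, total_qaly = 1.5), class = "econ_outcome")
#' b <- structure(list(total_cost = 20000, total_qaly = 1.0), class = "econ_outcome")
#' compare_strategies(a, b)$icer   # 20000
#' @export
compare_strategies <- function(intervention, comparator,
                               labels = c("intervention", "comparator")) {
  stopifnot(inherits(intervention, "econ_outcome"),
            inherits(comparator, "econ_outcome"))
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qaly - comparator$total_qaly
  quadrant <- paste0(if (dc >= 0) "N" else "S", if (de >= 0) "E" else "W")
  icer <- NA_real_
  label <- NA_character_
  if (de == 0) {
    # no effect difference: no division; direction conveyed by delta_cost
    label <- if (dc == 0) "equivalent" else if (dc < 0) "dominant" else "dominated"
  } else if (dc < 0 && de > 0) {
    label <- "dominant"
  } else if (dc > 0 && de < 0) {
    label <- "dominated"
  } else {
    icer <- dc / de
  }
  structure(list(delta_cost = dc, delta_effect = de, icer = icer,
                 label = label, quadrant = quadrant, labels = labels,
                 intervention = intervention, comparator = comparator),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("<incremental_result> %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  incremental cost:   EUR %.0f\n", x$delta_cost))
  cat(sprintf("  incremental effect: %.4f QALYs\n", x$delta_effect))
  if (is.na(x$icer)) {
    cat(sprintf("  %s (%s quadrant)\n", x$label, x$quadrant))
  } else {
    cat(sprintf("  ICER: EUR %.0f per QALY (%s quadrant)\n", x$icer, x$quadrant))
  }
  invisible(x)
}

#' Serialize an incremental result to a plain list / JSON
#'
#' @param x An `incremental_result`.
#' @param file Optional path; when given, JSON is written there.
#' @return The plain list, invisibly when writing.
#' @export
incremental_to_json <- function(x, file = NULL) {
  out <- list(delta_cost = x$delta_cost, delta_effect = x$delta_effect,
              icer = x$icer, label = x$label, quadrant = x$quadrant)
  if (!is.null(file)) {
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                         na = "null")
    return(invisible(out))
  }
  out
}
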