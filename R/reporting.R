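#' Run a base-case analysis and produce its report
#'
#' Builds both arms of the requested model, runs the cohort engine, and
#' returns a run report: per-arm discounted totals, the incremental
#' comparison, death fractions at the horizon, and a configuration echo. When
#' `out_dir` is given, also writes per-arm trace CSVs, a JSON results file,
#' and a markdown table mirroring the layout of the published results table.
#'
#' @param model `"I"` or `"II"`.
#' @param params A [default_parameters()] list, or a path to a YAML parameter
#'   file.
#' @param out_dir Optional output directory.
#' @param ... Configuration overrides passed to the model builders
#'   (`horizon`, `annual_discount`, `cohort_size`, ...).
#' @return A `run_report` list: `model`, `arms` (named list of
#'   `econ_outcome`), `incremental`, `death_fraction` (per arm and average),
#'   `config`.
#' @examples
#' rep <- run_base("I")
#' rep$incremental$icer
#' @export
run_base <- function(model = c("I", "II"), params = default_parameters(),
                     out_dir = NULL, ...) {
  model <- match.arg(model)
  if (is.character(params)) params <- default_parameters(params)
  issues <- validate_params(params)
  if (nrow(issues)) {
    stop(paste0("run_base: invalid parameters:\n",
                paste(sprintf("  - %s: %s", issues$path, issues$rule),
                      collapse = "\n")), call. = FALSE)
  }
  build <- if (model == "I") build_model_I else build_model_II
  arms <- if (model == "I") c("PRLT_SoC", "SoC") else c("PRLT_SoC", "CBZ")
  outs <- lapply(arms, function(a) run_strategy(build(a, params, ...)))
  names(outs) <- arms
  incr <- compare_strategies(outs[[1]], outs[[2]], labels = arms)
  dfr <- vapply(outs, death_fraction, numeric(1))
  report <- structure(list(
    model = model, arms = outs, incremental = incr,
    death_fraction = c(dfr, average = mean(dfr)),
    config = attr(outs[[1]], "model")$config
  ), class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (a in arms) {
      write_trace_csv(outs[[a]]$trace,
                      file.path(out_dir, sprintf("model%s_%s_trace.csv", model, a)))
    }
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, sprintf("model%s_results.json", model)),
                         auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(report_markdown(report),
               file.path(out_dir, sprintf("model%s_results.md", model)))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> Model %s (%d cycles, %.1f%% discount, cohort %d)\n",
              x$model, x$config$horizon, 100 * x$config$annual_discount,
              x$config$cohort_size))
  for (a in names(x$arms)) {
    cat(sprintf("  %-10s cost EUR %8.0f   %.4f QALYs   death at horizon %.1f%%\n",
                a, x$arms[[a]]$total_cost, x$arms[[a]]$total_qaly,
                100 * x$death_fraction[[a]]))
  }
  print(x$incremental)
  invisible(x)
}

#' @rdname run_base
#' @param report A `run_report`.
#' @export
report_to_list <- function(report) {
  list(
    model = report$model,
    config = report$config[c("horizon", "annual_discount", "cohort_size",
                             "within_cycle_correction", "progression_rule")],
    arms = lapply(report$arms, function(o)
      list(total_cost = o$total_cost, total_qaly = o$total_qaly)),
    death_fraction = as.list(report$death_fraction),
    incremental = incremental_to_json(report$incremental)
  )
}

#' @rdname run_base
#' @export
report_markdown <- function(report) {
  arms <- names(report$arms)
  inc <- report$incremental
  icer_cell <- if (is.na(inc$icer)) inc$label else sprintf("%.0f", inc$icer)
  c(sprintf("### Model %s base case", report$model),
    "",
    sprintf("| | %s | %s |", arms[1], arms[2]),
    "|---|---|---|",
    sprintf("| Incurred costs (EUR) | %.0f | %.0f |",
            report$arms[[1]]$total_cost, report$arms[[2]]$total_cost),
    sprintf("| Incurred effect (QALY) | %.2f | %.2f |",
            report$arms[[1]]$total_qaly, report$arms[[2]]$total_qaly),
    sprintf("| Incremental costs (EUR) | %.0f | |", inc$delta_cost),
    sprintf("| Incremental effect (QALY) | %.2f | |", inc$delta_effect),
    sprintf("| ICER (EUR per QALY) | %s | |", icer_cell),
    sprintf("| Death-state share at horizon | %.1f%% | %.1f%% |",
            100 * report$death_fraction[[1]], 100 * report$death_fraction[[2]]))
}

#' Validate a parameter list against the model schema
#'
#' Checks that survival specifications are known distributions with valid
#' parameters, costs are non-negative, utilities lie in `[0, 1]`, the
#' third-line mix sums to 1, the configuration is usable, and each utility's
#' beta distribution has a mean consistent with its base value (within
#' 0.001).
#'
#' @param params A [default_parameters()] list (or path to a YAML file).
#' @return A data frame with columns `path` and `rule`, one row per
#'   violation; zero rows when the parameters are valid.
#' @examples
#' nrow(validate_params(default_parameters()))   # 0
#' @export
validate_params <- function(params) {
  if (is.character(params)) params <- default_parameters(params)
  bad <- list()
  note <- function(path, rule) bad[[length(bad) + 1L]] <<- data.frame(path = path, rule = rule)

  cfg <- params$model_config
  if (is.null(cfg$horizon) || cfg$horizon < 1) {
    note("model_config.horizon", "must be >= 1")
  }
  if (is.null(cfg$annual_discount) || cfg$annual_discount < 0) {
    note("model_config.annual_discount", "must be >= 0")
  }
  for (m in names(params$survival)) {
    for (a in names(params$survival[[m]])) {
      for (ep in names(params$survival[[m]][[a]])) {
        d <- params$survival[[m]][[a]][[ep]]
        path <- sprintf("survival.%s.%s.%s", m, a, ep)
        ok <- tryCatch({
          dist_from_list(if (inherits(d, c("surv_dist", "surv_piecewise"))) d
                         else d)
          TRUE
        }, error = function(e) conditionMessage(e))
        if (!isTRUE(ok)) note(path, ok)
      }
    }
  }
  for (m in names(params$values)) {
    for (a in names(params$values[[m]])) {
      for (s in names(params$values[[m]][[a]])) {
        v <- params$values[[m]][[a]][[s]]
        path <- sprintf("values.%s.%s.%s", m, a, s)
        if (is.null(v$cost) || v$cost < 0) note(paste0(path, ".cost"), "must be >= 0")
        if (is.null(v$utility) || v$utility < 0 || v$utility > 1) {
          note(paste0(path, ".utility"), "must be in [0, 1]")
        } else if (!is.null(v$beta1) && !is.null(v$beta2)) {
          if (v$beta1 <= 0 || v$beta2 <= 0) {
            note(paste0(path, ".beta"), "beta shapes must be > 0")
          } else if (abs(beta_mean(v$beta1, v$beta2) - v$utility) > 0.001) {
            note(paste0(path, ".beta"),
                 sprintf("beta mean %.4f inconsistent with utility %.4f",
                         beta_mean(v$beta1, v$beta2), v$utility))
          }
        }
        if (!is.null(v$cost_sd) && v$cost_sd <= 0) {
          note(paste0(path, ".cost_sd"), "must be > 0")
        }
      }
    }
  }
  mix <- unlist(params$third_line_mix)
  if (abs(sum(mix) - 1) > 1e-9 || any(mix < 0)) {
    note("third_line_mix", "weights must be >= 0 and sum to 1")
  }
  for (a in names(params$treatment_duration)) {
    if (params$treatment_duration[[a]] < 1) {
      note(sprintf("treatment_duration.%s", a), "must be >= 1")
    }
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(path = character(0), rule = character(0))
}
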