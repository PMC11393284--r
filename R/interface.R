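# Report writers tying the pipeline together: run a configured analysis
# and write the class-by-strategy, value-breakdown and sensitivity CSVs
# plus a JSON summary.

#' Configuration for a pipeline run
#'
#' The defaults reproduce the Danish benchmark setup: all five built-in
#' strategies, a spring census of 1000, a 0.02 collision floor, the
#' benchmark valuation and ±50% grouped sensitivity bounds.
#'
#' @param strategies `"all"` (the built-ins), a character vector of
#'   built-in ids, or a named list of [strategy_definition()] objects.
#' @param spring_target Spring census target (> 0).
#' @param baseline Collision mortality floor.
#' @param valuation A [valuation_parameters()] object or a path to a CSV
#'   readable by [read_valuation_csv()]; `NULL` for the benchmark.
#' @param sensitivity_factor Grouped variation fraction.
#' @param outdir Output directory for report files (created if absent).
#' @param verbose Print progress and provenance notes.
#' @return Object of class `run_config`.
#' @export
run_config <- function(strategies = "all", spring_target = 1000,
                       baseline = 0.02, valuation = NULL,
                       sensitivity_factor = 0.5,
                       outdir = tempfile("deer_cba_"), verbose = FALSE) {
  if (is.character(strategies)) {
    pool <- builtin_strategies()
    if (identical(strategies, "all")) {
      strategies <- pool
    } else {
      unknown <- setdiff(strategies, names(pool))
      if (length(unknown)) {
        stop("unknown strategy id(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
      }
      strategies <- pool[strategies]
    }
  }
  params <- if (is.null(valuation)) {
    benchmark_valuation()
  } else if (inherits(valuation, "valuation_parameters")) {
    valuation
  } else if (is.character(valuation)) {
    if (!file.exists(valuation)) {
      stop("valuation file not found: ", valuation, call. = FALSE)
    }
    read_valuation_csv(valuation)
  } else {
    stop("`valuation` must be NULL, a valuation_parameters object or a ",
         "CSV path", call. = FALSE)
  }
  structure(
    list(strategies = strategies, spring_target = spring_target,
         baseline = baseline, params = params,
         sensitivity_factor = sensitivity_factor,
         outdir = outdir, verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

#' Run the full analysis and write report files
#'
#' Executes [deer_cba()] under a [run_config()] and writes four files to
#' the output directory: `cohort_classes.csv` (population and harvest per
#' strategy and class), `value_breakdown.csv` (per-class and total values
#' and costs per strategy), `sensitivity.csv` (grouped bounds) and
#' `summary.json` (full-precision net benefits, the recommendation, sex
#' ratio checks and rate-provenance notes). CSV amounts are rounded to
#' whole individuals / DKK; the JSON carries full precision. Output is
#' deterministic: identical configs give byte-identical files.
#'
#' @param config A [run_config()].
#' @return The [deer_cba()] object, invisibly, with a `files` attribute
#'   naming the written reports.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  fit <- deer_cba(strategies = config$strategies,
                  params = config$params,
                  spring_target = config$spring_target,
                  baseline = config$baseline,
                  sensitivity_factor = config$sensitivity_factor)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    cohorts = file.path(config$outdir, "cohort_classes.csv"),
    values = file.path(config$outdir, "value_breakdown.csv"),
    sensitivity = file.path(config$outdir, "sensitivity.csv"),
    summary = file.path(config$outdir, "summary.json")
  )

  cohorts <- do.call(rbind, lapply(names(fit$aggregates), function(id) {
    agg <- fit$aggregates[[id]]
    data.frame(strategy = id, class = agg$class,
               population = round(agg$population),
               harvest = round(agg$harvest), stringsAsFactors = FALSE)
  }))
  utils::write.csv(cohorts, files[["cohorts"]], row.names = FALSE)

  values <- do.call(rbind, lapply(names(fit$breakdowns), function(id) {
    bd <- fit$breakdowns[[id]]
    by_class <- bd$by_class
    rbind(
      data.frame(strategy = id, class = by_class$class,
                 meat = round(by_class$meat),
                 recreational = round(by_class$recreational),
                 browsing = round(by_class$browsing),
                 traffic = round(by_class$traffic),
                 net_benefit = NA_real_, stringsAsFactors = FALSE),
      data.frame(strategy = id, class = "total",
                 meat = round(bd$totals[["meat"]]),
                 recreational = round(bd$totals[["recreational"]]),
                 browsing = round(bd$totals[["browsing"]]),
                 traffic = round(bd$totals[["traffic"]]),
                 net_benefit = round(bd$net_benefit),
                 stringsAsFactors = FALSE)
    )
  }))
  utils::write.csv(values, files[["values"]], row.names = FALSE)

  sens <- as.data.frame(fit$sensitivity)
  sens[c("lower", "benchmark", "upper")] <-
    lapply(sens[c("lower", "benchmark", "upper")], round)
  utils::write.csv(sens, files[["sensitivity"]], row.names = FALSE)

  provenance <- lapply(fit$schedules, function(s) {
    lapply(s$provenance, function(p) {
      list(derived_ages = which(p == "derived") - 1L,
           floor_ages = which(p == "floor") - 1L)
    })
  })
  summary_obj <- list(
    config = list(spring_target = config$spring_target,
                  baseline = config$baseline,
                  sensitivity_factor = config$sensitivity_factor),
    net_benefits = as.list(fit$net_benefits),
    decision = fit$decision[c("decision", "strategy", "net_benefit")],
    sex_ratio = lapply(fit$sex_ratio, function(x) {
      x[c("ok", "ratio", "mature_stags", "females_1plus")]
    }),
    provenance = provenance
  )
  writeLines(jsonlite::toJSON(summary_obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"),
             files[["summary"]])
  if (config$verbose) {
    message("wrote ", paste(basename(files), collapse = ", "),
            " to ", config$outdir)
  }
  attr(fit, "files") <- files
  invisible(fit)
}

#' Write a cohort table as CSV
#'
#' One row per sex and age with the population, total deaths, hunting
#' harvest and collision deaths.
#'
#' @param table A `cohort_table`.
#' @param path CSV file path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  utils::write.csv(
    as.data.frame(table)[c("sex", "age", "population", "deaths",
                           "harvest", "collisions")],
    path, row.names = FALSE)
  invisible(path)
}
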