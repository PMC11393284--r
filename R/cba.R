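# Decision rules over strategies and the grouped +/-50% sensitivity
# analysis, plus the deer_cba() driver that runs the whole pipeline.

SENS_GROUPS <- c("meat", "recreational", "browsing", "traffic")

#' Rank strategies and apply the decision rules
#'
#' Given annual net benefits per strategy: implement the strategy with the
#' highest NB if that NB is positive; if every NB is negative, the
#' zero-population alternative (NB = 0) dominates and the population
#' should be driven to extinction; a maximal NB of exactly zero is
#' indifferent to extinction, and tied maxima are reported as
#' indifference.
#'
#' @param net_benefits Named numeric vector of annual net benefits
#'   (DKK/yr), one per strategy.
#' @return List with `decision` (`"implement"`, `"extinction"` or
#'   `"indifferent"`), `strategy` (recommended id(s), or `NA` for
#'   extinction), `net_benefit` of the best strategy, and the input
#'   ranking.
#' @examples
#' rank_and_decide(c(a = 5, b = 3))        # implement a
#' rank_and_decide(c(a = -10, b = -5))     # extinction
#' @export
rank_and_decide <- function(net_benefits) {
  if (length(net_benefits) == 0) {
    stop("net_benefits must contain at least one strategy", call. = FALSE)
  }
  if (any(!is.finite(net_benefits))) {
    stop("net_benefits must be finite", call. = FALSE)
  }
  if (is.null(names(net_benefits))) {
    names(net_benefits) <- seq_along(net_benefits)
  }
  ranking <- sort(net_benefits, decreasing = TRUE)
  best <- ranking[1]
  tied <- names(net_benefits)[net_benefits == best]
  decision <-
    if (best > 0 && length(tied) == 1L) "implement"
    else if (best > 0) "indifferent"
    else if (best == 0) "indifferent"
    else "extinction"
  list(
    decision = decision,
    strategy = if (decision == "extinction") NA_character_ else tied,
    net_benefit = if (decision == "extinction") 0 else unname(best),
    ranking = ranking
  )
}

# Rescale one parameter group of a valuation by `factor`.
scale_valuation_group <- function(params, group, factor) {
  group <- match.arg(group, SENS_GROUPS)
  switch(group,
    meat = { params$meat_price <- params$meat_price * factor },
    recreational = { params$recreational <- params$recreational * factor },
    browsing = { params$browsing <- params$browsing * factor },
    # the traffic group is the product alpha * t_i; scale the constants
    traffic = { params$traffic <- params$traffic * factor }
  )
  params
}

#' Grouped sensitivity bounds on the net benefit
#'
#' Varies the four marginal value/cost groups (meat values `m*w_i`,
#' recreational values `r_i`, browsing costs `b_i`, traffic costs
#' `alpha*t_i`) one group at a time by a common factor (default +/-50%),
#' all classes simultaneously. Because the net benefit is linear in each
#' group, each bound equals the benchmark NB plus or minus
#' `factor * group_total`; the upper bound of a value raises NB, the upper
#' bound of a cost lowers it.
#'
#' @param breakdowns Named list of [net_benefit()] results, one per
#'   strategy, computed at the benchmark.
#' @param factor Variation fraction in `(0, 1]` (default 0.5).
#' @param method `"identity"` (default) uses the exact linearity identity;
#'   `"recompute"` rescales the parameter set and revalues the aggregate,
#'   an independent path used as a cross-check.
#' @return Object of class `sensitivity_table`: data frame with columns
#'   `strategy`, `group`, `lower`, `benchmark`, `upper`.
#' @examples
#' fit <- deer_cba()
#' sensitivity_table(fit$breakdowns)
#' @export
sensitivity_table <- function(breakdowns, factor = 0.5,
                              method = c("identity", "recompute")) {
  method <- match.arg(method)
  if (!is.finite(factor) || factor <= 0 || factor > 1) {
    stop("factor must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(names(breakdowns))) {
    names(breakdowns) <- seq_along(breakdowns)
  }
  rows <- lapply(names(breakdowns), function(id) {
    bd <- breakdowns[[id]]
    stopifnot(inherits(bd, "net_benefit_breakdown"))
    nb <- bd$net_benefit
    sign <- c(meat = 1, recreational = 1, browsing = -1, traffic = -1)
    vals <- lapply(SENS_GROUPS, function(g) {
      if (method == "identity") {
        delta <- factor * bd$totals[[g]]
        c(lower = nb - sign[[g]] * delta, upper = nb + sign[[g]] * delta)
      } else {
        if (is.null(bd$aggregate) || is.null(bd$params)) {
          stop("recomputation path needs a breakdown with its aggregate ",
               "and parameters", call. = FALSE)
        }
        lo <- net_benefit(bd$aggregate,
                          scale_valuation_group(bd$params, g, 1 - factor))
        hi <- net_benefit(bd$aggregate,
                          scale_valuation_group(bd$params, g, 1 + factor))
        c(lower = lo$net_benefit, upper = hi$net_benefit)
      }
    })
    data.frame(
      strategy = id,
      group = SENS_GROUPS,
      lower = vapply(vals, `[[`, numeric(1), "lower"),
      benchmark = nb,
      upper = vapply(vals, `[[`, numeric(1), "upper"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sensitivity_table", "data.frame"),
            factor = factor, method = method)
}

#' Cost-benefit analysis of red deer management strategies
#'
#' Runs the full pipeline for a set of management strategies: resolve each
#' strategy to a mortality schedule, build the stationary cohort table at
#' the common spring census, collapse to the eight sex/age classes, value
#' with the net-benefit function, then apply the decision rules and the
#' grouped sensitivity analysis.
#'
#' All strategies share the same spring census so the comparison isolates
#' the composition (not the size) of the population and harvest.
#'
#' @param strategies Named list of [strategy_definition()] objects
#'   (default: the five built-ins).
#' @param params A [valuation_parameters()] object (default: the Danish
#'   benchmark).
#' @param spring_target Common spring census (default 1000).
#' @param baseline Collision mortality floor (default 0.02).
#' @param sensitivity_factor Grouped variation fraction (default 0.5).
#' @return Object of class `deer_cba`: list with `strategies`, `tables`
#'   (cohort tables), `aggregates`, `breakdowns`, `net_benefits` (named
#'   vector), `decision` ([rank_and_decide()] output), `sensitivity`
#'   ([sensitivity_table()]), `sex_ratio` checks and the configuration.
#' @examples
#' fit <- deer_cba()
#' fit                 # ranking and recommendation
#' summary(fit)        # per-strategy value/cost totals
#' @export
deer_cba <- function(strategies = builtin_strategies(),
                     params = benchmark_valuation(),
                     spring_target = 1000,
                     baseline = 0.02,
                     sensitivity_factor = 0.5) {
  if (is.null(names(strategies))) {
    names(strategies) <- vapply(strategies, `[[`, character(1), "id")
  }
  schedules <- lapply(strategies, resolve_schedule, baseline = baseline)
  tables <- lapply(schedules, stationary_table,
                   spring_target = spring_target)
  aggregates <- lapply(tables, aggregate_classes)
  breakdowns <- lapply(aggregates, net_benefit, params = params)
  net_benefits <- vapply(breakdowns, `[[`, numeric(1), "net_benefit")
  sex_ratio <- lapply(tables, function(t) {
    withCallingHandlers(check_sex_ratio(t),
                        warning = function(w) invokeRestart("muffleWarning"))
  })
  structure(
    list(strategies = strategies,
         schedules = schedules,
         tables = tables,
         aggregates = aggregates,
         breakdowns = breakdowns,
         net_benefits = net_benefits,
         decision = rank_and_decide(net_benefits),
         sensitivity = sensitivity_table(breakdowns,
                                         factor = sensitivity_factor),
         sex_ratio = sex_ratio,
         config = list(spring_target = spring_target, baseline = baseline,
                       sensitivity_factor = sensitivity_factor)),
    class = "deer_cba"
  )
}

#' @export
print.deer_cba <- function(x, ...) {
  cat("Cost-benefit analysis of red deer management strategies\n")
  cat(sprintf("  spring census %g, collision floor %g, sensitivity +/-%g%%\n",
              x$config$spring_target, x$config$baseline,
              100 * x$config$sensitivity_factor))
  cat("\n  Annual net benefit (DKK/yr):\n")
  for (id in names(x$decision$ranking)) {
    cat(sprintf("    %-4s %-55s %12.0f\n", id,
                x$strategies[[id]]$label, x$decision$ranking[[id]]))
  }
  d <- x$decision
  cat("\n  Recommendation: ")
  if (d$decision == "implement") {
    cat(sprintf("implement strategy %s (%s)\n", d$strategy,
                x$strategies[[d$strategy]]$label))
  } else if (d$decision == "extinction") {
    cat("all strategies yield negative net benefit; the zero-population\n",
        "  alternative (NB = 0) dominates (extinction rule)\n", sep = "")
  } else {
    cat("indifferent between:", paste(d$strategy, collapse = ", "), "\n")
  }
  flagged <- names(x$sex_ratio)[!vapply(x$sex_ratio, `[[`, logical(1), "ok")]
  if (length(flagged)) {
    cat("  Note: polygyny sex-ratio minimum violated under strategy",
        paste(flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.deer_cba <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$breakdowns), function(id) {
    bd <- object$breakdowns[[id]]
    data.frame(strategy = id,
               label = object$strategies[[id]]$label,
               meat = bd$totals[["meat"]],
               recreational = bd$totals[["recreational"]],
               browsing = bd$totals[["browsing"]],
               traffic = bd$totals[["traffic"]],
               net_benefit = bd$net_benefit,
               sex_ratio_ok = object$sex_ratio[[id]]$ok,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(totals = tab, decision = object$decision,
                 sensitivity = object$sensitivity,
                 config = object$config),
            class = "summary.deer_cba")
}

#' @export
print.summary.deer_cba <- function(x, ...) {
  cat("Per-strategy annual totals (DKK/yr):\n")
  tab <- x$totals
  tab[c("meat", "recreational", "browsing", "traffic", "net_benefit")] <-
    lapply(tab[c("meat", "recreational", "browsing", "traffic",
                 "net_benefit")], round)
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("\nSensitivity bounds (+/-%g%%, grouped):\n",
              100 * attr(x$sensitivity, "factor")))
  sens <- as.data.frame(x$sensitivity)
  sens[c("lower", "benchmark", "upper")] <-
    lapply(sens[c("lower", "benchmark", "upper")], round)
  print.data.frame(sens, row.names = FALSE)
  invisible(x)
}
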