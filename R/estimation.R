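# Cull-based population estimator and collision-probability calculation
# used to parameterize the browsing and traffic cost terms.

#' Estimate a population from cull statistics
#'
#' Reconstructs a spring population from game-bag statistics:
#' `N = C * L * lambda / eta`, where `C` is the seasonal cull, `L` the
#' mean age of harvested deer (longevity, years), `lambda` the annual
#' population growth rate and `eta` the proportion of all deaths due to
#' culling.
#'
#' @param culled Individuals reported culled in a season (`C >= 0`).
#' @param longevity Mean age of harvested deer, years (`L > 0`).
#' @param growth Annual growth rate (`lambda > 0`; below 1 for a
#'   declining population).
#' @param cull_share Proportion of deaths due to culling, in `(0, 1]`.
#' @return List with `estimate` (unrounded) and `rounded` (nearest
#'   individual).
#' @examples
#' population_from_cull(9745, 2.91, 0.971, 0.97)$rounded   # 28387
#' @export
population_from_cull <- function(culled, longevity, growth, cull_share) {
  if (culled < 0) stop("culled must be >= 0", call. = FALSE)
  if (longevity <= 0) stop("longevity must be > 0", call. = FALSE)
  if (growth <= 0) stop("growth must be > 0", call. = FALSE)
  if (cull_share <= 0 || cull_share > 1) {
    stop("cull_share must lie in (0, 1]", call. = FALSE)
  }
  est <- culled * longevity * growth / cull_share
  list(estimate = est, rounded = round(est))
}

#' Annual probability of a red deer vehicle collision
#'
#' The count of registered collisions involving red deer is the national
#' deer-collision total scaled by the red deer share of tracking callouts;
#' dividing by the spring population gives the per-individual annual
#' collision probability, capped at 1.
#'
#' @param total_deer_collisions Registered vehicle collisions with deer of
#'   any species.
#' @param red_deer_callouts,all_deer_callouts Tracking callouts involving
#'   red deer, and in total (`all_deer_callouts > 0`).
#' @param spring_population Spring population (> 0), e.g. from
#'   [population_from_cull()].
#' @param round_intermediate Round the red deer collision count to a whole
#'   number of individuals before dividing (default `FALSE`: the
#'   unrounded count is carried through).
#' @return Probability in `[0, 1]`.
#' @examples
#' N <- population_from_cull(9745, 2.91, 0.971, 0.97)$estimate
#' round(collision_probability(12000, 295, 6862, N), 4)   # 0.0182
#' @export
collision_probability <- function(total_deer_collisions, red_deer_callouts,
                                  all_deer_callouts, spring_population,
                                  round_intermediate = FALSE) {
  if (total_deer_collisions < 0 || red_deer_callouts < 0) {
    stop("collision counts must be >= 0", call. = FALSE)
  }
  if (all_deer_callouts <= 0) {
    stop("all_deer_callouts must be > 0", call. = FALSE)
  }
  if (spring_population <= 0) {
    stop("spring_population must be > 0", call. = FALSE)
  }
  red_collisions <- total_deer_collisions * red_deer_callouts /
    all_deer_callouts
  if (round_intermediate) red_collisions <- floor(red_collisions)
  min(red_collisions / spring_population, 1)
}

#' Browsing damage cost per individual
#'
#' Divides a total annual browsing damage cost by the pre-hunting-season
#' population (browsing occurs mainly in spring and summer, before the
#' season). The result feeds [allocate_by_weight()] for per-class costs.
#'
#' @param total_annual_cost Total browsing damage cost, DKK/yr.
#' @param pre_season_population Pre-season population (> 0).
#' @return Marginal browsing cost, DKK per individual per year.
#' @export
browsing_cost_per_individual <- function(total_annual_cost,
                                         pre_season_population) {
  if (pre_season_population <= 0) {
    stop("pre_season_population must be > 0", call. = FALSE)
  }
  if (total_annual_cost < 0) {
    stop("total_annual_cost must be >= 0", call. = FALSE)
  }
  total_annual_cost / pre_season_population
}
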