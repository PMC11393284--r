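# Eight-class aggregation and the annual net-benefit function.
#
# Classes follow the Danish management convention: female calves (FC),
# female yearlings (FY), adult females (FA, 2+), male calves (MC), male
# yearlings (MY), young stags (YS, 2-4), near-mature stags (NS, 5-7) and
# mature stags (MS, 8+). Meat and recreational values are proportional to
# the harvest of each class; browsing and traffic damage costs are
# proportional to its standing population.

CLASS_LEVELS <- c("FC", "FY", "FA", "MC", "MY", "YS", "NS", "MS")

class_ranges <- function() {
  data.frame(
    class = CLASS_LEVELS,
    sex = c("female", "female", "female", "male", "male", "male", "male",
            "male"),
    from = c(0L, 1L, 2L, 0L, 1L, 2L, 5L, 8L),
    to = c(0L, 1L, MAX_AGE, 0L, 1L, 4L, 7L, MAX_AGE),
    stringsAsFactors = FALSE
  )
}

#' Collapse a cohort table to the eight sex/age classes
#'
#' Sums populations and harvests over the management classes. The calf
#' classes (FC, MC) report the recruits entering the population and the
#' calf harvest; the remaining classes partition the spring census.
#'
#' @param table A `cohort_table` from [stationary_table()].
#' @return Object of class `class_aggregate`: data frame with columns
#'   `class`, `population`, `harvest` (eight rows, fixed class order).
#' @examples
#' tab <- stationary_table(resolve_schedule(builtin_strategies()[["2"]]))
#' round(aggregate_classes(tab)$population)   # MS rounds to 130
#' @export
aggregate_classes <- function(table) {
  rng <- class_ranges()
  agg <- do.call(rbind, lapply(seq_len(nrow(rng)), function(i) {
    sel <- table$sex == rng$sex[i] &
      table$age >= rng$from[i] & table$age <= rng$to[i]
    data.frame(class = rng$class[i],
               population = sum(table$population[sel]),
               harvest = sum(table$harvest[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(agg, class = c("class_aggregate", "data.frame"),
            n_spring = attr(table, "n_spring"))
}

#' Valuation parameters for the eight classes
#'
#' Annual marginal values and costs per sex/age class: a single meat price
#' (DKK/kg), carcass weights (kg), marginal recreational values
#' (DKK/harvested individual), marginal browsing damage costs
#' (DKK/individual/yr), traffic-damage cost constants (DKK/individual) and
#' the vehicle-collision probability. All monetary values are producer
#' prices in a common price year.
#'
#' @param meat_price Meat price, DKK per kg (same for all classes).
#' @param weight,recreational,browsing,traffic Numeric vectors of length 8
#'   in class order FC, FY, FA, MC, MY, YS, NS, MS (names optional).
#' @param collision_prob Annual probability a deer is involved in a
#'   registered vehicle collision.
#' @param price_year,price_nature Metadata (documentation only).
#' @return Object of class `valuation_parameters`.
#' @seealso [benchmark_valuation()] for the Danish benchmark values.
#' @export
valuation_parameters <- function(meat_price, weight, recreational,
                                 browsing, traffic, collision_prob,
                                 price_year = NA, price_nature = "producer") {
  as_class_vector <- function(x, what) {
    x <- as.numeric(x)
    if (length(x) != length(CLASS_LEVELS)) {
      stop(what, " must have length ", length(CLASS_LEVELS), call. = FALSE)
    }
    if (any(!is.finite(x) | x < 0)) {
      stop(what, " must be nonnegative and finite", call. = FALSE)
    }
    names(x) <- CLASS_LEVELS
    x
  }
  if (meat_price < 0) stop("meat_price must be >= 0", call. = FALSE)
  if (collision_prob < 0 || collision_prob > 1) {
    stop("collision_prob must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(meat_price = meat_price,
         weight = as_class_vector(weight, "weight"),
         recreational = as_class_vector(recreational, "recreational"),
         browsing = as_class_vector(browsing, "browsing"),
         traffic = as_class_vector(traffic, "traffic"),
         collision_prob = collision_prob,
         price_year = price_year, price_nature = price_nature),
    class = "valuation_parameters"
  )
}

#' Danish benchmark valuation
#'
#' The 2022 producer-price benchmark parameter set for red deer in
#' Denmark: informal-market meat price of 20 DKK/kg, sex/age-specific
#' carcass weights, benefit-transferred marginal recreational values
#' (trophy value embodied in the stag classes), adjusted-transfer browsing
#' damage costs, insurance-based traffic cost constants, and a 0.02
#' collision probability.
#'
#' @return A [valuation_parameters()] object.
#' @export
benchmark_valuation <- function() {
  valuation_parameters(
    meat_price = 20,
    weight = c(38.3, 60.0, 73.9, 40.7, 64.5, 113.6, 131.6, 118.7),
    recreational = c(3182, 3391, 3600, 3182, 3746, 5130, 6117, 7272),
    browsing = c(564, 898, 1094, 607, 950, 1677, 1939, 1818),
    traffic = c(12423, 19787, 24101, 13364, 20922, 36946, 42720, 40060),
    collision_prob = 0.02,
    price_year = 2022
  )
}

#' Annual net benefit of a population/harvest composition
#'
#' Values a class aggregate with a valuation parameter set. Per class `i`:
#' meat value `m * w_i * h_i`, recreational value `r_i * h_i`, browsing
#' cost `b_i * n_i`, traffic cost `alpha * t_i * n_i`. The net benefit is
#' the exact signed sum
#' `NB = (meat + recreational) - (browsing + traffic)`.
#'
#' @param aggregate A [aggregate_classes()] result, or any data frame with
#'   `class`, `population`, `harvest` rows covering all eight classes.
#' @param params A [valuation_parameters()] object.
#' @return Object of class `net_benefit_breakdown`: list with `by_class`
#'   (per-class terms), `totals` (named: meat, recreational, browsing,
#'   traffic), `net_benefit`, and the inputs (`aggregate`, `params`) for
#'   downstream recomputation.
#' @examples
#' tab <- stationary_table(resolve_schedule(builtin_strategies()[["3"]]))
#' net_benefit(aggregate_classes(tab), benchmark_valuation())
#' @export
net_benefit <- function(aggregate, params) {
  stopifnot(inherits(params, "valuation_parameters"))
  missing <- setdiff(CLASS_LEVELS, aggregate$class)
  if (length(missing)) {
    stop("aggregate is missing class(es): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  i <- match(CLASS_LEVELS, aggregate$class)
  n <- aggregate$population[i]
  h <- aggregate$harvest[i]
  by_class <- data.frame(
    class = CLASS_LEVELS,
    population = n,
    harvest = h,
    meat = params$meat_price * params$weight * h,
    recreational = params$recreational * h,
    browsing = params$browsing * n,
    traffic = params$collision_prob * params$traffic * n,
    stringsAsFactors = FALSE
  )
  rownames(by_class) <- NULL
  totals <- c(meat = sum(by_class$meat),
              recreational = sum(by_class$recreational),
              browsing = sum(by_class$browsing),
              traffic = sum(by_class$traffic))
  structure(
    list(by_class = by_class, totals = totals,
         net_benefit = (totals[["meat"]] + totals[["recreational"]]) -
           (totals[["browsing"]] + totals[["traffic"]]),
         aggregate = aggregate, params = params),
    class = "net_benefit_breakdown"
  )
}

#' @export
print.net_benefit_breakdown <- function(x, ...) {
  cat("Annual net benefit breakdown (DKK)\n")
  t <- x$totals
  cat(sprintf("  meat value:          %12.0f\n", t[["meat"]]))
  cat(sprintf("  recreational value:  %12.0f\n", t[["recreational"]]))
  cat(sprintf("  browsing cost:       %12.0f\n", t[["browsing"]]))
  cat(sprintf("  traffic cost:        %12.0f\n", t[["traffic"]]))
  cat(sprintf("  net benefit:         %12.0f\n", x$net_benefit))
  invisible(x)
}

#' Build a breakdown from published group totals
#'
#' Constructs a `net_benefit_breakdown` directly from the four value/cost
#' group totals, for working with published results where the per-class
#' composition is not available. The net benefit is the exact signed sum.
#' The result supports [sensitivity_table()] with `method = "identity"`;
#' the recomputation path needs a full aggregate and errors.
#'
#' @param meat,recreational,browsing,traffic Group totals, DKK/yr.
#' @return Object of class `net_benefit_breakdown` (without per-class
#'   detail).
#' @export
breakdown_from_totals <- function(meat, recreational, browsing, traffic) {
  totals <- c(meat = meat, recreational = recreational,
              browsing = browsing, traffic = traffic)
  if (any(!is.finite(totals) | totals < 0)) {
    stop("group totals must be nonnegative and finite", call. = FALSE)
  }
  structure(
    list(by_class = NULL, totals = totals,
         net_benefit = (meat + recreational) - (browsing + traffic),
         aggregate = NULL, params = NULL),
    class = "net_benefit_breakdown"
  )
}

#' Allocate a per-individual value across classes by body weight
#'
#' Damage costs (browsing, traffic) scale linearly with body size, so a
#' single per-individual reference value is distributed over classes in
#' proportion to carcass weight: `value_i = reference * w_i / w_ref`.
#'
#' @param reference_value Reference value, DKK per individual.
#' @param reference_weight Weight the reference value refers to (kg, > 0).
#' @param weights Named or unnamed vector of class weights (kg).
#' @return Per-class values, DKK per individual.
#' @export
allocate_by_weight <- function(reference_value, reference_weight, weights) {
  if (!is.finite(reference_weight) || reference_weight <= 0) {
    stop("reference_weight must be > 0", call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be > 0", call. = FALSE)
  reference_value * weights / reference_weight
}

#' Normalize a price to producer terms in a common price year
#'
#' Converts a consumer price to a producer price by removing value-added
#' tax, then rebases it between price years with a net price index:
#' `value / (1 + vat_rate) * index_to / index_from`.
#'
#' @param value Monetary value (DKK).
#' @param vat_rate VAT rate as a fraction (Danish standard: 0.25); use 0
#'   for values already in producer prices.
#' @param index_from,index_to Net price index in the source and target
#'   year (> 0); equal values leave the price year unchanged.
#' @return Normalized value (DKK).
#' @examples
#' normalize_price(125, vat_rate = 0.25)          # 100
#' normalize_price(100, 0, index_from = 104, index_to = 108)
#' @export
normalize_price <- function(value, vat_rate = 0.25, index_from = 1,
                            index_to = 1) {
  if (vat_rate < 0) stop("vat_rate must be >= 0", call. = FALSE)
  if (index_from <= 0 || index_to <= 0) {
    stop("price indices must be > 0", call. = FALSE)
  }
  value / (1 + vat_rate) * index_to / index_from
}

#' Read / write valuation parameters as CSV
#'
#' CSV mirror of the benchmark table: one row per class, columns
#' `class`, `meat_price`, `weight`, `recreational`, `browsing`, `traffic`,
#' `collision_prob`.
#'
#' @param path CSV file path.
#' @param params A [valuation_parameters()] object.
#' @return `read_valuation_csv()` a [valuation_parameters()];
#'   `write_valuation_csv()` the path, invisibly.
#' @export
read_valuation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "meat_price", "weight", "recreational", "browsing",
            "traffic", "collision_prob")
  if (!all(need %in% names(df))) {
    stop("valuation CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  i <- match(CLASS_LEVELS, df$class)
  if (anyNA(i)) {
    stop("valuation CSV missing class(es): ",
         paste(CLASS_LEVELS[is.na(i)], collapse = ", "), call. = FALSE)
  }
  valuation_parameters(
    meat_price = df$meat_price[i][1],
    weight = df$weight[i],
    recreational = df$recreational[i],
    browsing = df$browsing[i],
    traffic = df$traffic[i],
    collision_prob = df$collision_prob[i][1]
  )
}

#' @rdname read_valuation_csv
#' @export
write_valuation_csv <- function(params, path) {
  stopifnot(inherits(params, "valuation_parameters"))
  df <- data.frame(
    class = CLASS_LEVELS,
    meat_price = params$meat_price,
    weight = unname(params$weight),
    recreational = unname(params$recreational),
    browsing = unname(params$browsing),
    traffic = unname(params$traffic),
    collision_prob = params$collision_prob,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
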