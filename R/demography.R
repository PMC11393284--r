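# Stationary sex- and age-structured life-table engine.
#
# Ages are September ages x = 0..24 (25 classes). All mortality is annual
# total mortality q_x, partitioned into a vehicle-collision floor and a
# hunting remainder. Age 24 is terminal: survivors are counted as deaths in
# the same year so that recruitment balances deaths exactly.

MAX_AGE <- 24L
N_AGES <- 25L
SEXES <- c("female", "male")

`%||%` <- function(a, b) if (is.null(a)) b else a

check_prob <- function(x, what, sex = NULL, upper = 1) {
  bad <- !is.finite(x) | x < 0 | x > upper
  if (any(bad)) {
    ages <- paste(which(bad) - 1L, collapse = ", ")
    where <- if (is.null(sex)) "" else paste0(" (", sex, ", age ", ages, ")")
    stop(what, " must lie in [0, ", upper, "]", where, call. = FALSE)
  }
  invisible(x)
}

as_age_vector <- function(x, what, sex) {
  x <- as.numeric(x)
  if (length(x) == 1L) x <- rep(x, N_AGES)
  if (length(x) != N_AGES) {
    stop(what, " for ", sex, " must have length ", N_AGES,
         " (ages 0-", MAX_AGE, "), got ", length(x), call. = FALSE)
  }
  names(x) <- 0:MAX_AGE
  x
}

#' Total annual mortality schedule
#'
#' Bundles per-sex, per-age total annual mortality probabilities for
#' September ages 0--24 together with the all-class vehicle-collision
#' baseline rate. Construct directly, or from hunting rates via
#' [effective_mortality()], or from a strategy via [resolve_schedule()].
#'
#' @param female,male Numeric vectors of 25 total annual mortality
#'   probabilities (ages 0--24); a scalar is recycled.
#' @param baseline All-class annual vehicle-collision mortality rate,
#'   in `[0, 1)`. Every `q_x` must be at least `baseline`.
#' @param provenance Optional list with `female` and `male` character
#'   vectors (length 25) tagging each entry as `"stated"`, `"derived"` or
#'   `"floor"`; defaults to `"stated"`.
#' @return An object of class `mortality_schedule`: a list with elements
#'   `female`, `male`, `baseline` and `provenance`.
#' @seealso [effective_mortality()], [survivorship()], [stationary_table()]
#' @export
mortality_schedule <- function(female, male, baseline = 0.02,
                               provenance = NULL) {
  female <- as_age_vector(female, "mortality", "female")
  male <- as_age_vector(male, "mortality", "male")
  check_prob(female, "total mortality q_x", "female")
  check_prob(male, "total mortality q_x", "male")
  if (!is.finite(baseline) || baseline < 0 || baseline >= 1) {
    stop("baseline collision rate must lie in [0, 1)", call. = FALSE)
  }
  for (sx in SEXES) {
    q <- if (sx == "female") female else male
    if (any(q < baseline - 1e-12)) {
      stop("total mortality below the collision baseline (", sx, ", age ",
           paste(which(q < baseline - 1e-12) - 1L, collapse = ", "), ")",
           call. = FALSE)
    }
  }
  prov <- provenance %||% list(
    female = rep("stated", N_AGES),
    male = rep("stated", N_AGES)
  )
  structure(
    list(female = female, male = male, baseline = baseline,
         provenance = prov),
    class = "mortality_schedule"
  )
}

#' @export
print.mortality_schedule <- function(x, ...) {
  cat("Mortality schedule (total annual q_x, ages 0-", MAX_AGE, ")\n",
      sep = "")
  cat("  collision baseline:", x$baseline, "\n")
  for (sx in SEXES) {
    q <- x[[sx]]
    cat(sprintf("  %-6s q0 = %.3f, range ages 1+ = [%.3f, %.3f]\n",
                sx, q[1], min(q[-1]), max(q[-1])))
  }
  invisible(x)
}

#' Combine hunting rates with the collision floor
#'
#' Converts per-sex, per-age hunting mortality rates into total annual
#' mortality with the vehicle-collision floor: `q_x = max(hunting_x,
#' baseline)`. Ages whose hunting rate falls below the baseline are tagged
#' `"floor"` in the provenance record.
#'
#' @param hunting A list with numeric elements `female` and `male` (length
#'   25 or scalar): annual hunting mortality rates by September age.
#' @param baseline All-class collision mortality rate (default 0.02).
#' @param provenance Optional provenance tags carried from a strategy
#'   definition; entries raised to the floor are overwritten with
#'   `"floor"`.
#' @return A [mortality_schedule()].
#' @examples
#' sched <- effective_mortality(list(female = 0.2, male = 0), baseline = 0.02)
#' sched$male[["5"]]   # 0.02: the collision floor binds
#' @export
effective_mortality <- function(hunting, baseline = 0.02,
                                provenance = NULL) {
  if (!is.list(hunting) || !all(SEXES %in% names(hunting))) {
    stop("`hunting` must be a list with elements `female` and `male`",
         call. = FALSE)
  }
  q <- list()
  prov <- list()
  for (sx in SEXES) {
    h <- as_age_vector(hunting[[sx]], "hunting rate", sx)
    check_prob(h, "hunting rate", sx)
    q[[sx]] <- pmax(h, baseline)
    p <- (provenance[[sx]] %||% rep("stated", N_AGES))
    p[h < baseline] <- "floor"
    prov[[sx]] <- p
  }
  mortality_schedule(q$female, q$male, baseline = baseline,
                     provenance = prov)
}

#' Age-specific survivorship curve
#'
#' Computes, per sex, the probability `l_x` of surviving from recruitment
#' (age 0) to age `x` as the product of the preceding annual survival
#' rates: `l_x = prod(1 - q_0 .. q_{x-1})`, with `l_0 = 1`.
#'
#' @param schedule A [mortality_schedule()].
#' @return Object of class `survivorship_curve`: list with numeric
#'   `female` and `male` vectors of length 25 (names are ages).
#' @examples
#' s <- resolve_schedule(builtin_strategies()[["2"]])
#' survivorship(s)$male[["8"]]   # ~0.56: trophy hunting spares prime males
#' @export
survivorship <- function(schedule) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  out <- lapply(SEXES, function(sx) {
    q <- schedule[[sx]]
    l <- cumprod(c(1, 1 - q[-N_AGES]))
    names(l) <- 0:MAX_AGE
    l
  })
  names(out) <- SEXES
  structure(out, class = "survivorship_curve")
}

# Accounting mortality: terminal age absorbs its survivors (q_24 := 1).
accounting_q <- function(schedule, sex) {
  q <- schedule[[sex]]
  q[N_AGES] <- 1
  q
}

#' Stationary cohort table
#'
#' Builds the steady-state population by sex and age implied by a mortality
#' schedule. Per sex, `n_x = n_0 * l_x`; a single common recruitment
#' `n_0` for both sexes (equal sex ratio at birth, identical calf
#' mortality) is chosen so that the spring census -- ages 1--24 summed over
#' both sexes -- equals `spring_target`. Deaths are partitioned into
#' hunting harvest and collision deaths by [mortality_partition()], and the
#' September census is attached using `fecundity`.
#'
#' Recruitment is determined by the census scaling, not by the fecundity
#' schedule; fecundity enters only the September census.
#'
#' @param schedule A [mortality_schedule()].
#' @param spring_target Positive spring census (post-season, ages 1+) to
#'   scale to; the field convention is 1000. Ignored when `recruits` is
#'   supplied.
#' @param recruits Optional per-sex recruitment `n_0` overriding the census
#'   scaling (used by the projection oracle).
#' @param fecundity A [fecundity_parameters()] object.
#' @return Object of class `cohort_table` (a data frame): one row per sex
#'   and age with columns `sex`, `age`, `q`, `population`, `deaths`,
#'   `harvest`, `collisions`. Attributes: `recruits` (per sex),
#'   `n_spring`, `n_september`, `spring_target`, `baseline`.
#' @examples
#' tab <- stationary_table(resolve_schedule(builtin_strategies()[["2"]]))
#' round(attr(tab, "n_september"))   # 1288
#' @export
stationary_table <- function(schedule, spring_target = 1000,
                             recruits = NULL,
                             fecundity = fecundity_parameters()) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  surv <- survivorship(schedule)
  l_spring <- sum(surv$female[-1]) + sum(surv$male[-1])
  if (is.null(recruits)) {
    if (spring_target <= 0) stop("spring_target must be > 0", call. = FALSE)
    if (l_spring <= 0) {
      stop("degenerate schedule: no individual survives to age 1, the ",
           "spring population cannot be positive", call. = FALSE)
    }
    recruits <- spring_target / l_spring
  } else {
    if (recruits < 0) stop("recruits must be >= 0", call. = FALSE)
    spring_target <- recruits * l_spring
  }
  tab <- do.call(rbind, lapply(SEXES, function(sx) {
    data.frame(
      sex = sx,
      age = 0:MAX_AGE,
      q = unname(schedule[[sx]]),
      population = unname(recruits * surv[[sx]]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  tab <- mortality_partition(tab, schedule)
  n_spring <- sum(tab$population[tab$age >= 1])
  attr(tab, "recruits") <- c(female = recruits, male = recruits)
  attr(tab, "spring_target") <- spring_target
  attr(tab, "baseline") <- schedule$baseline
  attr(tab, "n_spring") <- n_spring
  attr(tab, "n_september") <-
    september_population(tab, fecundity)$total
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Partition deaths into harvest and collision deaths
#'
#' Fills the `deaths`, `harvest` and `collisions` columns of a cohort
#' table: `deaths = n_x * q_x`, `collisions = n_x * baseline`, and
#' `harvest = n_x * (q_x - baseline)` (floored at zero). At the terminal
#' age the accounting mortality is 1, so survivors of age 24 are harvested
#' or collide that year and recruitment balances deaths exactly.
#'
#' @param table A data frame with columns `sex`, `age`, `q`, `population`.
#' @param schedule The [mortality_schedule()] the table was built from.
#' @return The table with `deaths`, `harvest`, `collisions` columns filled.
#' @export
mortality_partition <- function(table, schedule) {
  stopifnot(inherits(schedule, "mortality_schedule"),
            all(c("sex", "age", "population") %in% names(table)))
  baseline <- schedule$baseline
  table$deaths <- NA_real_
  table$harvest <- NA_real_
  table$collisions <- NA_real_
  for (sx in SEXES) {
    i <- table$sex == sx
    q <- accounting_q(schedule, sx)[as.character(table$age[i])]
    n <- table$population[i]
    table$deaths[i] <- n * q
    table$collisions[i] <- n * baseline
    table$harvest[i] <- pmax(n * (q - baseline), 0)
  }
  table
}

#' Fecundity parameters
#'
#' Age-specific fecundity (calves per female alive at the start of the
#' hunting season) and the proportion of recruits that are female. Danish
#' field estimates: 0.57 for yearling hinds, 0.82 for hinds aged 2+, equal
#' sex ratio at birth.
#'
#' @param yearling Fecundity of age-1 females.
#' @param adult Fecundity of females aged 2+.
#' @param prop_female Proportion of calves that are female.
#' @return Object of class `fecundity_parameters`: list with `m` (numeric
#'   length 25, `m_0 = 0`) and `prop_female`.
#' @export
fecundity_parameters <- function(yearling = 0.57, adult = 0.82,
                                 prop_female = 0.5) {
  if (yearling < 0 || adult < 0) stop("fecundity must be >= 0", call. = FALSE)
  if (prop_female < 0 || prop_female > 1) {
    stop("prop_female must lie in [0, 1]", call. = FALSE)
  }
  m <- c(0, yearling, rep(adult, N_AGES - 2L))
  names(m) <- 0:MAX_AGE
  structure(list(m = m, prop_female = prop_female),
            class = "fecundity_parameters")
}

#' September (pre-season) census
#'
#' The September population equals the spring population plus the calves
#' born over the summer that survive to the season start:
#' `N_September = N_Spring + sum(n_{x,f} * m_x)` over ages 1--24. The calf
#' cohort is split into female and male recruits by `prop_female`.
#'
#' @param table A `cohort_table`.
#' @param fecundity A [fecundity_parameters()] object.
#' @return List with `total`, `n_spring`, `calves_born`,
#'   `female_recruits`, `male_recruits`.
#' @export
september_population <- function(table, fecundity = fecundity_parameters()) {
  stopifnot(inherits(fecundity, "fecundity_parameters"))
  adult <- table$age >= 1
  n_spring <- sum(table$population[adult])
  f <- table$sex == "female" & adult
  calves <- sum(table$population[f] * fecundity$m[as.character(table$age[f])])
  list(
    total = n_spring + calves,
    n_spring = n_spring,
    calves_born = calves,
    female_recruits = calves * fecundity$prop_female,
    male_recruits = calves * (1 - fecundity$prop_female)
  )
}

#' Forward cohort projection (stationarity oracle)
#'
#' Iterates cohort aging under a fixed mortality schedule and constant
#' per-sex recruitment: each year the age-x cohort is the survivors of last
#' year's age-(x-1) cohort and age 0 is reset to `recruits`. With enough
#' years the structure converges to the closed-form stationary table built
#' with the same recruitment, which is the package's internal consistency
#' check for [stationary_table()].
#'
#' @param schedule A [mortality_schedule()].
#' @param recruits Per-sex annual recruitment (calves of each sex).
#' @param years Number of years to iterate (>= 1).
#' @param initial Optional starting structure: list with `female` and
#'   `male` numeric vectors (length 25); defaults to all zeros.
#' @return List with `female` and `male` age-structure vectors (ages 0--24).
#' @export
project_forward <- function(schedule, recruits, years, initial = NULL) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  if (years < 1) stop("years must be >= 1", call. = FALSE)
  if (recruits < 0) stop("recruits must be >= 0", call. = FALSE)
  pop <- initial %||% list(female = numeric(N_AGES), male = numeric(N_AGES))
  for (sx in SEXES) {
    pop[[sx]] <- as_age_vector(pop[[sx]], "initial structure", sx)
    if (any(pop[[sx]] < 0)) {
      stop("initial structure must be nonnegative", call. = FALSE)
    }
  }
  for (i in seq_len(years)) {
    for (sx in SEXES) {
      survive <- pop[[sx]][-N_AGES] * (1 - schedule[[sx]][-N_AGES])
      pop[[sx]] <- c(recruits, survive)
      names(pop[[sx]]) <- 0:MAX_AGE
    }
  }
  pop
}

#' @export
print.cohort_table <- function(x, digits = 1, ...) {
  cat("Stationary cohort table\n")
  cat(sprintf("  recruits per sex: %.1f   spring census: %.1f   September: %.1f\n",
              attr(x, "recruits")[["female"]], attr(x, "n_spring"),
              attr(x, "n_september")))
  print.data.frame(
    transform(as.data.frame(x),
              population = round(population, digits),
              deaths = round(deaths, digits),
              harvest = round(harvest, digits),
              collisions = round(collisions, digits)),
    row.names = FALSE, ...)
  invisible(x)
}
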