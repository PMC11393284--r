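# Shared fixtures built in code.

# Cohort table populated from a class-aggregate style specification:
# per-class populations spread over a representative age per class, used
# where a full life table is not needed (sex-ratio checks, degenerate
# aggregates).
toy_cohort_table <- function(populations, harvests = NULL) {
  tab <- expand.grid(sex = c("female", "male"), age = 0:24,
                     stringsAsFactors = FALSE)
  tab <- tab[order(tab$sex, tab$age), ]
  tab$q <- 0.2
  tab$population <- 0
  tab$deaths <- 0
  tab$harvest <- 0
  tab$collisions <- 0
  rng <- data.frame(
    class = c("FC", "FY", "FA", "MC", "MY", "YS", "NS", "MS"),
    sex = c("female", "female", "female", "male", "male", "male", "male",
            "male"),
    age = c(0L, 1L, 2L, 0L, 1L, 2L, 5L, 8L)
  )
  for (cl in names(populations)) {
    i <- which(rng$class == cl)
    sel <- tab$sex == rng$sex[i] & tab$age == rng$age[i]
    tab$population[sel] <- populations[[cl]]
    if (!is.null(harvests)) tab$harvest[sel] <- harvests[[cl]] %||% 0
  }
  attr(tab, "n_spring") <- sum(tab$population[tab$age >= 1])
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Published reference tables, loaded once per test file.
refs <- reference_tables()

ref_totals <- function(strategy) {
  r <- refs$value_totals[refs$value_totals$strategy == strategy, ]
  breakdown_from_totals(r$meat, r$recreational, r$browsing, r$traffic)
}

benchmark_fit <- deer_cba()
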