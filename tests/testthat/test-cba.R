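test_that("decision rules pick the best positive strategy or extinction", {
  expect_equal(rank_and_decide(c(j = 5, k = 3))$strategy, "j")
  expect_equal(rank_and_decide(c(j = 5, k = 3))$decision, "implement")

  ext <- rank_and_decide(c(j = -10, k = -5))
  expect_equal(ext$decision, "extinction")
  expect_true(is.na(ext$strategy))
  expect_equal(ext$net_benefit, 0)

  tie <- rank_and_decide(c(a = 7, b = 7, c = 1))
  expect_equal(tie$decision, "indifferent")
  expect_setequal(tie$strategy, c("a", "b"))

  zero <- rank_and_decide(c(a = 0, b = -3))
  expect_equal(zero$decision, "indifferent")

  expect_error(rank_and_decide(numeric(0)), "at least one")
  expect_error(rank_and_decide(c(a = NaN)), "finite")

  # the published benchmark net benefits single out maximum harvest
  nb <- setNames(refs$value_totals$net_benefit_published,
                 refs$value_totals$strategy)
  best <- rank_and_decide(nb)
  expect_equal(best$strategy, "3")
  expect_equal(best$decision, "implement")
})

test_that("sensitivity bounds follow the exact linearity identity", {
  sens <- sensitivity_table(list(s1 = ref_totals("1"), s4A = ref_totals("4A")))
  row <- function(s, g) sens[sens$strategy == s & sens$group == g, ]
  # published anchors: NB +/- 0.5 * group total
  expect_equal(row("s1", "meat")$upper, 272442)
  expect_equal(round(row("s4A", "meat")$upper), 62356)
  expect_equal(row("s1", "recreational")$upper, 751699)
  expect_equal(row("s1", "traffic")$lower, 313798)
  # cost groups flip: their upper bound lowers the net benefit
  expect_lt(row("s1", "browsing")$upper, row("s1", "browsing")$lower)
  # bounds are symmetric about the benchmark
  for (g in unique(sens$group)) {
    r <- row("s1", g)
    expect_equal(r$upper - r$benchmark, r$benchmark - r$lower,
                 tolerance = 1e-9)
  }
  # factor -> 0 limit: every bound collapses onto the benchmark
  tiny <- sensitivity_table(list(s1 = ref_totals("1")), factor = 1e-12)
  expect_equal(tiny$lower, tiny$benchmark, tolerance = 1e-3)
  expect_error(sensitivity_table(list(s1 = ref_totals("1")), factor = 0),
               "factor")
})

test_that("identity and recomputation sensitivity paths agree", {
  for (seed in 1:20) {
    spec <- scenario_spec(seed)
    params <- random_valuation(spec)
    agg <- aggregate_classes(
      stationary_table(resolve_schedule(random_strategy(spec))))
    bd <- list(s = net_benefit(agg, params))
    a <- sensitivity_table(bd, method = "identity")
    b <- sensitivity_table(bd, method = "recompute")
    expect_equal(a$lower, b$lower, tolerance = 1e-9)
    expect_equal(a$upper, b$upper, tolerance = 1e-9)
  }
  # totals-only breakdowns cannot take the recomputation path
  expect_error(sensitivity_table(list(s = ref_totals("1")),
                                 method = "recompute"),
               "recomputation")
})

test_that("strategy ranking is invariant under all grouped variations", {
  fit <- benchmark_fit
  bench_order <- names(sort(fit$net_benefits, decreasing = TRUE))
  sens <- fit$sensitivity
  for (g in unique(sens$group)) {
    for (bound in c("lower", "upper")) {
      nb <- setNames(sens[[bound]][sens$group == g],
                     sens$strategy[sens$group == g])
      expect_equal(names(sort(nb, decreasing = TRUE)), bench_order,
                   info = paste(g, bound))
    }
  }
})

test_that("net-benefit signs flip where the published analysis says they do", {
  # under the engine's own arithmetic, maximum harvest turns negative at
  # the recreational lower bound and at both cost upper bounds
  sens <- benchmark_fit$sensitivity
  row <- function(s, g) sens[sens$strategy == s & sens$group == g, ]
  expect_gt(row("3", "meat")$benchmark, 0)
  expect_lt(row("3", "recreational")$lower, 0)
  expect_lt(row("3", "browsing")$upper, 0)
  expect_lt(row("3", "traffic")$upper, 0)
  # trophy hunting stays negative under every variation
  s2 <- sens[sens$strategy == "2", ]
  expect_true(all(s2$lower < 0) && all(s2$upper < 0))
})

test_that("the full pipeline recommends maximum harvest at the benchmark", {
  fit <- benchmark_fit
  expect_equal(fit$decision$strategy, "3")
  expect_equal(fit$decision$decision, "implement")
  expect_gt(fit$net_benefits[["3"]], 0)
  # trophy hunting carries a large negative net benefit
  expect_lt(fit$net_benefits[["2"]], -1e6 * 0.9)
  # restricted to the negative strategies, the extinction rule applies
  sub <- deer_cba(strategies = builtin_strategies()[c("2", "4A", "4B")])
  expect_equal(sub$decision$decision, "extinction")
})

test_that("summary reports per-strategy totals consistent with the breakdowns", {
  s <- summary(benchmark_fit)
  expect_s3_class(s, "summary.deer_cba")
  for (i in seq_len(nrow(s$totals))) {
    id <- s$totals$strategy[i]
    expect_equal(s$totals$net_benefit[i],
                 benchmark_fit$breakdowns[[id]]$net_benefit)
  }
  expect_output(print(s), "Per-strategy annual totals")
  expect_output(print(benchmark_fit), "Recommendation")
})
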