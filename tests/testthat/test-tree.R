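test_that("combined quit rate follows the independence rule", {
  expect_equal(combined_quit_rate(c(0.83, 0.52)), 0.9184)
  expect_equal(round(combined_quit_rate(c(0.83, 0.52)), 3), 0.918)
  expect_equal(combined_quit_rate(c(0.6, 0.83, 0.52)), 0.96736)
  expect_equal(combined_quit_rate(c(0.5, 0.5)), 0.75)
  expect_equal(combined_quit_rate(0.37), 0.37)
  expect_equal(combined_quit_rate(numeric(0)), 0)
})

test_that("combined quit rate is bounded, monotone and permutation-invariant", {
  withr::with_seed(42, {
    for (i in 1:50) {
      p <- runif(sample(1:6, 1))
      r <- combined_quit_rate(p)
      expect_gte(r, max(p))
      expect_lte(r, 1)
      expect_equal(combined_quit_rate(sample(p)), r)
    }
  })
})

test_that("combined quit rate rejects values outside [0, 1]", {
  expect_error(combined_quit_rate(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(combined_quit_rate(-0.1), "\\[0, 1\\]")
})

test_that("stage reach probabilities are sequential failure products", {
  expect_equal(stage_reach_probs(c(0.52, 0.6, 0.5)), c(1, 0.48, 0.192))
  expect_equal(stage_reach_probs(0.9), 1)
  expect_equal(stage_reach_probs(c(1, 0.5, 0.5)), c(1, 0, 0))
  expect_equal(stage_reach_probs(numeric(0)), numeric(0))
  withr::with_seed(7, {
    for (i in 1:20) {
      q <- runif(sample(2:6, 1))
      r <- stage_reach_probs(q)
      expect_true(all(diff(r) <= 0))
      expect_equal(r[1], 1)
    }
  })
})

test_that("sequential evaluation matches the brute-force path enumeration", {
  withr::with_seed(11, {
    for (i in 1:25) {
      k <- sample(1:6, 1)
      quits <- runif(k)
      costs <- runif(k, 10, 5000)
      kinds <- sample(c("counselling", "pharmacotherapy"), k, replace = TRUE)
      cfg <- make_linear_config(quits, costs, kinds, cohort = 1000)
      ev <- evaluate_strategy(cfg, "S")
      oracle <- oracle_stratum(quits, costs, kinds)
      expect_equal(ev$quitters[ev$stratum == "Total"],
                   1000 * oracle$quit_rate, tolerance = 1e-9)
      expect_equal(ev$cost_inr[ev$stratum == "Total"],
                   1000 * oracle$cost_per_person, tolerance = 1e-9)
    }
  })
})

test_that("a single counselling stage gives the hand-computed result", {
  cfg <- make_linear_config(0.52, 226, "counselling", cohort = 100)
  ev <- evaluate_strategy(cfg, "S")
  tot <- ev[ev$stratum == "Total", ]
  expect_equal(tot$quitters, 52)
  expect_equal(tot$cost_inr, 22600)
  expect_equal(tot$cost_usd, 22600 / 83.93)
})

test_that("zero quit rates mean no attrition: everyone pays every stage", {
  cfg <- make_linear_config(c(0, 0, 0), c(100, 200, 300), cohort = 50)
  tot <- strategy_totals(evaluate_strategy(cfg, "S"))
  expect_equal(tot$quitters, 0)
  expect_equal(tot$cost_inr, 50 * 600)
})

test_that("raising a quit rate never loses quitters; raising a cost never saves money", {
  base <- c(0.3, 0.5, 0.4)
  costs <- c(200, 1000, 800)
  t0 <- strategy_totals(evaluate_strategy(make_linear_config(base, costs), "S"))
  for (j in 1:3) {
    up <- base
    up[j] <- up[j] + 0.2
    t1 <- strategy_totals(evaluate_strategy(make_linear_config(up, costs), "S"))
    expect_gte(t1$quitters, t0$quitters)
    cup <- costs
    cup[j] <- cup[j] + 500
    t2 <- strategy_totals(evaluate_strategy(make_linear_config(base, cup), "S"))
    expect_gte(t2$cost_inr, t0$cost_inr)
  }
})

test_that("a stage with zero quit rate and zero cost changes nothing", {
  cfg1 <- make_linear_config(c(0.4, 0.6), c(300, 900))
  cfg2 <- make_linear_config(c(0.4, 0, 0.6), c(300, 0, 900))
  t1 <- strategy_totals(evaluate_strategy(cfg1, "S"))
  t2 <- strategy_totals(evaluate_strategy(cfg2, "S"))
  expect_equal(t1$quitters, t2$quitters)
  expect_equal(t1$cost_inr, t2$cost_inr)
})

test_that("quitters are order-invariant but pharmacotherapy costs are not", {
  a <- strategy_totals(evaluate_strategy(
    make_linear_config(c(0.5, 0.7), c(100, 1000),
                       c("pharmacotherapy", "pharmacotherapy")), "S"))
  b <- strategy_totals(evaluate_strategy(
    make_linear_config(c(0.7, 0.5), c(1000, 100),
                       c("pharmacotherapy", "pharmacotherapy")), "S"))
  expect_equal(a$quitters, b$quitters)
  expect_false(isTRUE(all.equal(a$cost_inr, b$cost_inr)))
})

test_that("totals equal the closed-form cohort x weighted combined rate", {
  cfg <- base_case_config()
  ev <- evaluate_strategies(cfg)
  vals <- ceatree:::param_base_values(cfg)
  w <- ceatree:::stratum_weights_vec(cfg, vals)
  for (s in names(cfg$strategies)) {
    expected <- 0
    for (k in seq_along(cfg$strata$label)) {
      lab <- cfg$strata$label[k]
      stages <- cfg$strategies[[s]]$stages[[lab]]
      q <- vapply(stages, function(nm) {
        combined_quit_rate(vapply(cfg$components[[nm]]$quit,
                                  function(p) vals[[p]], numeric(1)))
      }, numeric(1))
      expected <- expected + cfg$cohort_size * w[[k]] * combined_quit_rate(q)
    }
    tot <- ev[ev$strategy == s & ev$stratum == "Total", ]
    expect_equal(tot$quitters, expected, tolerance = 1e-12)
    per_stratum <- ev[ev$strategy == s & ev$stratum != "Total", ]
    expect_equal(sum(per_stratum$quitters), tot$quitters)
    expect_equal(sum(per_stratum$cost_inr), tot$cost_inr)
    expect_lte(tot$quitters, cfg$cohort_size)
    expect_gte(tot$quitters, 0)
  }
})

test_that("evaluate_strategies enforces its contract", {
  cfg <- base_case_config()
  expect_equal(length(unique(evaluate_strategies(cfg)$strategy)), 4)
  expect_error(evaluate_strategies(cfg, character(0)), "no strategies")
  expect_error(evaluate_strategies(cfg, c("CS", "CS")), "duplicate.*CS")
  expect_error(evaluate_strategies(cfg, "nope"), "nope")
})

test_that("currency conversion divides by the exchange rate", {
  expect_equal(round(inr_to_usd(359867788, 83.93)), 4287713)
  expect_equal(inr_to_usd(0, 42), 0)
  expect_equal(inr_to_usd(83.93, 83.93), 1)
  expect_error(inr_to_usd(100, 0), "positive")
  expect_error(inr_to_usd(100, -2), "positive")
})
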