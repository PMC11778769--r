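test_that("moment matching reproduces the base value as the fitted mean", {
  b <- fit_distribution(0.52, 0.39, 0.65, "beta")
  expect_equal(b$shape1 / (b$shape1 + b$shape2), 0.52, tolerance = 1e-6)
  expect_equal(b$sd, (0.65 - 0.39) / 3.92)

  g <- fit_distribution(3024, 2268, 3780, "gamma")
  expect_equal(g$shape * g$scale, 3024, tolerance = 1e-6)
  expect_equal(g$sd, 1512 / 3.92, tolerance = 1e-4) # ~385.7
  expect_equal(sqrt(g$shape) * g$scale, g$sd, tolerance = 1e-9)

  n <- fit_distribution(18.2, 13.65, 22.75, "normal")
  expect_equal(n$mean, 18.2)
  expect_equal(n$sd, 9.1 / 3.92, tolerance = 1e-6) # 2.321
})

test_that("distribution fitting rejects invalid supports", {
  expect_error(fit_distribution(1.2, 1.1, 1.3, "beta", name = "p"), "p.*Beta")
  expect_error(fit_distribution(0, -0.1, 0.1, "beta"), "Beta")
  # spread too wide for a Beta mean this close to the boundary
  expect_error(fit_distribution(0.05, 0, 1, "beta", name = "narrow"),
               "narrow.*variance")
  expect_error(fit_distribution(0.5, 0.6, 0.7, "beta"), "lower <= base")
  expect_error(fit_distribution(-5, -10, 0, "gamma"), "non-negative")
})

test_that("sampled distributions recover their fitted mean within 1%", {
  cfg <- base_case_config()
  specs <- ceatree:::fit_all_distributions(cfg)
  withr::with_seed(123, {
    for (nm in c("quit_bi", "quit_ec", "cost_nrt4", "prev_fi_8p")) {
      draws <- sample_dist(specs[[nm]], 2e5)
      expect_equal(mean(draws), specs[[nm]]$base,
                   tolerance = 0.01)
      if (specs[[nm]]$family == "beta") {
        expect_true(all(draws >= 0 & draws <= 1))
      }
      if (specs[[nm]]$family == "gamma") expect_true(all(draws >= 0))
      # moment matching, not quantile matching: the empirical central 95%
      # interval only loosely brackets the stated bounds
      qs <- quantile(draws, c(0.025, 0.975))
      half <- (specs[[nm]]$upper - specs[[nm]]$lower) / 2
      expect_lt(abs(qs[1] - specs[[nm]]$lower), half)
      expect_lt(abs(qs[2] - specs[[nm]]$upper), half)
    }
  })
})

test_that("tornado rows vary one parameter at a time and sort by swing", {
  cfg <- base_case_config()
  tor <- owsa(cfg, "PS1", "CS")
  expect_true(all(diff(tor$swing) <= 0))
  expect_setequal(tor$parameter, names(cfg$parameters))
  # mean age enters no economic computation: zero swing, ranked last
  age <- tor[tor$parameter == "mean_age", ]
  expect_equal(age$swing, 0)
  expect_equal(tor$parameter[nrow(tor)] %in%
                 tor$parameter[tor$swing == 0], TRUE)
})

test_that("a bound producing zero incremental effect yields an undefined side", {
  cfg <- make_linear_config(0.5, 100,
                            extra_strategy = list(
                              name = "T", stages = list(Only = list("Stage 1"))))
  # the two strategies are identical, so every contrast has zero effect
  w <- capture_warnings(tor <- owsa(cfg, "T", "S"))
  expect_true(all(grepl("incremental effect is zero", w)))
  expect_gt(length(w), 0)
  expect_true(all(is.na(tor$icer_low)))
})

test_that("setting a parameter to its base value reproduces the base ICER", {
  cfg <- base_case_config()
  totals <- strategy_totals(evaluate_strategies(cfg))
  inc <- incremental_table(totals, "CS", cfg$wtp_threshold)
  base_icer <- inc$icer[inc$intervention == "PS1"]
  # collapse one parameter's bounds onto its base: both tornado sides must
  # then equal the deterministic base-case ICER
  cfg$parameters$cost_nrt4$lower <- cfg$parameters$cost_nrt4$base
  cfg$parameters$cost_nrt4$upper <- cfg$parameters$cost_nrt4$base
  tor <- owsa(cfg, "PS1", "CS")
  row <- tor[tor$parameter == "cost_nrt4", ]
  expect_equal(row$icer_low, base_icer, tolerance = 1e-12)
  expect_equal(row$icer_high, base_icer, tolerance = 1e-12)
  expect_equal(row$swing, 0)
})

test_that("the PSA is reproducible under a fixed seed", {
  cfg <- base_case_config()
  a <- run_psa(cfg, "CS", n = 50, seed = 7)
  b <- run_psa(cfg, "CS", n = 50, seed = 7)
  expect_identical(a$draws, b$draws)
  expect_identical(a$samples, b$samples)
  c_ <- run_psa(cfg, "CS", n = 50, seed = 8)
  expect_false(identical(a$draws$delta_cost, c_$draws$delta_cost))
  expect_equal(nrow(a$draws), 50 * 3)
})

test_that("PSA sample means recover the base-case parameters", {
  cfg <- base_case_config()
  psa <- run_psa(cfg, "CS", n = 4000, seed = 31)
  specs <- ceatree:::fit_all_distributions(cfg)
  for (nm in colnames(psa$samples)) {
    mc_se <- specs[[nm]]$sd / sqrt(psa$n)
    expect_lt(abs(mean(psa$samples[[nm]]) - specs[[nm]]$base), 5 * mc_se)
  }
})

test_that("quadrant proportions partition the draws", {
  psa <- make_psa(delta_cost = c(-1, 1, -1, 1),
                  delta_effect = c(1, 1, -1, -1))
  q <- quadrant_proportions(psa, "A")
  expect_equal(unname(q), rep(0.25, 4))
  expect_equal(sum(q), 1)

  all_se <- make_psa(delta_cost = rep(-5, 10), delta_effect = rep(2, 10))
  expect_equal(unname(quadrant_proportions(all_se, "A")), c(1, 0, 0, 0))
  expect_error(quadrant_proportions(psa, "missing"), "missing")
})

test_that("the CEAC is a probability and behaves at its limits", {
  withr::with_seed(2, {
    dc <- rnorm(500, 0, 100)
    de <- abs(rnorm(500, 5, 2)) + 0.1 # all positive effects
    psa <- make_psa(dc, de)
    grid <- seq(0, 1000, by = 50)
    cv <- ceac(psa, grid)
    expect_true(all(cv$probability >= 0 & cv$probability <= 1))
    # at lambda = 0 the net benefit is -delta_cost
    expect_equal(cv$probability[cv$wtp == 0], mean(dc < 0))
    # with all effects positive the curve is non-decreasing in lambda
    expect_true(all(diff(cv$probability) >= 0))
    # at large lambda it approaches the fraction of draws with positive effect
    expect_equal(ceac(psa, 1e12)$probability, mean(de > 0))
  })
  expect_error(ceac(make_psa(1, 1), numeric(0)), "non-empty")
  expect_error(ceac(make_psa(1, 1), -5), "non-negative")
})
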