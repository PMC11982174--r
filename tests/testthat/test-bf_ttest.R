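test_that("JZS Bayes factors reproduce the published subgroup reanalysis", {
  # published values 0.353 / 0.20 were computed at the printed t statistics
  expect_equal(bf10_ttest(-1.36, 123, 97)$bf10, 0.353, tolerance = 0.01 / 0.353)
  expect_equal(bf10_ttest(0.91, 132, 136)$bf10, 0.20, tolerance = 0.01 / 0.20)
  expect_equal(bf10_ttest(-1.61, 220, 268)$bf10, 0.355, tolerance = 0.01 / 0.355)
  # df convention is immaterial at these sizes
  expect_equal(bf10_ttest(-1.36, 123, 97, df_convention = "residual")$bf10,
               bf10_ttest(-1.36, 123, 97, df_convention = "total")$bf10,
               tolerance = 1e-4)
})

test_that("adversarial informed-prior Bayes factors reproduce the published values", {
  expect_equal(bf10_adversarial(-1.36, 123, 97, location = -0.36,
                                scale = 0.42, prior_df = 3)$bf10,
               0.64, tolerance = 0.02 / 0.64)
  expect_equal(bf10_adversarial(-1.61, 220, 268, location = -0.15,
                                scale = 0.745, prior_df = 3)$bf10,
               0.41, tolerance = 0.02 / 0.41)
  # a huge symmetric prior at null data is penalized
  expect_lt(bf10_adversarial(0, 50, 50, location = 0, scale = 50,
                             prior_df = 3)$bf10, 1)
  expect_error(bf10_adversarial(-1, 50, 50, location = 0, scale = 1,
                                prior_df = 2), class = "bayesreanal_invalid_input")
})

test_that("BF10 tends to 1 as the prior collapses onto the null", {
  expect_equal(bf10_ttest(-1.36, 123, 97, cauchy_prior(1e-6))$bf10, 1,
               tolerance = 1e-3)
  expect_equal(bf10_ttest(2.5, 40, 60, cauchy_prior(1e-6))$bf10, 1,
               tolerance = 1e-3)
  expect_equal(bf10_ttest(2.5, 40, 60, student_t_prior(0, 1e-6, 3))$bf10, 1,
               tolerance = 1e-3)
})

test_that("BF is symmetric in t for symmetric-about-zero priors", {
  for (p in list(cauchy_prior(0.707), student_t_prior(0, 0.745, 3))) {
    for (tt in c(0.3, 0.91, 1.61, 2.8)) {
      expect_equal(bf10_ttest(tt, 60, 80, p)$bf10,
                   bf10_ttest(-tt, 60, 80, p)$bf10, tolerance = 1e-9)
    }
  }
})

test_that("BF10 increases strictly with |t| under a fixed prior", {
  ts <- seq(0, 4, by = 0.5)
  bfs <- vapply(ts, function(tt) bf10_ttest(tt, 123, 97)$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("stored fields are internally consistent", {
  r <- bf10_ttest(-1.36, 123, 97)
  expect_equal(r$bf10 * r$bf01, 1, tolerance = 1e-12)
  expect_equal(r$log_bf10, log(r$bf10), tolerance = 1e-12)
  expect_equal(r$marginal_h0, dt(-1.36, 220))
  expect_equal(r$n_eff, 123 * 97 / 220)
  expect_true(is.finite(r$log_bf10))
})

test_that("quadrature agrees with the Monte-Carlo prior-sampling oracle", {
  set.seed(20)
  configs <- list(
    list(t = -1.36, n_a = 123L, n_b = 97L, prior = cauchy_prior(0.707)),
    list(t = 0.91, n_a = 132L, n_b = 136L, prior = cauchy_prior(0.707)),
    list(t = -1.61, n_a = 220L, n_b = 268L, prior = student_t_prior(-0.15, 0.745, 3)),
    list(t = 2.2, n_a = 35L, n_b = 48L, prior = cauchy_prior(0.3)),
    list(t = -0.4, n_a = 60L, n_b = 20L, prior = student_t_prior(0.5, 1.2, 4)),
    list(t = 3.1, n_a = 200L, n_b = 150L, prior = cauchy_prior(1.2))
  )
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    quad <- bf10_ttest(cf$t, cf$n_a, cf$n_b, cf$prior)$bf10
    mc <- mc_bf10(cf$t, cf$n_a, cf$n_b, cf$prior, n_draws = 2e5, seed = 100 + i)
    expect_lt(abs(quad - mc$bf10), 3 * mc$se + 1e-8)
  }
})

test_that("one-sided variants bracket the two-sided BF for symmetric priors", {
  # marginal likelihood of the two-sided test is the average of the two
  # folded one-sided marginals when the prior is symmetric about zero
  r2 <- bf10_ttest(-1.36, 123, 97)
  rl <- bf10_ttest(-1.36, 123, 97, alternative = "less")
  rg <- bf10_ttest(-1.36, 123, 97, alternative = "greater")
  expect_equal(r2$marginal_h1, (rl$marginal_h1 + rg$marginal_h1) / 2,
               tolerance = 1e-8)
  expect_gt(rl$bf10, r2$bf10)  # prior aligned with the sign of t
  expect_lt(rg$bf10, r2$bf10)
})

test_that("robustness curve behaves as published: max near 1, near-null start", {
  e <- published_effects()
  rc <- robustness_curve(e$don$t, e$don$n_a, e$don$n_b)
  expect_identical(nrow(rc$curve), 150L)
  expect_equal(rc$curve$bf10[1], 1, tolerance = 0.05)      # r = 0.01
  expect_equal(rc$max_bf10, max(rc$curve$bf10))
  expect_lte(rc$max_bf10, 1.15)
  # small grids work and the argmax is reported consistently
  rc2 <- robustness_curve(2.5, 40, 60, scale_grid = c(0.1, 0.5, 1))
  expect_equal(rc2$max_bf10, max(rc2$curve$bf10))
  expect_equal(rc2$scale_at_max,
               rc2$curve$scale[which.max(rc2$curve$bf10)])
  expect_error(robustness_curve(1, 40, 60, scale_grid = numeric(0)),
               class = "bayesreanal_invalid_input")
  expect_error(robustness_curve(1, 40, 60, scale_grid = c(0.5, -1)),
               class = "bayesreanal_invalid_input")
})

test_that("evidence classification follows the conventional bands", {
  expect_identical(classify_evidence(0.20), "moderate evidence for H0")
  expect_identical(classify_evidence(1), "no evidence")
  expect_identical(classify_evidence(150), "extreme evidence for H1")
  expect_identical(classify_evidence(0.353), "anecdotal evidence for H0")
  expect_identical(classify_evidence(c(5, 15, 50, 0.005)),
                   c("moderate evidence for H1", "strong evidence for H1",
                     "very strong evidence for H1", "extreme evidence for H0"))
  expect_identical(classify_evidence(0.02), "very strong evidence for H0")
  expect_error(classify_evidence(0), class = "bayesreanal_invalid_input")
  expect_error(classify_evidence(-2), class = "bayesreanal_invalid_input")
})

test_that("invalid t-test inputs raise typed errors", {
  expect_error(bf10_ttest(Inf, 50, 50), class = "bayesreanal_invalid_input")
  expect_error(bf10_ttest(1, 1, 50), class = "bayesreanal_invalid_input")
  expect_error(bf10_ttest(1, 50.5, 50), class = "bayesreanal_invalid_input")
})

test_that("BF reports serialize with prior spec and robustness curve", {
  r <- bf10_ttest(-1.36, 123, 97)
  rc <- robustness_curve(-1.36, 123, 97, scale_grid = c(0.1, 0.707, 1.5))
  js <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_bf_report(r, js, robustness = rc, tsv_path = tsv)
  rec <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(rec$bf10, r$bf10)
  expect_identical(rec$category, classify_evidence(r$bf10))
  expect_equal(rec$robustness$max_bf10, rc$max_bf10)
  curve <- utils::read.delim(tsv)
  expect_equal(curve$bf10, rc$curve$bf10, tolerance = 1e-9)
})
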