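test_that("single study with tau pinned at 0 matches the conjugate closed form", {
  y <- 0.8; s <- 0.25; s0 <- 1
  fit <- fit_nnhm(data.frame(y = y, sigma = s), mu_prior_sd = s0,
                  tau_prior = half_normal_prior(1e-7))
  v <- 1 / (1 / s0^2 + 1 / s^2)
  m <- v * y / s^2
  mu <- posterior_summary(fit, "mu", kind = "mean")
  expect_equal(mu$estimate, m, tolerance = 1e-6)
  med <- posterior_summary(fit, "mu")
  expect_equal(med$estimate, m, tolerance = 1e-6)
  expect_equal(med$lower, qnorm(0.025, m, sqrt(v)), tolerance = 1e-5)
  expect_equal(med$upper, qnorm(0.975, m, sqrt(v)), tolerance = 1e-5)
})

test_that("a symmetric single study at y = 0 has a centered posterior", {
  fit <- fit_nnhm(data.frame(y = 0, sigma = 0.5))
  expect_equal(posterior_summary(fit, "mu", kind = "mean")$estimate, 0,
               tolerance = 1e-10)
  expect_equal(posterior_summary(fit, "mu")$estimate, 0, tolerance = 1e-8)
})

test_that("tau marginal and mu mixture densities are proper", {
  fit <- fit_nnhm(published_study_df())
  expect_equal(sum(fit$wt), 1, tolerance = 1e-10)
  mass <- integrate(function(x)
    vapply(x, function(q) sum(fit$wt * dnorm(q, fit$cond_mean,
                                             sqrt(fit$cond_var))), numeric(1)),
    -Inf, Inf, rel.tol = 1e-8)$value
  expect_equal(mass, 1, tolerance = 1e-4)
  expect_true(all(fit$cond_var > 0))
  expect_gte(fit$grid$points, 1600)
})

test_that("the two-study fit reproduces the published posterior summaries", {
  fit <- fit_nnhm(published_study_df())
  mu <- posterior_summary(fit, "mu")
  tau <- posterior_summary(fit, "tau")
  expect_equal(mu$estimate, -0.06, tolerance = 0.02 / 0.06)
  expect_equal(tau$estimate, 0.33, tolerance = 0.05 / 0.33)
  expect_equal(tau$lower, 0, tolerance = 0.05)
  expect_equal(tau$upper, 0.88, tolerance = 0.05 / 0.88)
  # median and mean summaries agree closely here
  expect_lt(abs(posterior_summary(fit, "mu", kind = "mean")$estimate -
                  mu$estimate), 0.02)
})

test_that("Savage-Dickey and marginal-likelihood-ratio routes coincide", {
  for (studies in list(published_study_df(),
                       data.frame(y = c(0.2, -0.1, 0.5), sigma = c(0.2, 0.3, 0.25)))) {
    fit <- fit_nnhm(studies)
    sd_route <- bf10_meta(fit, "savage_dickey")$bf10
    ml_route <- bf10_meta(fit, "ml_ratio")$bf10
    expect_equal(sd_route, ml_route, tolerance = 1e-4)
  }
})

test_that("null data concentrated at zero favor the null strongly", {
  fit <- fit_nnhm(data.frame(y = c(0, 0, 0), sigma = c(0.05, 0.05, 0.05)))
  expect_lt(bf10_meta(fit)$bf10, 0.2)
})

test_that("the inclusion BF averages fixed and random models and needs a proper prior", {
  fit <- fit_nnhm(published_study_df())
  incl <- bf10_meta(fit, "inclusion")$bf10
  sd_route <- bf10_meta(fit)$bf10
  expect_false(isTRUE(all.equal(incl, sd_route, tolerance = 0.01)))
  expect_true(incl > 0 && incl < 1)
  jfit <- fit_nnhm(published_study_df(), tau_prior = jeffreys_prior())
  expect_error(bf10_meta(jfit, "inclusion"), class = "bayesreanal_invalid_input")
})

test_that("Jeffreys prior raises the heterogeneity estimate on the two-study input", {
  hn <- posterior_summary(fit_nnhm(published_study_df()), "tau")$estimate
  jf <- posterior_summary(fit_nnhm(published_study_df(),
                                   tau_prior = jeffreys_prior()), "tau")$estimate
  expect_gt(jf, hn)
})

test_that("widening the mu prior from SD 1 to 4 barely moves the estimate", {
  m1 <- posterior_summary(fit_nnhm(published_study_df(), mu_prior_sd = 1), "mu")$estimate
  m4 <- posterior_summary(fit_nnhm(published_study_df(), mu_prior_sd = 4), "mu")$estimate
  expect_lt(abs(m1 - m4), 0.02)
})

test_that("an infinitely imprecise study leaves the posterior unchanged", {
  base <- fit_nnhm(published_study_df())
  padded <- rbind(published_study_df(),
                  data.frame(label = "vague", y = 5, sigma = 1e6))
  aug <- fit_nnhm(padded)
  expect_equal(posterior_summary(aug, "mu")$estimate,
               posterior_summary(base, "mu")$estimate, tolerance = 1e-6)
  expect_equal(posterior_summary(aug, "tau")$estimate,
               posterior_summary(base, "tau")$estimate, tolerance = 1e-5)
  expect_equal(bf10_meta(aug)$bf10, bf10_meta(base)$bf10, tolerance = 1e-6)
})

test_that("shrinkage pools completely as tau -> 0 and not at all for huge tau", {
  df <- data.frame(y = c(-0.5, 0.7), sigma = c(0.2, 0.2))
  pooled <- fit_nnhm(df, tau_prior = half_normal_prior(1e-7))
  mu <- posterior_summary(pooled, "mu")
  sh <- shrinkage(pooled)
  expect_equal(sh$estimate, rep(mu$estimate, 2), tolerance = 1e-6)
  expect_equal(sh$lower, rep(mu$lower, 2), tolerance = 1e-4)
  loose <- fit_nnhm(df, mu_prior_sd = 100, tau_prior = half_normal_prior(100))
  shl <- shrinkage(loose)
  expect_equal(shl$estimate, df$y, tolerance = 0.05)
  expect_equal(shl$upper - shl$lower, rep(2 * 1.96 * 0.2, 2), tolerance = 0.05)
})

test_that("published-fit shrinkage lies between direct and pooled estimates", {
  fit <- fit_nnhm(published_study_df())
  mu_hat <- posterior_summary(fit, "mu")$estimate
  sh <- shrinkage(fit)
  for (i in 1:2) {
    lo <- min(fit$studies$y[i], mu_hat); hi <- max(fit$studies$y[i], mu_hat)
    expect_gt(sh$estimate[i], lo)
    expect_lt(sh$estimate[i], hi)
  }
  expect_error(shrinkage(fit, 3), class = "bayesreanal_invalid_input")
})

test_that("the predictive distribution widens the mu interval and covers 0", {
  fit <- fit_nnhm(published_study_df())
  mu <- posterior_summary(fit, "mu")
  pr <- predictive(fit)
  expect_gt(pr$upper - pr$lower, mu$upper - mu$lower)
  expect_lt(pr$lower, 0); expect_gt(pr$upper, 0)
  # tau ~ 0: predictive collapses onto the mu posterior
  tight <- fit_nnhm(data.frame(y = 0.3, sigma = 0.2),
                    tau_prior = half_normal_prior(1e-7))
  expect_equal(unlist(predictive(tight)[c("estimate", "lower", "upper")]),
               unlist(posterior_summary(tight, "mu")[c("estimate", "lower", "upper")]),
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("predictive moments match the mixture formula on a simulated fit", {
  d <- simulate_meta_studies(k = 40, mu = 0.1, tau = 1, sigmas = 0.3, seed = 99)
  fit <- fit_nnhm(d, mu_prior_sd = 5, tau_prior = half_normal_prior(2))
  pr <- predictive(fit)
  mix_var <- sum(fit$wt * (fit$cond_var + fit$tau^2)) +
    sum(fit$wt * fit$cond_mean^2) - sum(fit$wt * fit$cond_mean)^2
  half_width <- (pr$upper - pr$lower) / 2
  expect_equal(half_width, 1.96 * sqrt(mix_var), tolerance = 0.05)
})

test_that("posterior_summary validates its arguments", {
  fit <- fit_nnhm(published_study_df())
  expect_error(posterior_summary(fit, "mu", cri_level = 1.2),
               class = "bayesreanal_invalid_input")
  expect_error(posterior_summary(fit, "mu", cri_level = 0),
               class = "bayesreanal_invalid_input")
  # both interval styles are available for either parameter
  sh_mu <- posterior_summary(fit, "mu", interval = "shortest")
  et_mu <- posterior_summary(fit, "mu", interval = "equal_tailed")
  expect_lte(sh_mu$upper - sh_mu$lower, et_mu$upper - et_mu$lower + 1e-9)
  et_tau <- posterior_summary(fit, "tau", interval = "equal_tailed")
  sh_tau <- posterior_summary(fit, "tau", interval = "shortest")
  expect_lte(sh_tau$upper - sh_tau$lower, et_tau$upper - et_tau$lower + 1e-9)
  expect_gt(et_tau$lower, 0)
})

test_that("fit_nnhm rejects degenerate inputs", {
  expect_error(fit_nnhm(data.frame(y = numeric(0), sigma = numeric(0))),
               class = "bayesreanal_invalid_input")
  expect_error(fit_nnhm(data.frame(y = 1, sigma = 0)),
               class = "bayesreanal_invalid_input")
  expect_error(fit_nnhm(published_study_df(), mu_prior_sd = -1),
               class = "bayesreanal_invalid_input")
  expect_error(fit_nnhm(list(1, 2)), class = "bayesreanal_invalid_input")
})

test_that("forest data assembles direct, shrinkage, overall and prediction rows", {
  fit <- fit_nnhm(published_study_df())
  fd <- forest_data(fit)
  expect_identical(nrow(fd), 6L)
  expect_identical(fd$type, c("direct", "direct", "shrinkage", "shrinkage",
                              "overall", "prediction"))
  expect_equal(fd$estimate[fd$type == "direct"], fit$studies$y)
  expect_equal(fd$lower[1], -0.41 - 1.959964 * 0.30, tolerance = 1e-6)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_forest_data(fit, tsv)
  expect_equal(utils::read.delim(tsv)$estimate, fd$estimate, tolerance = 1e-9)
  js <- withr::local_tempfile(fileext = ".json")
  write_nnhm_json(fit, js)
  rec <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(rec$mu$estimate, posterior_summary(fit, "mu")$estimate)
  expect_equal(rec$grid$points, fit$grid$points)
})
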