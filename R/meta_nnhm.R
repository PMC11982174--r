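# Bayesian normal-normal hierarchical meta-analysis (NNHM) by deterministic
# grid integration.
#
# Model: y_i ~ N(theta_i, sigma_i^2), theta_i ~ N(mu, tau^2),
#        mu ~ N(0, mu_prior_sd^2), tau ~ pi(tau).
# Conditional on tau the mu posterior is conjugate normal; the tau marginal
# is computed on a dense grid, and every downstream quantity (mu summaries,
# shrinkage, prediction, Savage-Dickey) is a tau-mixture of conditional
# normals. No Monte Carlo: results are reproducible given the grid spec.

#' Heterogeneity priors for the NNHM
#'
#' `half_normal_prior(sd)` is the weakly informative half-normal prior on
#' the between-study SD tau (default sd 0.5, consistent with empirical
#' heterogeneity distributions across large collections of meta-analyses).
#' `jeffreys_prior()` is the (improper) Jeffreys prior derived from the
#' Fisher information of tau in the marginal model
#' y_i ~ N(mu, sigma_i^2 + tau^2):
#' \deqn{\pi(\tau) \propto \tau \sqrt{\sum_i (\sigma_i^2+\tau^2)^{-2}},}
#' normalized numerically on the integration grid.
#'
#' @param sd scale of the half-normal (> 0).
#' @return An object of class `tau_prior`.
#' @export
half_normal_prior <- function(sd = 0.5) {
  if (!is_num1(sd) || sd <= 0) br_invalid("half-normal sd must be a single positive number")
  structure(list(family = "half_normal", sd = sd, proper = TRUE), class = "tau_prior")
}

#' @rdname half_normal_prior
#' @export
jeffreys_prior <- function() {
  structure(list(family = "jeffreys", sd = NULL, proper = FALSE), class = "tau_prior")
}

# unnormalized prior density on tau >= 0; jeffreys needs the sigmas
tau_prior_density <- function(prior, tau, sigmas) {
  stopifnot(inherits(prior, "tau_prior"))
  switch(prior$family,
    half_normal = 2 * stats::dnorm(tau, 0, prior$sd),
    jeffreys = {
      s <- vapply(tau, function(tt) sum((sigmas^2 + tt^2)^-2), numeric(1))
      tau * sqrt(s)
    })
}

# coerce studies input (data.frame with y/sigma, list of effect_estimate,
# or list of trial_summary) to a data.frame(label, y, sigma)
as_study_df <- function(studies) {
  if (is.data.frame(studies)) {
    if (!all(c("y", "sigma") %in% names(studies)))
      br_invalid("study data.frame needs columns 'y' and 'sigma'")
    if (nrow(studies) < 1L) br_invalid("at least one study is required")
    lab <- if ("label" %in% names(studies)) as.character(studies$label)
           else paste0("study_", seq_len(nrow(studies)))
    d <- data.frame(label = lab, y = as.numeric(studies$y),
                    sigma = as.numeric(studies$sigma), stringsAsFactors = FALSE)
  } else if (is.list(studies) && length(studies) > 0L &&
             all(vapply(studies, inherits, logical(1), "effect_estimate"))) {
    d <- data.frame(label = vapply(studies, `[[`, character(1), "label"),
                    y = vapply(studies, `[[`, numeric(1), "md"),
                    sigma = vapply(studies, `[[`, numeric(1), "se"),
                    stringsAsFactors = FALSE)
  } else if (is.list(studies) && length(studies) > 0L &&
             all(vapply(studies, inherits, logical(1), "trial_summary"))) {
    est <- lapply(studies, effect_from_summary)
    return(as_study_df(est))
  } else br_invalid("studies must be a data.frame(y, sigma) or a list of effect estimates/trial summaries")
  if (nrow(d) < 1L) br_invalid("at least one study is required")
  if (any(!is.finite(d$y)) || any(!is.finite(d$sigma)) || any(d$sigma <= 0))
    br_invalid("study effects must be finite and sigmas positive")
  d
}

# log marginal likelihood log p(y | tau), mu integrated out against
# N(0, s0^2), vectorized over a tau grid; mu_fixed0 gives log p(y | tau, mu=0)
.logml_tau <- function(tau, y, sigma, s0, mu_fixed0 = FALSE) {
  D <- outer(tau^2, sigma^2, "+")                  # n_tau x k
  ssq <- rowSums(sweep(1 / D, 2, y^2, "*"))        # sum y_i^2 / D_i
  if (mu_fixed0)
    return(-0.5 * rowSums(log(2 * pi * D)) - 0.5 * ssq)
  P <- 1 / s0^2 + rowSums(1 / D)
  m <- rowSums(sweep(1 / D, 2, y, "*")) / P
  -0.5 * rowSums(log(2 * pi * D)) - log(s0) - 0.5 * log(P) - 0.5 * (ssq - m^2 * P)
}

#' Fit a Bayesian random-effects meta-analysis by grid integration
#'
#' Fits the normal-normal hierarchical model with a zero-mean normal prior
#' on the overall effect mu and a half-normal or Jeffreys prior on the
#' heterogeneity SD tau. Conditional on tau, the mu posterior is conjugate
#' normal; the tau marginal is evaluated on a dense uniform grid from 0
#' upward, whose upper end is doubled until the posterior tail mass beyond
#' 95% of the grid is below `tail_mass` (proper priors error out at the
#' hard cap of 100 times the largest sigma; the improper Jeffreys prior,
#' whose posterior tail decays only polynomially, is truncated there —
#' point estimates and intervals are insensitive to the truncation).
#'
#' @param studies a `data.frame` with columns `y` (observed effect), `sigma`
#'   (within-study SE) and optionally `label`; or a list of
#'   `effect_estimate` / [trial_summary()] objects (MD and SE are used).
#' @param mu_prior_sd SD of the zero-mean normal prior on mu (> 0);
#'   default 1.
#' @param tau_prior a [half_normal_prior()] (default, sd 0.5) or
#'   [jeffreys_prior()].
#' @param grid_points number of tau grid nodes (>= 1600 by default).
#' @param tail_mass target posterior tail mass beyond the grid.
#' @return An object of class `nnhm_fit`: the tau grid with normalized
#'   quadrature weights, conditional mu moments per node, the study inputs,
#'   prior specification, grid spec and log marginal likelihood components.
#' @examples
#' studies <- data.frame(label = c("TRAILBLAZER-ALZ2", "Clarity"),
#'                       y = c(-0.41, 0.28), sigma = c(0.30, 0.31))
#' fit <- fit_nnhm(studies)
#' posterior_summary(fit, "mu")
#' @export
fit_nnhm <- function(studies, mu_prior_sd = 1,
                     tau_prior = half_normal_prior(0.5),
                     grid_points = 1600L, tail_mass = 1e-6) {
  d <- as_study_df(studies)
  if (!is_num1(mu_prior_sd) || mu_prior_sd <= 0) br_invalid("mu_prior_sd must be positive")
  stopifnot(inherits(tau_prior, "tau_prior"))
  if (!is_count(grid_points, 2L)) br_invalid("grid_points must be an integer >= 2")
  y <- d$y; sigma <- d$sigma
  cap <- 100 * max(sigma)
  # initial upper: a half-normal prior bounds the posterior tail itself
  # (tail mass beyond 8 sd is ~1e-15 whatever the data); the improper
  # Jeffreys prior needs a data-driven start
  upper <- if (tau_prior$family == "half_normal") 8 * tau_prior$sd
           else 10 * max(sigma)

  build <- function(upper) {
    tau <- seq(0, upper, length.out = grid_points)
    lp <- log(tau_prior_density(tau_prior, tau, sigma))
    lml <- .logml_tau(tau, y, sigma, mu_prior_sd)
    lw <- lp + lml
    lw[!is.finite(lw)] <- -Inf
    w <- exp(lw - max(lw[is.finite(lw)]))
    h <- tau[2] - tau[1]
    wt <- w * h; wt[c(1, grid_points)] <- wt[c(1, grid_points)] / 2  # trapezoid
    list(tau = tau, wt = wt / sum(wt), lml = lml, lp = lp, h = h,
         norm = sum(wt))
  }
  g <- build(upper)
  while (sum(g$wt[g$tau > 0.95 * max(g$tau)]) > tail_mass) {
    upper <- 2 * upper
    if (upper > cap) {
      if (tau_prior$proper)
        br_numerical("tau grid failed to capture posterior mass below the hard cap ",
                     signif(cap, 3), "; check the inputs")
      upper <- cap  # improper prior: documented truncation at the cap
      g <- build(upper)
      break
    }
    g <- build(upper)
  }

  D <- outer(g$tau^2, sigma^2, "+")
  P <- 1 / mu_prior_sd^2 + rowSums(1 / D)
  m <- rowSums(sweep(1 / D, 2, y, "*")) / P
  structure(list(studies = d, mu_prior_sd = mu_prior_sd, tau_prior = tau_prior,
                 tau = g$tau, wt = g$wt, log_ml_tau = g$lml,
                 log_prior_tau = g$lp,
                 cond_mean = m, cond_var = 1 / P,
                 grid = list(points = grid_points, upper = max(g$tau),
                             step = g$h, tail_mass = tail_mass)),
            class = "nnhm_fit")
}

# mixture CDF of mu (or any tau-mixture of normals) and its quantiles
.mix_cdf <- function(x, wt, mean, sd) {
  vapply(x, function(q) sum(wt * stats::pnorm(q, mean, sd)), numeric(1))
}

.mix_quantile <- function(p, wt, mean, sd) {
  lo <- min(mean - 10 * sd); hi <- max(mean + 10 * sd)
  vapply(p, function(pp)
    stats::uniroot(function(q) .mix_cdf(q, wt, mean, sd) - pp, c(lo, hi),
                   tol = 1e-10)$root, numeric(1))
}

# shortest interval for a gridded marginal (tau): search lower bounds on the
# grid whose CDF is below 1 - level
.shortest_grid_interval <- function(tau, cdf, level) {
  Fl <- function(x) stats::approx(tau, cdf, x, ties = "ordered", rule = 2)$y
  Qi <- function(p) stats::approx(cdf, tau, p, ties = "ordered", rule = 2)$y
  cand <- tau[cdf <= 1 - level + 1e-12]
  if (length(cand) == 0L) cand <- 0
  best <- c(Inf, NA_real_, NA_real_)  # width, lower, upper
  for (l in cand) {
    u <- Qi(Fl(l) + level)
    if (!is.na(u) && u - l < best[1]) best <- c(u - l, l, u)
  }
  best[2:3]
}

.equal_tailed_grid_interval <- function(tau, cdf, level) {
  a <- (1 - level) / 2
  Qi <- function(p) stats::approx(cdf, tau, p, ties = "ordered", rule = 2)$y
  c(Qi(a), Qi(1 - a))
}

#' Posterior summaries for the overall effect or the heterogeneity
#'
#' Point estimate (median by default, mean available) and credible interval
#' for mu or tau. The mu interval is equal-tailed by default (the mu
#' posterior is a tau-mixture of conditional normals); the tau interval is
#' shortest-coverage by default, so its lower bound may be 0. Both interval
#' styles are available for either parameter.
#'
#' @param fit an [fit_nnhm()] object.
#' @param param `"mu"` or `"tau"`.
#' @param kind `"median"` (default) or `"mean"`.
#' @param cri_level credible level in (0, 1); default 0.95.
#' @param interval `"equal_tailed"` or `"shortest"`; default depends on
#'   `param`.
#' @return A list with `param`, `kind`, `estimate`, `level`, `interval`,
#'   `lower`, `upper`.
#' @export
posterior_summary <- function(fit, param = c("mu", "tau"),
                              kind = c("median", "mean"), cri_level = 0.95,
                              interval = NULL) {
  stopifnot(inherits(fit, "nnhm_fit"))
  param <- match.arg(param); kind <- match.arg(kind)
  if (!is_num1(cri_level) || cri_level <= 0 || cri_level >= 1)
    br_invalid("cri_level must be in (0, 1)")
  interval <- interval %||% if (param == "mu") "equal_tailed" else "shortest"
  interval <- match.arg(interval, c("equal_tailed", "shortest"))
  a <- (1 - cri_level) / 2
  if (param == "mu") {
    sdv <- sqrt(fit$cond_var)
    est <- if (kind == "mean") sum(fit$wt * fit$cond_mean)
           else .mix_quantile(0.5, fit$wt, fit$cond_mean, sdv)
    if (interval == "equal_tailed") {
      ci <- .mix_quantile(c(a, 1 - a), fit$wt, fit$cond_mean, sdv)
    } else {
      # shortest interval for the (unimodal) mu mixture: optimize the lower
      # tail probability
      qfun <- function(p) .mix_quantile(c(p, p + cri_level), fit$wt, fit$cond_mean, sdv)
      opt <- stats::optimize(function(p) diff(qfun(p)), c(1e-9, 1 - cri_level - 1e-9))
      ci <- qfun(opt$minimum)
    }
  } else {
    cdf <- cumsum(fit$wt)
    est <- if (kind == "mean") sum(fit$wt * fit$tau)
           else stats::approx(cdf, fit$tau, 0.5, ties = "ordered", rule = 2)$y
    ci <- if (interval == "equal_tailed")
      .equal_tailed_grid_interval(fit$tau, cdf, cri_level)
    else .shortest_grid_interval(fit$tau, cdf, cri_level)
  }
  list(param = param, kind = kind, estimate = est, level = cri_level,
       interval = interval, lower = ci[1], upper = ci[2])
}

#' Shrinkage (study-level) posterior estimates
#'
#' Posterior of each study's true effect theta_i. Conditional on tau,
#' theta_i is normal with mean `w y_i + (1 - w) m(tau)` and variance
#' `w sigma_i^2 + (1 - w)^2 v(tau)` where `w = tau^2 / (tau^2 + sigma_i^2)`
#' and (m, v) are the conditional mu posterior moments; the reported
#' posterior mixes these over the tau marginal. As tau -> 0 every theta_i
#' coincides with mu (complete pooling); as tau -> infinity it reverts to
#' the study's own likelihood N(y_i, sigma_i^2).
#'
#' @param fit an [fit_nnhm()] object.
#' @param index study index or vector of indices; `NULL` for all.
#' @param cri_level credible level; intervals are equal-tailed.
#' @return A data.frame with `label`, `y`, `sigma`, `estimate` (posterior
#'   median), `lower`, `upper`.
#' @export
shrinkage <- function(fit, index = NULL, cri_level = 0.95) {
  stopifnot(inherits(fit, "nnhm_fit"))
  k <- nrow(fit$studies)
  index <- index %||% seq_len(k)
  if (any(index < 1L | index > k)) br_invalid("study index out of range 1..", k)
  a <- (1 - cri_level) / 2
  rows <- lapply(index, function(i) {
    yi <- fit$studies$y[i]; si <- fit$studies$sigma[i]
    w <- fit$tau^2 / (fit$tau^2 + si^2)
    mean_i <- w * yi + (1 - w) * fit$cond_mean
    sd_i <- sqrt(w * si^2 + (1 - w)^2 * fit$cond_var)
    qs <- .mix_quantile(c(0.5, a, 1 - a), fit$wt, mean_i, sd_i)
    data.frame(label = fit$studies$label[i], y = yi, sigma = si,
               estimate = qs[1], lower = qs[2], upper = qs[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Posterior predictive distribution for a new study
#'
#' The effect expected in a hypothetical new exchangeable study,
#' theta_new | data: a tau-mixture of N(m(tau), v(tau) + tau^2). Its
#' interval is at least as wide as the mu credible interval, since the
#' between-study variance adds to the posterior uncertainty about mu.
#'
#' @param fit an [fit_nnhm()] object.
#' @param cri_level credible level; equal-tailed interval.
#' @return A list with `estimate` (median), `lower`, `upper`, `level`.
#' @export
predictive <- function(fit, cri_level = 0.95) {
  stopifnot(inherits(fit, "nnhm_fit"))
  a <- (1 - cri_level) / 2
  sdv <- sqrt(fit$cond_var + fit$tau^2)
  qs <- .mix_quantile(c(0.5, a, 1 - a), fit$wt, fit$cond_mean, sdv)
  list(estimate = qs[1], lower = qs[2], upper = qs[3], level = cri_level)
}

#' Bayes factor for a nonzero overall effect in the meta-analysis
#'
#' Three routes are implemented:
#' \describe{
#'   \item{`"savage_dickey"`}{(default) the Savage--Dickey density ratio for
#'     the point null mu = 0 nested in the fitted model: BF01 is the
#'     marginal posterior density of mu at 0 (evaluated exactly from the
#'     tau-mixture of conditional normals) over the prior density at 0.}
#'   \item{`"ml_ratio"`}{the marginal-likelihood ratio of the full model to
#'     the mu = 0 submodel, each integrated over the tau prior on the grid;
#'     analytically identical to Savage--Dickey and used as an internal
#'     cross-check.}
#'   \item{`"inclusion"`}{the fixed/random model-averaged Bayes factor:
#'     both hypotheses average a fixed-effect (tau = 0) and a random-effects
#'     (tau ~ prior) variant with equal model prior odds,
#'     BF10 = (p(y|FE1) + p(y|RE1)) / (p(y|FE0) + p(y|RE0)). This is the
#'     default convention of the model-averaged meta-analysis software
#'     family and requires a proper tau prior.}
#' }
#'
#' @param fit an [fit_nnhm()] object (mu prior must be proper, as it is by
#'   construction here).
#' @param type `"savage_dickey"`, `"ml_ratio"` or `"inclusion"`.
#' @return An object of class `meta_bf`: list with `bf10`, `bf01`,
#'   `log_bf10`, `type`.
#' @export
bf10_meta <- function(fit, type = c("savage_dickey", "ml_ratio", "inclusion")) {
  stopifnot(inherits(fit, "nnhm_fit"))
  type <- match.arg(type)
  y <- fit$studies$y; sigma <- fit$studies$sigma; s0 <- fit$mu_prior_sd
  if (type == "savage_dickey") {
    post0 <- sum(fit$wt * stats::dnorm(0, fit$cond_mean, sqrt(fit$cond_var)))
    bf01 <- post0 / stats::dnorm(0, 0, s0)
  } else {
    # prior-weighted grid averages of the conditional marginal likelihoods
    lw <- fit$log_prior_tau
    lw[!is.finite(lw)] <- -Inf
    h <- fit$grid$step
    pw <- exp(lw - max(lw[is.finite(lw)])) * h
    pw[c(1, length(pw))] <- pw[c(1, length(pw))] / 2
    lml0 <- .logml_tau(fit$tau, y, sigma, s0, mu_fixed0 = TRUE)
    c0 <- max(fit$log_ml_tau)
    re1 <- sum(pw * exp(fit$log_ml_tau - c0))
    re0 <- sum(pw * exp(lml0 - c0))
    if (type == "ml_ratio") {
      bf01 <- re0 / re1
    } else {
      if (!fit$tau_prior$proper)
        br_invalid("the inclusion Bayes factor requires a proper tau prior")
      pw <- pw / sum(pw)  # normalized model-internal prior over tau
      re1 <- sum(pw * exp(fit$log_ml_tau - c0))
      re0 <- sum(pw * exp(lml0 - c0))
      fe1 <- exp(.logml_tau(0, y, sigma, s0) - c0)
      fe0 <- exp(.logml_tau(0, y, sigma, s0, mu_fixed0 = TRUE) - c0)
      bf01 <- (fe0 + re0) / (fe1 + re1)
    }
  }
  structure(list(bf10 = 1 / bf01, bf01 = bf01, log_bf10 = -log(bf01),
                 type = type, mu_prior_sd = s0,
                 tau_prior = fit$tau_prior$family),
            class = "meta_bf")
}

#' @export
print.meta_bf <- function(x, ...) {
  cat(sprintf("Meta-analytic BF10 = %.4g (%s route): %s\n",
              x$bf10, x$type, classify_evidence(x$bf10)))
  invisible(x)
}

#' @export
print.nnhm_fit <- function(x, ...) {
  mu <- posterior_summary(x, "mu"); tau <- posterior_summary(x, "tau")
  cat(sprintf("NNHM fit: %d studies, mu ~ N(0, %.3g^2), tau ~ %s\n",
              nrow(x$studies), x$mu_prior_sd, x$tau_prior$family))
  cat(sprintf("  mu  %.3f [%.3f, %.3f] (median, equal-tailed 95%%)\n",
              mu$estimate, mu$lower, mu$upper))
  cat(sprintf("  tau %.3f [%.3f, %.3f] (median, shortest 95%%)\n",
              tau$estimate, tau$lower, tau$upper))
  cat(sprintf("  grid: %d nodes on [0, %.3g]\n", x$grid$points, x$grid$upper))
  invisible(x)
}

#' Forest-plot data: direct, shrinkage, overall and predictive rows
#'
#' Assembles the quantities of a meta-analytic forest plot as a plain
#' data.frame: one row per study with the direct estimate (y with its
#' normal 95% CI) and the shrinkage posterior, then an `overall` row (mu
#' posterior) and a `prediction` row (posterior predictive).
#'
#' @param fit an [fit_nnhm()] object.
#' @param cri_level credible level.
#' @return A data.frame with columns `label`, `type`, `estimate`, `lower`,
#'   `upper`.
#' @export
forest_data <- function(fit, cri_level = 0.95) {
  stopifnot(inherits(fit, "nnhm_fit"))
  z <- stats::qnorm(1 - (1 - cri_level) / 2)
  direct <- data.frame(label = fit$studies$label, type = "direct",
                       estimate = fit$studies$y,
                       lower = fit$studies$y - z * fit$studies$sigma,
                       upper = fit$studies$y + z * fit$studies$sigma,
                       stringsAsFactors = FALSE)
  sh <- shrinkage(fit, cri_level = cri_level)
  shr <- data.frame(label = sh$label, type = "shrinkage",
                    estimate = sh$estimate, lower = sh$lower, upper = sh$upper,
                    stringsAsFactors = FALSE)
  mu <- posterior_summary(fit, "mu", cri_level = cri_level)
  pr <- predictive(fit, cri_level = cri_level)
  rbind(direct, shr,
        data.frame(label = "overall", type = "overall", estimate = mu$estimate,
                   lower = mu$lower, upper = mu$upper, stringsAsFactors = FALSE),
        data.frame(label = "prediction", type = "prediction",
                   estimate = pr$estimate, lower = pr$lower, upper = pr$upper,
                   stringsAsFactors = FALSE))
}

#' Serialize a meta-analysis fit
#'
#' `write_forest_data()` writes the [forest_data()] table as TSV;
#' `write_nnhm_json()` writes a JSON fit record (inputs, priors, grid spec,
#' posterior summaries, Bayes factors).
#'
#' @param fit an [fit_nnhm()] object.
#' @param path output path.
#' @param cri_level credible level for the serialized summaries.
#' @return `path`, invisibly.
#' @export
write_forest_data <- function(fit, path, cri_level = 0.95) {
  utils::write.table(forest_data(fit, cri_level), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forest_data
#' @export
write_nnhm_json <- function(fit, path, cri_level = 0.95) {
  stopifnot(inherits(fit, "nnhm_fit"))
  mu <- posterior_summary(fit, "mu", cri_level = cri_level)
  tau <- posterior_summary(fit, "tau", cri_level = cri_level)
  pr <- predictive(fit, cri_level)
  bf <- bf10_meta(fit)
  rec <- list(
    studies = fit$studies,
    priors = list(mu = list(family = "normal", mean = 0, sd = fit$mu_prior_sd),
                  tau = fit$tau_prior[!vapply(fit$tau_prior, is.null, logical(1))]),
    grid = fit$grid,
    mu = mu, tau = tau, prediction = pr,
    bf10 = list(savage_dickey = bf$bf10,
                inclusion = if (fit$tau_prior$proper)
                  bf10_meta(fit, "inclusion")$bf10 else NULL))
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
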