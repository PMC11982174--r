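# Monte-Carlo prior-predictive oracle for the quadrature Bayes factors:
# BF10 = E_prior[ f_nct(t; df, delta sqrt(n_eff)) ] / f_t(t; df),
# estimated by direct prior sampling, with its Monte-Carlo standard error.
mc_bf10 <- function(t, n_a, n_b, prior, n_draws = 2e5, seed = 1) {
  df <- n_a + n_b
  n_eff <- n_a * n_b / (n_a + n_b)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  delta <- prior_sample(prior, n_draws)
  num <- suppressWarnings(dt(t, df, ncp = delta * sqrt(n_eff)))
  num[!is.finite(num)] <- 0
  ratio <- num / dt(t, df)
  list(bf10 = mean(ratio), se = sd(ratio) / sqrt(n_draws))
}

published_studies <- function() apoe4_subgroup_summaries()

published_effects <- function() {
  s <- published_studies()
  e1 <- effect_from_summary(s[[1]])
  e2 <- effect_from_summary(s[[2]])
  list(don = e1, lec = e2, diff = difference_effect(e1, e2))
}

published_study_df <- function() {
  data.frame(label = c("TRAILBLAZER-ALZ2", "Clarity"),
             y = c(-0.41, 0.28), sigma = c(0.30, 0.31),
             stringsAsFactors = FALSE)
}
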