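#' Published subgroup summary of a two-arm trial
#'
#' Container for one published comparison: the adjusted mean difference (MD)
#' between treatment and placebo on the outcome scale (here CDR-SB points),
#' its 95% confidence interval and/or standard error, and the number of
#' cases per arm. At least one of the CI pair and `se` must be given; the
#' missing one is reconstructed downstream.
#'
#' @param label study / comparison label.
#' @param md mean difference, outcome-scale points (treatment minus placebo;
#'   negative favors treatment for a harm scale such as CDR-SB).
#' @param ci_lower,ci_upper 95% confidence bounds for `md` (optional if `se`
#'   given).
#' @param se standard error of `md` (optional if the CI pair is given).
#' @param n_a,n_b number of cases in each group (>= 2).
#' @return An object of class `trial_summary`.
#' @examples
#' trial_summary("TRAILBLAZER-ALZ2", md = -0.41, se = 0.30, n_a = 123, n_b = 97)
#' @export
trial_summary <- function(label, md, ci_lower = NA_real_, ci_upper = NA_real_,
                          se = NA_real_, n_a, n_b) {
  if (!is.character(label) || length(label) != 1L) br_invalid("label must be a single string")
  if (!is_num1(md)) br_invalid("md must be a single finite number")
  if (!is_count(n_a, 2L) || !is_count(n_b, 2L)) br_invalid("n_a and n_b must be integer counts >= 2")
  has_ci <- is_num1(ci_lower) && is_num1(ci_upper)
  has_se <- is_num1(se)
  if (!has_ci && !has_se) br_invalid("either the CI pair (ci_lower, ci_upper) or se must be given")
  if (has_ci && ci_lower > ci_upper) br_invalid("inverted confidence interval: ci_lower > ci_upper")
  if (has_se && se < 0) br_invalid("se must be non-negative")
  structure(list(label = label, md = md,
                 ci_lower = if (has_ci) ci_lower else NA_real_,
                 ci_upper = if (has_ci) ci_upper else NA_real_,
                 se = if (has_se) se else NA_real_,
                 n_a = as.integer(n_a), n_b = as.integer(n_b)),
            class = "trial_summary")
}

#' Standard error from a 95% confidence interval
#'
#' SE = |upper - lower| / (2 t(df, 0.975)), with the Student-t quantile for
#' df <= 120 and the standard-normal quantile 1.959964 above (at the sample
#' sizes of interest, > 200 cases, the two coincide to the printed
#' precision).
#'
#' @param ci_lower,ci_upper 95% confidence bounds.
#' @param df degrees of freedom (>= 3).
#' @return The standard error (>= 0).
#' @examples
#' se_from_ci(-0.83, 0.12, df = 1000) # 0.2423, reported as 0.24
#' @export
se_from_ci <- function(ci_lower, ci_upper, df) {
  if (!is_num1(ci_lower) || !is_num1(ci_upper)) br_invalid("CI bounds must be single finite numbers")
  if (!is.numeric(df) || length(df) != 1L || !is.finite(df) || df < 3)
    br_invalid("df must be a single number >= 3")
  if (ci_lower > ci_upper) br_invalid("inverted confidence interval: ci_lower > ci_upper")
  q <- if (df > 120) 1.959964 else stats::qt(0.975, df)
  abs(ci_upper - ci_lower) / (2 * q)
}

#' Standard error of a difference of two independent estimates
#'
#' @param se_a,se_b standard errors (>= 0).
#' @return sqrt(se_a^2 + se_b^2).
#' @examples
#' combine_se(0.30, 0.31) # 0.4314, reported as 0.43
#' @export
combine_se <- function(se_a, se_b) {
  if (!is_num1(se_a) || !is_num1(se_b) || se_a < 0 || se_b < 0)
    br_invalid("standard errors must be single non-negative numbers")
  sqrt(se_a^2 + se_b^2)
}

resolve_df <- function(n_a, n_b, df_convention = c("total", "residual")) {
  df_convention <- match.arg(df_convention)
  if (df_convention == "total") n_a + n_b else n_a + n_b - 2L
}

#' Reconstruct a full effect estimate from a published summary
#'
#' Resolves the standard error (from the CI if absent), and derives the
#' t statistic T = MD/SE, the implied standard deviation of the effect
#' SD = SE sqrt(n_a n_b / (n_a + n_b)), and Cohen's d = MD/SD.
#'
#' @param s a [trial_summary()].
#' @param df_convention `"total"` uses df = n_a + n_b (the convention of the
#'   source analyses reproduced here); `"residual"` uses the conventional
#'   n_a + n_b - 2. The difference is negligible at the sample sizes of
#'   interest.
#' @return An object of class `effect_estimate` with fields `label`, `md`,
#'   `se`, `df`, `t`, `sd`, `d`, `n_a`, `n_b`.
#' @examples
#' s <- trial_summary("TRAILBLAZER-ALZ2", md = -0.41, se = 0.30,
#'                    n_a = 123, n_b = 97)
#' effect_from_summary(s)
#' @export
effect_from_summary <- function(s, df_convention = c("total", "residual")) {
  stopifnot(inherits(s, "trial_summary"))
  df_convention <- match.arg(df_convention)
  df <- resolve_df(s$n_a, s$n_b, df_convention)
  se <- if (is.finite(s$se)) s$se else se_from_ci(s$ci_lower, s$ci_upper, df)
  if (se == 0) br_numerical("standard error is zero for '", s$label,
                            "': t statistic undefined (md = ", s$md, ")")
  new_effect_estimate(s$label, s$md, se, s$n_a, s$n_b, df_convention)
}

new_effect_estimate <- function(label, md, se, n_a, n_b, df_convention) {
  df <- resolve_df(n_a, n_b, df_convention)
  sd <- se * sqrt(n_a * n_b / (n_a + n_b))
  structure(list(label = label, md = md, se = se, df = as.integer(df),
                 t = md / se, sd = sd, d = md / sd,
                 n_a = as.integer(n_a), n_b = as.integer(n_b),
                 df_convention = df_convention),
            class = "effect_estimate")
}

#' Difference-of-effects contrast between two reconstructed estimates
#'
#' Forms the "effect of A versus effect of B" contrast: MD is the difference
#' of the two mean differences, SE combines in quadrature via
#' [combine_se()], and each trial's total sample acts as one group of the
#' contrast (so the contrast of a 123/97 trial against a 132/136 trial has
#' groups 220/268).
#'
#' @param a,b `effect_estimate` objects.
#' @param label label for the contrast row.
#' @return An `effect_estimate` for the contrast.
#' @export
difference_effect <- function(a, b, label = paste(a$label, "versus", b$label)) {
  stopifnot(inherits(a, "effect_estimate"), inherits(b, "effect_estimate"))
  new_effect_estimate(label, a$md - b$md, combine_se(a$se, b$se),
                      n_a = a$n_a + a$n_b, n_b = b$n_a + b$n_b,
                      df_convention = a$df_convention)
}

#' Tabulate reconstructed effect estimates
#'
#' @param effects a list of `effect_estimate` objects (or a single one).
#' @return A data.frame with one row per estimate: label, md, se, n_a, n_b,
#'   t, sd, d.
#' @export
effect_table <- function(effects) {
  if (inherits(effects, "effect_estimate")) effects <- list(effects)
  stopifnot(all(vapply(effects, inherits, logical(1), "effect_estimate")))
  do.call(rbind, lapply(effects, function(e)
    data.frame(label = e$label, md = e$md, se = e$se,
               n_a = e$n_a, n_b = e$n_b, df = e$df,
               t = e$t, sd = e$sd, d = e$d,
               stringsAsFactors = FALSE)))
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: MD %.2f (SE %.2f), n %d/%d, t = %.2f, SD %.2f, d = %.2f\n",
              x$label, x$md, x$se, x$n_a, x$n_b,
              round_away(x$t, 2), x$sd, round_away(x$d, 2)))
  invisible(x)
}

#' @export
print.trial_summary <- function(x, ...) {
  ci <- if (is.finite(x$ci_lower)) sprintf(" [%.2f, %.2f]", x$ci_lower, x$ci_upper) else ""
  se <- if (is.finite(x$se)) sprintf(", SE %.2f", x$se) else ""
  cat(sprintf("%s: MD %.2f%s%s, n %d/%d\n", x$label, x$md, ci, se, x$n_a, x$n_b))
  invisible(x)
}

# normalize Unicode minus (U+2212) and en dash used as minus to hyphen-minus
normalize_minus <- function(x) {
  x <- gsub("−", "-", x)
  trimws(x)
}

#' Read trial subgroup summaries from CSV
#'
#' Expects the header `label,md,ci_lower,ci_upper,se,n_a,n_b`; empty cells
#' are allowed for the optional fields (either the CI pair or `se` must be
#' present in each row). Unicode minus signs in numeric fields are
#' normalized.
#'
#' @param path CSV file path.
#' @return A list of [trial_summary()] objects.
#' @export
read_trial_summaries <- function(path) {
  d <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("label", "md", "ci_lower", "ci_upper", "se", "n_a", "n_b")
  if (!all(need %in% names(d)))
    br_invalid("CSV must have header: ", paste(need, collapse = ","))
  num <- function(x) suppressWarnings(as.numeric(normalize_minus(x)))
  lapply(seq_len(nrow(d)), function(i) {
    row <- d[i, ]
    tryCatch(
      trial_summary(label = trimws(row$label), md = num(row$md),
                    ci_lower = num(row$ci_lower) %|NA|% NA_real_,
                    ci_upper = num(row$ci_upper) %|NA|% NA_real_,
                    se = num(row$se) %|NA|% NA_real_,
                    n_a = num(row$n_a), n_b = num(row$n_b)),
      bayesreanal_invalid_input = function(e)
        br_invalid("row ", i, " (", row$label, "): ", conditionMessage(e)))
  })
}

`%|NA|%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a

#' Write a reconstructed effect table to TSV or JSON
#'
#' @param effects list of `effect_estimate` objects or the data.frame from
#'   [effect_table()].
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(effects, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- if (is.data.frame(effects)) effects else effect_table(effects)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(tab, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
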