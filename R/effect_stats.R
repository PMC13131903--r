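# Per tract-feature sex-difference testing: pooled t, Cohen's d, Bonferroni.

#' Pooled-variance two-sample t-test
#'
#' Student's (equal-variance) two-sample t statistic for male minus female,
#' with a two-sided p-value from the t distribution on
#' `n_male + n_female - 2` degrees of freedom. The pooled variance is the
#' df-weighted average of the two sample variances (denominator n - 1).
#'
#' @param values_male,values_female Numeric vectors, each of length >= 2.
#' @return A list with `t_stat`, `df`, `p_value`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
two_sample_t <- function(values_male, values_female) {
  p <- pooled_stats(values_male, values_female)
  t_stat <- (p$m1 - p$m2) / (p$sp * sqrt(1 / p$n1 + 1 / p$n2))
  list(t_stat = t_stat, df = p$df,
       p_value = 2 * pt(-abs(t_stat), df = p$df))
}

#' Cohen's d for a sex difference
#'
#' Standardized mean difference, male minus female, over the pooled standard
#' deviation (df-weighted, sample variances with denominator n - 1). Positive
#' d means males higher; this sign convention is used throughout the package.
#'
#' @inheritParams two_sample_t
#' @return A single numeric d.
#' @examples
#' cohens_d(c(1, 2, 3), c(2, 3, 4))  # -1
#' @export
cohens_d <- function(values_male, values_female) {
  p <- pooled_stats(values_male, values_female)
  (p$m1 - p$m2) / p$sp
}

pooled_stats <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    abort("each group needs at least 2 values", class = "tc_group_too_small")
  }
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  if (!is.finite(sp2) || sp2 <= 0) {
    abort("zero pooled variance: groups are degenerate (all values equal)",
          class = "tc_degenerate_variance")
  }
  list(n1 = n1, n2 = n2, m1 = mean(x), m2 = mean(y),
       df = df, sp = sqrt(sp2))
}

#' Bin an effect size by conventional magnitude
#'
#' Classifies |d| into negligible (< 0.2), small (0.2 to < 0.5), medium
#' (0.5 to < 0.8) and large (>= 0.8). Boundaries belong to the larger-named
#' bin (half-open intervals), so d = 0.2 is small and d = 0.8 is large.
#'
#' @param d Numeric vector of (signed) Cohen's d values; finite.
#' @return A factor with levels negligible, small, medium, large.
#' @examples
#' classify_magnitude(c(-0.19, 0.2, 0.65, 1.1))
#' @export
classify_magnitude <- function(d) {
  stopifnot(all(is.finite(d)))
  cut(abs(d), breaks = c(0, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large"))
}

#' Significance policy for the tract-feature test family
#'
#' Bonferroni control: the effective per-test threshold is
#' `alpha_family / m`, with `m` defaulting to the number of tract-feature
#' pairs actually tested. `override_threshold` replaces the computed value
#' outright; setting it to 6.5e-5 reproduces a replication-mode analysis that
#' inherits a more conservative threshold from a larger original test family.
#'
#' @param alpha_family Family-wise alpha (default 0.05).
#' @param m Number of comparisons; `NULL` (default) means "however many pairs
#'   the batch contains".
#' @param override_threshold Optional explicit per-test p threshold.
#' @return A list of class `significance_policy`.
#' @export
significance_policy <- function(alpha_family = 0.05, m = NULL,
                                override_threshold = NULL) {
  stopifnot(alpha_family > 0, alpha_family <= 1)
  if (!is.null(m)) stopifnot(m >= 1)
  if (!is.null(override_threshold)) stopifnot(override_threshold > 0)
  structure(list(alpha_family = alpha_family, m = m,
                 override_threshold = override_threshold),
            class = "significance_policy")
}

effective_threshold <- function(policy, n_pairs) {
  policy$override_threshold %||% (policy$alpha_family / (policy$m %||% n_pairs))
}

#' Test every tract-feature pair of one pipeline for a sex difference
#'
#' Runs the pooled t-test and Cohen's d for each (tract, feature) in the
#' table. Subjects missing a given pair are dropped for that pair only, and
#' the effective group sizes are recorded. Degenerate pairs (a group smaller
#' than 2, or zero pooled variance) do not abort the batch: they yield a row
#' flagged `degenerate` with `NA` statistics and `significant = FALSE`.
#'
#' @param table A [tract_feature_table()] containing both sexes.
#' @param policy A [significance_policy()]; default Bonferroni 0.05 over the
#'   pairs tested.
#' @return A tibble with one row per (tract, feature): group sizes and means,
#'   `t_stat`, `df`, `p_value`, `d`, `direction` (`male_higher` /
#'   `female_higher` / `none`), `magnitude`, `significant`, `degenerate`,
#'   plus the `pipeline_id` and the `threshold` applied (as attributes
#'   `threshold` and `n_pairs` too).
#' @export
run_effects <- function(table, policy = significance_policy()) {
  stopifnot(inherits(table, "tract_feature_table"))
  if (length(unique(table$sex)) < 2) {
    abort("table must contain both sexes")
  }
  pid <- pipeline_id(table)

  one_pair <- function(value, sex) {
    x <- value[sex == "male"]
    y <- value[sex == "female"]
    res <- tryCatch(
      c(two_sample_t(x, y), list(d = cohens_d(x, y), degenerate = FALSE)),
      error = function(e) list(t_stat = NA_real_, df = NA_integer_,
                               p_value = NA_real_, d = NA_real_,
                               degenerate = TRUE)
    )
    tibble::tibble(
      n_male = length(x), n_female = length(y),
      mean_male = if (length(x)) mean(x) else NA_real_,
      mean_female = if (length(y)) mean(y) else NA_real_,
      t_stat = res$t_stat, df = res$df, p_value = res$p_value, d = res$d,
      degenerate = res$degenerate
    )
  }

  out <- tibble::as_tibble(table) |>
    dplyr::group_by(.data$tract, .data$feature) |>
    dplyr::summarise(one_pair(.data$value, .data$sex), .groups = "drop")

  thr <- effective_threshold(policy, nrow(out))
  out$direction <- dplyr::case_when(
    is.na(out$d) ~ NA_character_,
    out$d > 0 ~ "male_higher",
    out$d < 0 ~ "female_higher",
    TRUE ~ "none"
  )
  out$magnitude <- factor(NA, levels = c("negligible", "small", "medium", "large"))
  ok <- !is.na(out$d)
  out$magnitude[ok] <- classify_magnitude(out$d[ok])
  out$significant <- !is.na(out$p_value) & out$p_value < thr
  out <- tibble::add_column(out, pipeline_id = pid, .before = 1)
  attr(out, "threshold") <- thr
  attr(out, "n_pairs") <- nrow(out)
  out
}
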