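# Shared fixtures and independent oracles.

# Independent oracle for the pooled t-test: stats::t.test with equal
# variances, never the package's own formula.
oracle_t <- function(x, y) {
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

# Direct textbook evaluation of Cohen's d with pooled SD, written
# independently of the package path.
oracle_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * stats::sd(x)^2 +
                (length(y) - 1) * stats::sd(y)^2) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

# Plain-loop percentile bootstrap of |d1| - |d2|, stratified by sex with
# pairing preserved; an independent Monte-Carlo cross-check for the
# vectorized implementation.
naive_boot_ci <- function(x1, x2, male, n_boot, seed) {
  set.seed(seed)
  im <- which(male); if_ <- which(!male)
  delta <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    sm <- sample(im, length(im), replace = TRUE)
    sf <- sample(if_, length(if_), replace = TRUE)
    d1 <- oracle_d(x1[sm], x1[sf])
    d2 <- oracle_d(x2[sm], x2[sf])
    delta[b] <- abs(d1) - abs(d2)
  }
  stats::quantile(delta, c(0.025, 0.975), type = 7, names = FALSE)
}

# Minimal long-format data frame using real registry labels.
toy_rows <- function(subjects = c("s1", "s2", "s3", "s4"),
                     sex = c("male", "male", "female", "female"),
                     tracts = c("CA", "MCP"),
                     features = c("FA", "MD")) {
  g <- expand.grid(subject_id = subjects, tract = tracts, feature = features,
                   stringsAsFactors = FALSE)
  g$sex <- sex[match(g$subject_id, subjects)]
  g$value <- seq_len(nrow(g)) / 10
  g[c("subject_id", "sex", "tract", "feature", "value")]
}

# One-row effect result carrying just what the concordance stage reads.
effect_row <- function(tract = "CA", feature = "FA",
                       significant = FALSE, direction = "male_higher",
                       d = 0.1) {
  tibble::tibble(tract = tract, feature = feature,
                 significant = significant, direction = direction,
                 d = d, p_value = if (significant) 1e-8 else 0.5)
}

# Small two-pipeline cohort for a single tract-feature pair.
pair_cohort <- function(d1, d2, n_male = 200, n_female = 200, rho = 0.6,
                        seed = 1) {
  cfg <- sim_config(
    n_male = n_male, n_female = n_female, tracts = "CA", features = "FA",
    true_d = tibble::tibble(tract = "CA", feature = "FA",
                            pipeline = 1:2, d = c(d1, d2)),
    rho = rho, seed = seed)
  generate_cohort(cfg)
}
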