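test_that("taxonomy assigns the documented categories on canonical cases", {
  # both significant, same direction -> A, strict agreement
  r <- classify_concordance(
    effect_row(significant = TRUE, direction = "male_higher", d = 0.4),
    effect_row(significant = TRUE, direction = "male_higher", d = 0.3))
  expect_equal(as.character(r$base_category), "A")
  expect_true(r$strict_agreement)
  expect_false(r$soft_disagreement)

  # both significant, opposite directions -> F, strict disagreement
  r <- classify_concordance(
    effect_row(significant = TRUE, direction = "male_higher", d = 0.4),
    effect_row(significant = TRUE, direction = "female_higher", d = -0.3))
  expect_equal(as.character(r$base_category), "F")
  expect_true(r$strict_disagreement)
  expect_false(r$strict_agreement)

  # neither significant, opposite directions -> D: the documented overlap,
  # simultaneously strict agreement and soft disagreement
  r <- classify_concordance(
    effect_row(significant = FALSE, direction = "male_higher", d = 0.05),
    effect_row(significant = FALSE, direction = "female_higher", d = -0.02))
  expect_equal(as.character(r$base_category), "D")
  expect_true(r$strict_agreement)
  expect_true(r$soft_disagreement)
  expect_true(r$soft_agreement)  # default variant includes D

  # the directional-only soft-agreement variant excludes D
  r2 <- classify_concordance(
    effect_row(significant = FALSE, direction = "male_higher", d = 0.05),
    effect_row(significant = FALSE, direction = "female_higher", d = -0.02),
    soft_agreement = "directional_only")
  expect_false(r2$soft_agreement)
})

test_that("all significance x direction combinations land in exactly one category", {
  sig <- c(TRUE, FALSE)
  dir <- c("male_higher", "female_higher")
  grid <- expand.grid(s1 = sig, s2 = sig, d1 = dir, d2 = dir,
                      stringsAsFactors = FALSE)
  want_cat <- function(s1, s2, d1, d2) {
    same <- d1 == d2
    n <- s1 + s2
    if (same) c("C", "B", "A")[n + 1] else c("D", "E", "F")[n + 1]
  }
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    r <- classify_concordance(
      effect_row(significant = g$s1, direction = g$d1,
                 d = ifelse(g$d1 == "male_higher", 0.3, -0.3)),
      effect_row(significant = g$s2, direction = g$d2,
                 d = ifelse(g$d2 == "male_higher", 0.3, -0.3)))
    expect_equal(as.character(r$base_category),
                 want_cat(g$s1, g$s2, g$d1, g$d2))
    # composite membership is a function of the base category alone
    expect_equal(r$strict_agreement, r$base_category %in% c("A", "C", "D"))
    expect_equal(r$soft_agreement, r$base_category %in% c("A", "B", "C", "D"))
    expect_equal(r$strict_disagreement, r$base_category == "F")
    expect_equal(r$soft_disagreement, r$base_category %in% c("D", "E", "F"))
    # strict agreement and strict disagreement never co-occur
    expect_false(r$strict_agreement && r$strict_disagreement)
  }
})

test_that("direction 'none' is agreement-leaning and counted", {
  r <- classify_concordance(
    effect_row(significant = FALSE, direction = "none", d = 0),
    effect_row(significant = FALSE, direction = "female_higher", d = -0.1))
  expect_equal(as.character(r$base_category), "C")
  expect_equal(attr(r, "n_direction_none"), 1L)
})

test_that("mismatched or duplicated keys are rejected", {
  a <- effect_row(tract = "CA")
  b <- effect_row(tract = "MCP")
  expect_error(classify_concordance(a, b), "pairs")
  dup <- dplyr::bind_rows(a, a)
  expect_error(classify_concordance(dup, dup), "duplicate")
})

test_that("summary counts partition records and stratify by feature class", {
  set.seed(41)
  tracts <- tract_registry()$abbreviation[1:10]
  feats <- feature_registry()$feature
  rows1 <- list(); rows2 <- list()
  for (tr in tracts) for (fe in feats) {
    s1 <- runif(1) < 0.4; s2 <- runif(1) < 0.4
    d1 <- rnorm(1, 0.2, 0.3); d2 <- rnorm(1, 0.2, 0.3)
    rows1[[paste(tr, fe)]] <- effect_row(tr, fe, s1,
      ifelse(d1 > 0, "male_higher", "female_higher"), d1)
    rows2[[paste(tr, fe)]] <- effect_row(tr, fe, s2,
      ifelse(d2 > 0, "male_higher", "female_higher"), d2)
  }
  rec <- classify_concordance(dplyr::bind_rows(rows1), dplyr::bind_rows(rows2))
  s <- summarize_concordance(rec)
  expect_equal(s$n_total, 90)
  cats <- s$categories
  for (st in unique(cats$stratum)) {
    expect_equal(sum(cats$n[cats$stratum == st]),
                 cats$stratum_n[cats$stratum == st][1])
  }
  comp <- s$composites
  expect_equal(comp$stratum_n[comp$stratum == "microstructural"][1], 70)
  expect_equal(comp$stratum_n[comp$stratum == "volumetric"][1], 20)
  # percentages recompute from counts under the declared rounding
  expect_equal(comp$pct,
               percentage(comp$n, comp$stratum_n, digits = 1))
  expect_equal(s$d_overlap, sum(rec$base_category == "D"))
})

test_that("relaxing the threshold cannot shrink the both-significant category", {
  coh <- generate_cohort(sim_config(n_male = 120, n_female = 120,
                                    tracts = tract_registry()$abbreviation[1:6],
                                    features = c("FA", "MD", "NDI"),
                                    seed = 17))
  count_A <- function(thr) {
    e1 <- run_effects(coh$pipeline1, significance_policy(override_threshold = thr))
    e2 <- run_effects(coh$pipeline2, significance_policy(override_threshold = thr))
    sum(classify_concordance(e1, e2)$base_category == "A")
  }
  expect_gte(count_A(0.05), count_A(6.5e-5))
})

test_that("rounding conventions are honored in percentages", {
  expect_equal(percentage(1, 8, digits = 1), 12.5)
  expect_equal(percentage(1, 8, digits = 0), 13)           # half up, not to even
  expect_equal(percentage(1, 8, digits = 0, method = "truncate"), 12)
  expect_equal(percentage(5, 1000, digits = 1), 0.5)
})
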