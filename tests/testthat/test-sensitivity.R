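test_that("identical pipelines give a zero difference and 'neither'", {
  coh <- pair_cohort(d1 = 0.4, d2 = 0.4, rho = 1, seed = 51)
  r <- bootstrap_sensitivity(coh$pipeline1, coh$pipeline2, "CA", "FA",
                             n_boot = 1000, seed = 1)
  expect_equal(r$delta_hat, 0, tolerance = 1e-12)
  expect_lte(r$ci_low, 0)
  expect_gte(r$ci_high, 0)
  expect_equal(r$more_sensitive, "neither")
})

test_that("same call and seed reproduce bit-identical intervals", {
  coh <- pair_cohort(d1 = 0.5, d2 = 0.2, seed = 52)
  r1 <- bootstrap_sensitivity(coh$pipeline1, coh$pipeline2, "CA", "FA",
                              n_boot = 1000, seed = 9)
  r2 <- bootstrap_sensitivity(coh$pipeline1, coh$pipeline2, "CA", "FA",
                              n_boot = 1000, seed = 9)
  expect_identical(r1, r2)
  r3 <- bootstrap_sensitivity(coh$pipeline1, coh$pipeline2, "CA", "FA",
                              n_boot = 1000, seed = 10)
  expect_false(identical(r1$ci_low, r3$ci_low))
})

test_that("a clearly more sensitive pipeline is flagged at cohort scale", {
  coh <- pair_cohort(d1 = 0.6, d2 = 0.0, n_male = 490, n_female = 575,
                     seed = 53)
  r <- bootstrap_sensitivity(coh$pipeline1, coh$pipeline2, "CA", "FA",
                             n_boot = 1500, seed = 2)
  expect_equal(r$more_sensitive, "method1")
  expect_gt(r$ci_low, 0)
})

test_that("vectorized bootstrap agrees with a plain-loop implementation", {
  coh <- pair_cohort(d1 = 0.5, d2 = 0.25, n_male = 150, n_female = 180,
                     seed = 54)
  a <- coh$pipeline1; b <- coh$pipeline2
  r <- bootstrap_sensitivity(a, b, "CA", "FA", n_boot = 4000, seed = 3)
  naive <- naive_boot_ci(a$value, b$value, a$sex == "male",
                         n_boot = 4000, seed = 99)
  # independent resampling streams: agreement within Monte-Carlo error
  expect_lt(abs(r$ci_low - naive[1]), 0.03)
  expect_lt(abs(r$ci_high - naive[2]), 0.03)
})

test_that("degenerate resamples are redrawn and counted", {
  df <- data.frame(
    subject_id = paste0("s", 1:8),
    sex = rep(c("male", "female"), each = 4),
    tract = "CA", feature = "FA",
    value = c(0, 0, 0, 1, 0, 0, 0, 0))
  a <- tract_feature_table(df, "p1")
  b <- tract_feature_table(transform(df, value = value + c(rep(0, 7), 1)), "p2")
  r <- bootstrap_sensitivity(a, b, "CA", "FA", n_boot = 300, seed = 4,
                             max_redraw = 1000)
  expect_gt(r$n_redrawn, 0)
  expect_true(all(is.finite(c(r$ci_low, r$ci_high))))
})

test_that("unaligned tables are rejected", {
  coh <- pair_cohort(d1 = 0.3, d2 = 0.3, n_male = 20, n_female = 20, seed = 55)
  b <- coh$pipeline2[coh$pipeline2$subject_id != "sub-0001", ]
  b <- tract_feature_table(b, "p2", tracts = NULL, features = NULL)
  expect_error(bootstrap_sensitivity(coh$pipeline1, b, "CA", "FA",
                                     n_boot = 100, seed = 1),
               "not aligned")
})

test_that("breaking the subject pairing widens the interval when rho > 0", {
  coh <- pair_cohort(d1 = 0.4, d2 = 0.4, n_male = 400, n_female = 400,
                     rho = 0.9, seed = 56)
  a <- coh$pipeline1
  b <- coh$pipeline2
  ci_len <- function(x, y, seed) {
    r <- bootstrap_sensitivity(x, y, "CA", "FA", n_boot = 1500, seed = seed)
    r$ci_high - r$ci_low
  }
  paired <- mean(vapply(1:3, function(s) ci_len(a, b, s), numeric(1)))
  # permute pipeline-2 values within sex: same marginals, pairing destroyed
  b_shuf <- tibble::as_tibble(b)
  set.seed(57)
  for (s in c("male", "female")) {
    i <- which(b_shuf$sex == s)
    b_shuf$value[i] <- b_shuf$value[sample(i)]
  }
  b_shuf <- tract_feature_table(b_shuf, "p2", tracts = NULL, features = NULL)
  broken <- mean(vapply(1:3, function(s) ci_len(a, b_shuf, s), numeric(1)))
  expect_gt(broken, paired)
})

test_that("run_sensitivity covers every pair with order-independent streams", {
  coh <- generate_cohort(sim_config(n_male = 60, n_female = 60,
                                    tracts = c("CA", "MCP"),
                                    features = c("FA", "volume"), seed = 58))
  r <- run_sensitivity(coh$pipeline1, coh$pipeline2, n_boot = 400, seed = 6)
  expect_equal(nrow(r), 4)
  # restricting to a subset reproduces the same per-pair results
  sub <- run_sensitivity(coh$pipeline1, coh$pipeline2, n_boot = 400, seed = 6,
                         pairs = tibble::tibble(tract = "MCP", feature = "FA"))
  expect_identical(sub, r[r$tract == "MCP" & r$feature == "FA", ])
})

test_that("sensitivity tallies add up per feature, stratum and method", {
  tracts <- tract_registry()$abbreviation
  res <- tidyr::expand_grid(tract = tracts,
                            feature = feature_registry()$feature)
  res$more_sensitive <- "neither"
  # 48 non-NDI microstructural pairs for method2, NDI alone contributing 35
  non_ndi <- which(res$feature %in% c("FA", "MD", "AD", "RD", "ODI", "ISOWF"))
  res$more_sensitive[non_ndi[1:48]] <- "method2"
  res$more_sensitive[which(res$feature == "NDI")[1:35]] <- "method2"
  res$more_sensitive[which(res$feature == "FA")[45:49]] <- "method1"
  tal <- tally_sensitivity(res)
  tot <- tal$totals
  expect_equal(tot$n_method2[tot$stratum == "overall"], 83)
  expect_equal(tot$n_method1[tot$stratum == "overall"], 5)
  expect_equal(tot$n_method2[tot$stratum == "microstructural"], 83)
  expect_equal(tot$n_method2[tot$stratum == "volumetric"], 0)
  expect_equal(sum(tal$per_feature$n_method2), 83)
  expect_equal(tal$per_feature$n_method2[tal$per_feature$feature == "NDI"], 35)
})
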