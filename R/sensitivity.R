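# Bootstrap comparison of effect-size magnitude between pipelines.

# Column-wise Cohen's d over a bootstrap index matrix, groups resampled
# separately (stratified design). Returns NA for degenerate columns.
boot_d_stratified <- function(xm, xf, idx_m, idx_f) {
  nm <- nrow(idx_m); nf <- nrow(idx_f)
  Xm <- matrix(xm[idx_m], nm); Xf <- matrix(xf[idx_f], nf)
  m1 <- colMeans(Xm); m2 <- colMeans(Xf)
  v1 <- (colMeans(Xm * Xm) - m1 * m1) * nm / (nm - 1)
  v2 <- (colMeans(Xf * Xf) - m2 * m2) * nf / (nf - 1)
  sp2 <- ((nm - 1) * v1 + (nf - 1) * v2) / (nm + nf - 2)
  d <- (m1 - m2) / sqrt(sp2)
  d[!is.finite(d)] <- NA_real_
  d
}

# Unstratified variant: subjects resampled from the whole cohort, so group
# sizes vary per replicate. `male` is the 0/1 indicator aligned with x.
boot_d_unstratified <- function(x, male, idx) {
  n <- nrow(idx)
  X <- matrix(x[idx], n)
  G <- matrix(male[idx], n)
  nm <- colSums(G); nf <- n - nm
  s1 <- colSums(X * G); s2 <- colSums(X) - s1
  m1 <- s1 / nm; m2 <- s2 / nf
  q1 <- colSums(X * X * G); q2 <- colSums(X * X) - q1
  v1 <- (q1 - nm * m1 * m1) / (nm - 1)
  v2 <- (q2 - nf * m2 * m2) / (nf - 1)
  sp2 <- ((nm - 1) * v1 + (nf - 1) * v2) / (nm + nf - 2)
  d <- (m1 - m2) / sqrt(sp2)
  d[!is.finite(d) | nm < 2 | nf < 2] <- NA_real_
  d
}

#' Bootstrap the cross-pipeline difference in effect-size magnitude
#'
#' For one tract-feature pair, resamples subjects with replacement —
#' stratified by sex so the design's group sizes are preserved, and carrying
#' each resampled subject's measurement from *both* pipelines so the
#' within-subject pairing survives resampling — recomputes Cohen's d in each
#' pipeline per replicate, and returns the 95% percentile confidence interval
#' (empirical 2.5% and 97.5% quantiles, linear interpolation, `type = 7`) of
#' `|d1| - |d2|`. Pipeline 1 is called significantly more sensitive when the
#' interval lies entirely above zero, pipeline 2 when entirely below.
#'
#' Replicates whose resample is degenerate (zero pooled variance, or a group
#' smaller than 2 in the unstratified variant) are redrawn, up to
#' `max_redraw` rounds; the number redrawn is reported.
#'
#' @param a,b Aligned [tract_feature_table()] objects (same subjects; see
#'   [align_cohorts()]).
#' @param tract,feature The pair to analyze.
#' @param n_boot Bootstrap iterations (default 10000).
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   results.
#' @param stratified Resample within sex (default `TRUE`).
#' @param statistic `"magnitude"` (default, `|d1| - |d2|`) or `"signed"`
#'   (`d1 - d2`).
#' @param max_redraw Cap on redraw rounds for degenerate replicates.
#' @return One-row tibble: keys, effective `n_male`/`n_female`, point
#'   estimate `delta_hat`, `ci_low`, `ci_high`, `n_boot`, `n_redrawn`, and
#'   `more_sensitive` (`"method1"`, `"method2"` or `"neither"`).
#' @export
bootstrap_sensitivity <- function(a, b, tract, feature,
                                  n_boot = 10000, seed = 1L,
                                  stratified = TRUE,
                                  statistic = c("magnitude", "signed"),
                                  max_redraw = 100L) {
  statistic <- match.arg(statistic)
  stopifnot(n_boot >= 1)
  pair <- extract_pair(a, b, tract, feature)
  with_seed(as.integer(seed), {
    boot_pair(pair, tract, feature, n_boot, stratified, statistic, max_redraw)
  })
}

# Pull the paired per-subject vectors for one tract-feature pair, dropping
# subjects missing in either pipeline for this pair.
extract_pair <- function(a, b, tract, feature) {
  stopifnot(inherits(a, "tract_feature_table"),
            inherits(b, "tract_feature_table"))
  ra <- a[a$tract == tract & a$feature == feature, ]
  rb <- b[b$tract == tract & b$feature == feature, ]
  if (nrow(ra) == 0 || nrow(rb) == 0) {
    abort(paste0("no measurements for (", tract, ", ", feature, ")"))
  }
  common <- intersect(ra$subject_id, rb$subject_id)
  if (!setequal(a$subject_id, b$subject_id)) {
    abort("tables are not aligned: subject rosters differ (see align_cohorts)")
  }
  ra <- ra[match(common, ra$subject_id), ]
  rb <- rb[match(common, rb$subject_id), ]
  if (!identical(ra$sex, rb$sex)) {
    abort("tables are not aligned: sex labels differ between pipelines")
  }
  male <- ra$sex == "male"
  if (sum(male) < 2 || sum(!male) < 2) {
    abort("each sex needs at least 2 subjects with paired measurements")
  }
  list(x1 = ra$value, x2 = rb$value, male = male)
}

boot_pair <- function(pair, tract, feature, n_boot, stratified, statistic,
                      max_redraw) {
  male <- pair$male
  nm <- sum(male); nf <- sum(!male); n <- nm + nf
  xm1 <- pair$x1[male]; xf1 <- pair$x1[!male]
  xm2 <- pair$x2[male]; xf2 <- pair$x2[!male]

  stat <- function(d1, d2) {
    if (statistic == "magnitude") abs(d1) - abs(d2) else d1 - d2
  }
  delta_hat <- stat(cohens_d(xm1, xf1), cohens_d(xm2, xf2))

  draw <- function(B) {
    if (stratified) {
      idx_m <- matrix(sample.int(nm, nm * B, replace = TRUE), nm)
      idx_f <- matrix(sample.int(nf, nf * B, replace = TRUE), nf)
      d1 <- boot_d_stratified(xm1, xf1, idx_m, idx_f)
      d2 <- boot_d_stratified(xm2, xf2, idx_m, idx_f)
    } else {
      idx <- matrix(sample.int(n, n * B, replace = TRUE), n)
      mi <- as.numeric(male)
      d1 <- boot_d_unstratified(pair$x1, mi, idx)
      d2 <- boot_d_unstratified(pair$x2, mi, idx)
    }
    stat(d1, d2)
  }

  delta <- draw(n_boot)
  n_redrawn <- 0L
  round_i <- 0L
  while (anyNA(delta)) {
    round_i <- round_i + 1L
    if (round_i > max_redraw) {
      abort("too many degenerate bootstrap replicates; data nearly constant")
    }
    bad <- which(is.na(delta))
    n_redrawn <- n_redrawn + length(bad)
    delta[bad] <- draw(length(bad))
  }

  ci <- quantile(delta, c(0.025, 0.975), type = 7, names = FALSE)
  tibble::tibble(
    tract = tract, feature = feature,
    n_male = nm, n_female = nf,
    delta_hat = delta_hat, ci_low = ci[1], ci_high = ci[2],
    n_boot = as.integer(n_boot), n_redrawn = n_redrawn,
    more_sensitive = if (ci[1] > 0) "method1"
                     else if (ci[2] < 0) "method2" else "neither"
  )
}

#' Bootstrap sensitivity for every shared tract-feature pair
#'
#' Runs [bootstrap_sensitivity()] over all (tract, feature) pairs present in
#' both tables. Each pair draws from its own deterministic substream of
#' `seed`, so results do not depend on pair order and adding a pair leaves
#' the others unchanged.
#'
#' @inheritParams bootstrap_sensitivity
#' @param pairs Optional tibble with columns `tract`, `feature` restricting
#'   which pairs to run.
#' @return A tibble with one row per pair (see [bootstrap_sensitivity()]).
#' @export
run_sensitivity <- function(a, b, n_boot = 10000, seed = 1L,
                            pairs = NULL, stratified = TRUE,
                            statistic = c("magnitude", "signed"),
                            max_redraw = 100L) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(a, "tract_feature_table"),
            inherits(b, "tract_feature_table"))
  if (!setequal(a$subject_id, b$subject_id)) {
    abort("tables are not aligned: subject rosters differ (see align_cohorts)")
  }
  ta <- tibble::as_tibble(a)
  tb <- tibble::as_tibble(b)
  ka <- split(seq_len(nrow(ta)), paste(ta$tract, ta$feature, sep = "\r"))
  kb <- split(seq_len(nrow(tb)), paste(tb$tract, tb$feature, sep = "\r"))
  if (is.null(pairs)) {
    keys <- intersect(names(ka), names(kb))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    pairs <- tibble::tibble(tract = vapply(parts, `[`, "", 1),
                            feature = vapply(parts, `[`, "", 2))
    pairs <- dplyr::arrange(pairs, .data$tract, .data$feature)
  }
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    key <- paste(pairs$tract[i], pairs$feature[i], sep = "\r")
    ra <- ta[ka[[key]], ]
    rb <- tb[kb[[key]], ]
    common <- intersect(ra$subject_id, rb$subject_id)
    ra <- ra[match(common, ra$subject_id), ]
    rb <- rb[match(common, rb$subject_id), ]
    if (!identical(ra$sex, rb$sex)) {
      abort("tables are not aligned: sex labels differ between pipelines")
    }
    pair <- list(x1 = ra$value, x2 = rb$value, male = ra$sex == "male")
    res[[i]] <- with_seed(
      substream_seed(seed, "sensitivity", pairs$tract[i], pairs$feature[i]),
      boot_pair(pair, pairs$tract[i], pairs$feature[i], n_boot,
                stratified, statistic, max_redraw))
  }
  dplyr::bind_rows(res)
}

#' Tally which pipeline is more sensitive, per feature and overall
#'
#' Counts, for each feature and in total, the tract-feature pairs whose
#' bootstrap interval flags each pipeline as significantly more sensitive,
#' plus totals within the microstructural and volumetric strata.
#'
#' @param results Tibble of [run_sensitivity()] /
#'   [bootstrap_sensitivity()] rows, one per tract-feature pair.
#' @param registry Feature registry supplying `feature_class`.
#' @return A list of class `sensitivity_tally`: `per_feature` (feature,
#'   feature_class, `n_method1`, `n_method2`) and `totals` (one row per
#'   stratum: overall, microstructural, volumetric).
#' @export
tally_sensitivity <- function(results, registry = feature_registry()) {
  if (anyDuplicated(paste(results$tract, results$feature, sep = "\r"))) {
    abort("duplicate (tract, feature) keys in sensitivity results")
  }
  r <- dplyr::left_join(tibble::as_tibble(results), registry, by = "feature")
  per_feature <- r |>
    dplyr::group_by(.data$feature, .data$feature_class) |>
    dplyr::summarise(
      n_method1 = sum(.data$more_sensitive == "method1"),
      n_method2 = sum(.data$more_sensitive == "method2"),
      .groups = "drop")
  strata <- list(overall = r,
                 microstructural = r[which(r$feature_class == "microstructural"), ],
                 volumetric = r[which(r$feature_class == "volumetric"), ])
  totals <- dplyr::bind_rows(lapply(names(strata), function(s) {
    rs <- strata[[s]]
    tibble::tibble(stratum = s,
                   n_method1 = sum(rs$more_sensitive == "method1"),
                   n_method2 = sum(rs$more_sensitive == "method2"))
  }))
  structure(list(per_feature = per_feature, totals = totals),
            class = "sensitivity_tally")
}

#' @export
print.sensitivity_tally <- function(x, ...) {
  cat("<sensitivity_tally>\n")
  print(x$totals)
  invisible(x)
}
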