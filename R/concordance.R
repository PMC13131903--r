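# Agreement taxonomy between two pipelines' effect results.

CATEGORY_LEVELS <- c("A", "B", "C", "D", "E", "F")
CATEGORY_LABELS <- c(
  A = "both significant, same direction",
  B = "one significant, same direction",
  C = "neither significant, same direction",
  D = "neither significant, opposite direction",
  E = "one significant, opposite direction",
  F = "both significant, opposite direction"
)

#' The six base agreement categories
#'
#' @return A tibble mapping category codes A-F to their definitions on the
#'   (significance count) x (direction agreement) lattice.
#' @export
concordance_categories <- function() {
  tibble::tibble(category = CATEGORY_LEVELS,
                 definition = unname(CATEGORY_LABELS))
}

#' Classify cross-pipeline agreement per tract-feature pair
#'
#' Joins two pipelines' effect tables on (tract, feature) and assigns each
#' pair one of six exhaustive base categories from how many results are
#' significant (both / one / neither) and whether the effect directions
#' agree. Four composite levels are defined on top:
#'
#' * strict agreement — both significant in the same direction, or neither
#'   significant (A, C, D);
#' * soft agreement — same direction regardless of significance, plus
#'   neither-significant pairs (A, B, C, D by default; variant
#'   `"directional_only"` drops D);
#' * strict disagreement — both significant, opposite directions (F);
#' * soft disagreement — any opposite directionality regardless of
#'   significance (D, E, F).
#'
#' Strict agreement and soft disagreement overlap in category D
#' (neither-significant, opposite direction): such pairs count as strict
#' agreement (neither pipeline found an effect) *and* as soft disagreement
#' (the point directions differ). The overlap is deliberate and reported by
#' [summarize_concordance()], which is why soft agreement and soft
#' disagreement percentages can sum above 100.
#'
#' A direction of `"none"` (d exactly 0) is treated as compatible with either
#' direction — the pair is classified as same-direction — and the number of
#' such pairs is recorded in attribute `n_direction_none`.
#'
#' @param effects1,effects2 Outputs of [run_effects()] for the two pipelines,
#'   covering the same tract-feature pairs.
#' @param soft_agreement `"with_null_pairs"` (default, includes D) or
#'   `"directional_only"` (A, B, C).
#' @param registry Feature registry supplying `feature_class`.
#' @return A tibble with one row per pair: keys, `feature_class`, per-pipeline
#'   `significant`/`direction`/`d`, `base_category`, and the four composite
#'   logical columns.
#' @export
classify_concordance <- function(effects1, effects2,
                                 soft_agreement = c("with_null_pairs",
                                                    "directional_only"),
                                 registry = feature_registry()) {
  soft_agreement <- match.arg(soft_agreement)
  for (e in list(effects1, effects2)) {
    if (anyDuplicated(paste(e$tract, e$feature, sep = "\r"))) {
      abort("duplicate (tract, feature) keys in an effects table")
    }
  }
  if (nrow(effects1) != nrow(effects2)) {
    abort("effects tables cover different numbers of tract-feature pairs")
  }
  keep <- c("tract", "feature", "significant", "direction", "d", "p_value")
  j <- dplyr::inner_join(effects1[keep], effects2[keep],
                         by = c("tract", "feature"),
                         suffix = c("_1", "_2"))
  if (nrow(j) != nrow(effects1)) {
    abort("effects tables cover different (tract, feature) pairs")
  }

  n_sig <- j$significant_1 + j$significant_2
  none1 <- j$direction_1 == "none"
  none2 <- j$direction_2 == "none"
  same_dir <- none1 | none2 | (j$direction_1 == j$direction_2)

  base <- dplyr::case_when(
    n_sig == 2 & same_dir ~ "A",
    n_sig == 1 & same_dir ~ "B",
    n_sig == 0 & same_dir ~ "C",
    n_sig == 0 & !same_dir ~ "D",
    n_sig == 1 & !same_dir ~ "E",
    n_sig == 2 & !same_dir ~ "F"
  )
  j$base_category <- factor(base, levels = CATEGORY_LEVELS)
  j$strict_agreement <- base %in% c("A", "C", "D")
  j$soft_agreement <- base %in%
    (if (soft_agreement == "with_null_pairs") c("A", "B", "C", "D")
     else c("A", "B", "C"))
  j$strict_disagreement <- base == "F"
  j$soft_disagreement <- base %in% c("D", "E", "F")

  j <- dplyr::left_join(j, registry, by = "feature")
  j <- dplyr::relocate(j, "feature_class", .after = "feature")
  attr(j, "soft_agreement_variant") <- soft_agreement
  attr(j, "n_direction_none") <- sum(none1 | none2)
  j
}

#' Summarize agreement counts and percentages
#'
#' Aggregates a classification from [classify_concordance()] into counts per
#' base category and per composite level, overall and within each feature
#' class (microstructural / volumetric). The base categories are asserted to
#' partition the records on every call. Percentages are
#' `100 * count / stratum size` at a configurable precision and rounding
#' convention (see [percentage()]).
#'
#' @param records Output of [classify_concordance()].
#' @param digits Decimal digits for percentages (default 1).
#' @param rounding `"half_up"` (default) or `"truncate"`.
#' @return A list of class `concordance_summary`: `n_total`, `categories`
#'   (stratum x category counts), `composites` (stratum x composite count and
#'   percentage), `d_overlap` (number of category-D records, the documented
#'   strict-agreement / soft-disagreement overlap), `n_direction_none`, and
#'   the rounding settings.
#' @export
summarize_concordance <- function(records, digits = 1,
                                  rounding = c("half_up", "truncate")) {
  rounding <- match.arg(rounding)
  if (nrow(records) == 0) abort("no records to summarize")
  if (anyDuplicated(paste(records$tract, records$feature, sep = "\r"))) {
    abort("duplicate (tract, feature) keys")
  }

  strata <- c("overall", sort(unique(records$feature_class)))
  stratum_rows <- function(s) {
    if (s == "overall") records else records[records$feature_class == s, ]
  }

  categories <- dplyr::bind_rows(lapply(strata, function(s) {
    r <- stratum_rows(s)
    tab <- table(r$base_category)
    tibble::tibble(stratum = s, category = names(tab),
                   n = as.integer(tab), stratum_n = nrow(r))
  }))
  # partition check: the six categories exhaust every record
  for (s in strata) {
    cs <- categories[categories$stratum == s, ]
    if (sum(cs$n) != cs$stratum_n[1]) {
      abort("base categories failed to partition the records")
    }
  }

  composite_cols <- c("strict_agreement", "soft_agreement",
                      "strict_disagreement", "soft_disagreement")
  composites <- dplyr::bind_rows(lapply(strata, function(s) {
    r <- stratum_rows(s)
    tibble::tibble(
      stratum = s, composite = composite_cols,
      n = vapply(composite_cols, function(cc) sum(r[[cc]]), integer(1)),
      stratum_n = nrow(r),
      pct = percentage(vapply(composite_cols, function(cc) sum(r[[cc]]),
                              integer(1)),
                       nrow(r), digits = digits, method = rounding)
    )
  }))

  structure(list(
    n_total = nrow(records),
    categories = categories,
    composites = composites,
    d_overlap = sum(records$base_category == "D"),
    n_direction_none = attr(records, "n_direction_none") %||% 0L,
    soft_agreement_variant = attr(records, "soft_agreement_variant"),
    digits = digits, rounding = rounding
  ), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("<concordance_summary>", x$n_total, "tract-feature pairs\n")
  ov <- x$composites[x$composites$stratum == "overall", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-20s %4d  (%s%%)\n", ov$composite[i], ov$n[i],
                format(ov$pct[i])))
  }
  cat("  category-D overlap (strict agreement & soft disagreement):",
      x$d_overlap, "\n")
  invisible(x)
}
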