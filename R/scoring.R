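# MRIx scoring: four margin-biology domains, each graded 0 (low risk),
# 1 (intermediate) or 2 (high risk), combined as a weighted composite.

#' Default MRIx scoring configuration
#'
#' Weights, category cut points and the close-margin override used to turn
#' the four domain scores into the composite Margin Risk Index (MRIx).
#'
#' The composite is `0.30 * histopathology + 0.25 * tumor_burden +
#' 0.25 * molecular + 0.20 * immune`, a multiple of 0.05 in `[0, 2]`.
#' Categories are assigned after rounding the composite half-up to one
#' decimal: low `<= 0.8`, intermediate `0.9-1.4`, high `>= 1.5`. A resection
#' margin of `<= override_margin_mm` (2 mm) forces the high-risk category
#' regardless of the numeric score.
#'
#' @param weights Named numeric vector of domain weights
#'   (`histopathology`, `tumor_burden`, `molecular`, `immune`); must sum to 1.
#' @param low_max Upper bound (inclusive, after rounding) of the low category.
#' @param intermediate_max Upper bound (inclusive, after rounding) of the
#'   intermediate category.
#' @param override_margin_mm Margin distance (mm) at or below which the
#'   category is forced to high.
#' @return A list of class `mrix_scoring_config`.
#' @export
#' @examples
#' cfg <- mrix_scoring_config()
#' compute_mrix(c(2, 1, 1, 1), margin_mm = 8, config = cfg)
mrix_scoring_config <- function(weights = c(histopathology = 0.30,
                                            tumor_burden = 0.25,
                                            molecular = 0.25,
                                            immune = 0.20),
                                low_max = 0.8,
                                intermediate_max = 1.4,
                                override_margin_mm = 2.0) {
  domains <- c("histopathology", "tumor_burden", "molecular", "immune")
  if (!all(domains %in% names(weights))) {
    stop("weights must be named for the four domains: ",
         paste(domains, collapse = ", "))
  }
  weights <- weights[domains]
  if (abs(sum(weights) - 1) > 1e-12) stop("domain weights must sum to 1")
  if (!(low_max < intermediate_max)) stop("category cuts must be ordered")
  structure(list(weights = weights,
                 low_max = low_max,
                 intermediate_max = intermediate_max,
                 override_margin_mm = override_margin_mm),
            class = "mrix_scoring_config")
}

# negative values are errors; NA propagates (complete-case handling happens
# at model-fitting time)
.check_nonneg <- function(x, what) {
  if (any(x < 0, na.rm = TRUE)) stop(what, " must be non-negative")
  invisible(x)
}

#' Score the histopathologic domain (TLS density)
#'
#' Tertiary lymphoid structure density at the margin: `>= 3 /mm^2` scores 0
#' (robust TLS response), `[1, 3)` scores 1, `< 1 /mm^2` scores 2.
#'
#' @param tls_density TLS per mm^2, non-negative numeric vector.
#' @return Integer vector of domain scores in `{0, 1, 2}`.
#' @export
score_histopathology <- function(tls_density) {
  .check_nonneg(tls_density, "tls_density")
  ifelse(tls_density >= 3, 0L, ifelse(tls_density >= 1, 1L, 2L))
}

.level_panck <- function(panck_foci) {
  .check_nonneg(panck_foci, "panck_foci")
  ifelse(panck_foci == 0, 0L, ifelse(panck_foci < 5, 1L, 2L))
}

.level_ki67 <- function(ki67_pct) {
  .check_nonneg(ki67_pct, "ki67_pct")
  if (any(ki67_pct > 100, na.rm = TRUE)) stop("ki67_pct must be a percentage in [0, 100]")
  ifelse(ki67_pct < 5, 0L, ifelse(ki67_pct <= 20, 1L, 2L))
}

#' Score the tumor-burden domain (Pan-CK foci and Ki-67)
#'
#' Sub-criteria: Pan-CK+ foci per mm^2 (0 detectable -> level 0, `(0, 5)` ->
#' level 1, `>= 5` -> level 2) and Ki-67 index (`< 5%` -> 0, `5-20%` -> 1,
#' `> 20%` -> 2). The domain score is the worse (maximum) of the two levels,
#' a risk-conservative resolution of discordant sub-criteria.
#'
#' @param panck_foci Pan-CK+ foci per mm^2 (non-negative).
#' @param ki67_pct Ki-67 proliferation index, percent in `[0, 100]`.
#' @return Integer vector of domain scores in `{0, 1, 2}`.
#' @export
score_tumor_burden <- function(panck_foci, ki67_pct) {
  pmax(.level_panck(panck_foci), .level_ki67(ki67_pct))
}

.level_mutations <- function(n_driver_mutations) {
  .check_nonneg(n_driver_mutations, "n_driver_mutations")
  if (any(n_driver_mutations != round(n_driver_mutations), na.rm = TRUE)) {
    stop("n_driver_mutations must be a non-negative integer count")
  }
  ifelse(n_driver_mutations == 0, 0L, ifelse(n_driver_mutations == 1, 1L, 2L))
}

.level_pdl1 <- function(pdl1_fold) {
  .check_nonneg(pdl1_fold, "pdl1_fold")
  ifelse(pdl1_fold < 1, 0L, ifelse(pdl1_fold <= 2, 1L, 2L))
}

#' Score the molecular-MRD domain (driver mutations and PD-L1 RNA)
#'
#' Sub-criteria: driver mutation count on the TP53/NOTCH1 panel (0 -> level 0,
#' 1 -> level 1, `>= 2` -> level 2) and PD-L1 RNA fold-change versus normal
#' mucosa (`< 1` -> 0, `[1, 2]` -> 1, `> 2` -> 2); domain score is the
#' maximum of the two levels.
#'
#' @param n_driver_mutations Non-negative integer count of driver mutations.
#' @param pdl1_fold PD-L1 RNA fold-change versus normal mucosa (non-negative).
#' @return Integer vector of domain scores in `{0, 1, 2}`.
#' @export
score_molecular <- function(n_driver_mutations, pdl1_fold) {
  pmax(.level_mutations(n_driver_mutations), .level_pdl1(pdl1_fold))
}

.level_ratio <- function(cd8_foxp3_ratio) {
  # ratio may be Inf (CD8 present, FoxP3 absent -> favorable) or NaN
  # (both absent -> no cytotoxic infiltrate, worst level)
  if (any(cd8_foxp3_ratio < 0, na.rm = TRUE)) {
    stop("cd8_foxp3_ratio must be non-negative")
  }
  out <- ifelse(cd8_foxp3_ratio >= 2, 0L,
                ifelse(cd8_foxp3_ratio >= 1, 1L, 2L))
  out[is.nan(cd8_foxp3_ratio)] <- 2L
  out
}

.level_gzmb <- function(gzmb_density) {
  .check_nonneg(gzmb_density, "gzmb_density")
  ifelse(gzmb_density > 200, 0L, ifelse(gzmb_density >= 50, 1L, 2L))
}

#' Score the immune-contexture domain (CD8+/FoxP3+ ratio and Granzyme B)
#'
#' Sub-criteria: CD8+/FoxP3+ ratio (`>= 2` -> level 0, `[1, 2)` -> level 1,
#' `< 1` -> level 2; `Inf` maps to level 0, `NaN` from 0/0 to level 2) and
#' Granzyme B+ density (`> 200 /mm^2` -> 0, `[50, 200]` -> 1, `< 50` -> 2);
#' domain score is the maximum of the two levels.
#'
#' @param cd8_foxp3_ratio Cytotoxic-to-regulatory T-cell ratio (may be `Inf`
#'   or `NaN`).
#' @param gzmb_density Granzyme B+ cells per mm^2 (non-negative).
#' @return Integer vector of domain scores in `{0, 1, 2}`.
#' @export
score_immune <- function(cd8_foxp3_ratio, gzmb_density) {
  pmax(.level_ratio(cd8_foxp3_ratio), .level_gzmb(gzmb_density))
}

#' Compute the composite MRIx score and risk category
#'
#' @param domain_scores Numeric vector or matrix (rows = patients) of the four
#'   domain scores in the order histopathology, tumor burden, molecular,
#'   immune; each in `{0, 1, 2}`.
#' @param margin_mm Resection margin distance in mm (recycled to rows).
#' @param config A [mrix_scoring_config()].
#' @return A data frame with columns `mrix_score` (exact weighted sum,
#'   a multiple of 0.05 under the default weights), `mrix_category`
#'   (`"low"`, `"intermediate"`, `"high"`) and `override_applied` (logical;
#'   `TRUE` when `margin_mm <= 2` forced the high category).
#' @export
#' @examples
#' compute_mrix(c(2, 1, 1, 1), margin_mm = 8)   # 1.30, intermediate
#' compute_mrix(c(0, 0, 0, 0), margin_mm = 1.5) # 0.00 but high via override
compute_mrix <- function(domain_scores, margin_mm,
                         config = mrix_scoring_config()) {
  s <- if (is.matrix(domain_scores) || is.data.frame(domain_scores)) {
    as.matrix(domain_scores)
  } else {
    matrix(domain_scores, nrow = 1)
  }
  if (ncol(s) != 4) stop("domain_scores must have four columns/elements")
  if (any(!(s %in% c(0:2, NA)))) stop("domain scores must be 0, 1 or 2")
  if (any(margin_mm < 0, na.rm = TRUE)) stop("margin_mm must be non-negative")
  margin_mm <- rep_len(margin_mm, nrow(s))
  # integer arithmetic keeps the composite an exact multiple of 0.05
  score <- as.numeric(s %*% round(config$weights * 100)) / 100
  rounded <- round_half_up(score, 1)
  category <- ifelse(rounded <= config$low_max, "low",
                     ifelse(rounded <= config$intermediate_max,
                            "intermediate", "high"))
  # a missing margin distance cannot trigger the override
  override <- !is.na(margin_mm) & margin_mm <= config$override_margin_mm
  category[override] <- "high"
  data.frame(mrix_score = score,
             mrix_category = factor(category, levels = mrix_levels()),
             override_applied = override)
}

#' MRIx category levels, in increasing risk order
#' @return `c("low", "intermediate", "high")`
#' @export
mrix_levels <- function() c("low", "intermediate", "high")

#' Enumerate all 81 domain-score combinations
#'
#' All assignments of `{0, 1, 2}` to the four domains with the resulting
#' composite score and (override-free) category; used for exhaustive checks
#' of the scoring rubric.
#'
#' @param config A [mrix_scoring_config()].
#' @return Data frame with 81 rows: the four domain scores, `mrix_score` and
#'   `mrix_category`.
#' @export
enumerate_mrix_combinations <- function(config = mrix_scoring_config()) {
  grid <- expand.grid(histopathology_score = 0:2, tumor_burden_score = 0:2,
                      molecular_score = 0:2, immune_score = 0:2,
                      KEEP.OUT.ATTRS = FALSE)
  res <- compute_mrix(as.matrix(grid), margin_mm = 100, config = config)
  cbind(grid, res[c("mrix_score", "mrix_category")])
}

#' Score a whole cohort table
#'
#' Applies the four domain scorers and [compute_mrix()] row-wise, appending
#' `histopathology_score`, `tumor_burden_score`, `molecular_score`,
#' `immune_score`, `mrix_score`, `mrix_category` and `override_applied`
#' columns. Existing columns are left untouched (score columns already
#' present are recomputed).
#'
#' @param cohort Data frame with the raw biomarker columns `tls_density`,
#'   `panck_foci`, `ki67_pct`, `n_driver_mutations`, `pdl1_fold`,
#'   `cd8_foxp3_ratio`, `gzmb_density`, `margin_mm`.
#' @param config A [mrix_scoring_config()].
#' @return The cohort with the seven derived columns appended.
#' @export
score_cohort <- function(cohort, config = mrix_scoring_config()) {
  needed <- c("tls_density", "panck_foci", "ki67_pct", "n_driver_mutations",
              "pdl1_fold", "cd8_foxp3_ratio", "gzmb_density", "margin_mm")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required biomarker column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ds <- cbind(score_histopathology(cohort$tls_density),
              score_tumor_burden(cohort$panck_foci, cohort$ki67_pct),
              score_molecular(cohort$n_driver_mutations, cohort$pdl1_fold),
              score_immune(cohort$cd8_foxp3_ratio, cohort$gzmb_density))
  res <- compute_mrix(ds, cohort$margin_mm, config)
  cohort$histopathology_score <- ds[, 1]
  cohort$tumor_burden_score <- ds[, 2]
  cohort$molecular_score <- ds[, 3]
  cohort$immune_score <- ds[, 4]
  cohort$mrix_score <- res$mrix_score
  cohort$mrix_category <- res$mrix_category
  cohort$override_applied <- res$override_applied
  cohort
}
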