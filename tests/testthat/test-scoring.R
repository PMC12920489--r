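test_that("domain scorers reproduce the rubric bands and boundaries", {
  # histopathology: TLS density, protective direction
  expect_identical(score_histopathology(c(3.2, 3, 1, 0.999, 0.5, 0)),
                   c(0L, 0L, 1L, 2L, 2L, 2L))
  # tumor burden: max of Pan-CK and Ki-67 sub-levels
  cases_tb <- list(list(0, 3, 0L), list(6, 25, 2L), list(0, 25, 2L),
                   list(0.5, 3, 1L), list(5, 1, 2L), list(0, 20, 1L),
                   list(0, 5, 1L), list(4.9, 4.9, 1L))
  for (cs in cases_tb) {
    expect_identical(score_tumor_burden(cs[[1]], cs[[2]]), cs[[3]])
  }
  # molecular: max of mutation count and PD-L1 fold sub-levels
  cases_mol <- list(list(0, 0.6, 0L), list(2, 2.5, 2L), list(1, 0.5, 1L),
                    list(0, 1, 1L), list(0, 2, 1L), list(0, 2.01, 2L),
                    list(3, 0, 2L))
  for (cs in cases_mol) {
    expect_identical(score_molecular(cs[[1]], cs[[2]]), cs[[3]])
  }
  # immune: max of CD8/FoxP3 ratio and Granzyme B sub-levels
  cases_imm <- list(list(2.4, 250, 0L), list(0.8, 30, 2L), list(1.95, 250, 1L),
                    list(2, 201, 0L), list(2, 200, 1L), list(5, 50, 1L),
                    list(5, 49.9, 2L), list(0.99, 500, 2L))
  for (cs in cases_imm) {
    expect_identical(score_immune(cs[[1]], cs[[2]]), cs[[3]])
  }
})

test_that("undefined CD8/FoxP3 ratios map deterministically", {
  expect_identical(score_immune(Inf, 250), 0L)   # CD8 present, FoxP3 absent
  expect_identical(score_immune(NaN, 250), 2L)   # no cytotoxic infiltrate
})

test_that("scorers reject invalid measurements but propagate missing ones", {
  expect_error(score_histopathology(-1), "non-negative")
  expect_error(score_tumor_burden(-1, 10), "non-negative")
  expect_error(score_tumor_burden(0, 105), "percentage")
  expect_error(score_molecular(1.5, 1), "integer")
  expect_error(score_immune(-0.1, 10), "non-negative")
  # NA flows through to an NA score/category for complete-case handling
  expect_identical(score_histopathology(c(NA, 5)), c(NA_integer_, 0L))
  res <- compute_mrix(c(NA, 1, 1, 1), margin_mm = 8)
  expect_true(is.na(res$mrix_score) && is.na(res$mrix_category))
  # but a missing margin cannot fire the override
  res2 <- compute_mrix(c(0, 0, 0, 0), margin_mm = NA)
  expect_false(res2$override_applied)
})

test_that("composite score is the exact weighted sum with rounded-category lookup", {
  expect_equal(compute_mrix(c(0, 0, 0, 0), 8)$mrix_score, 0)
  expect_equal(as.character(compute_mrix(c(0, 0, 0, 0), 8)$mrix_category), "low")
  r <- compute_mrix(c(2, 2, 2, 2), 8)
  expect_equal(r$mrix_score, 2)
  expect_equal(as.character(r$mrix_category), "high")
  r <- compute_mrix(c(2, 1, 1, 1), 8)
  expect_equal(r$mrix_score, 1.3)
  expect_equal(as.character(r$mrix_category), "intermediate")
  # achievable scores falling in the printed gaps round half-up first
  r <- compute_mrix(c(2, 1, 0, 0), 8)          # 0.85
  expect_equal(r$mrix_score, 0.85)
  expect_equal(as.character(r$mrix_category), "intermediate")
  r <- compute_mrix(c(1, 1, 2, 2), 8)          # 1.45
  expect_equal(r$mrix_score, 1.45)
  expect_equal(as.character(r$mrix_category), "high")
})

test_that("close-margin override forces high category without changing the score", {
  r <- compute_mrix(c(0, 0, 0, 0), margin_mm = 1.5)
  expect_equal(r$mrix_score, 0)
  expect_equal(as.character(r$mrix_category), "high")
  expect_true(r$override_applied)
  r2 <- compute_mrix(c(0, 0, 0, 0), margin_mm = 2)   # boundary is inclusive
  expect_true(r2$override_applied)
  r3 <- compute_mrix(c(2, 2, 2, 2), margin_mm = 1)   # never lowers a category
  expect_equal(as.character(r3$mrix_category), "high")
})

test_that("all 81 combinations stay on the 0.05 grid and are category-monotone", {
  e <- enumerate_mrix_combinations()
  expect_equal(nrow(e), 81)
  expect_equal(min(e$mrix_score), 0)
  expect_equal(max(e$mrix_score), 2)
  expect_true(all(abs(e$mrix_score / 0.05 - round(e$mrix_score / 0.05)) < 1e-9))
  ranks <- as.integer(e$mrix_category)
  doms <- c("histopathology_score", "tumor_burden_score",
            "molecular_score", "immune_score")
  for (d in doms) {
    for (i in seq_len(nrow(e))) {
      if (e[[d]][i] < 2) {
        j <- mapply(function(col) {
          e[[col]] == e[[col]][i] + as.integer(col == d)
        }, doms)
        expect_gte(ranks[which(rowSums(j) == 4)], ranks[i])
      }
    }
  }
})

test_that("scoring config validation catches bad weights and cuts", {
  expect_error(mrix_scoring_config(weights = c(histopathology = 0.5,
                                               tumor_burden = 0.25,
                                               molecular = 0.25,
                                               immune = 0.2)), "sum to 1")
  expect_error(mrix_scoring_config(low_max = 1.5, intermediate_max = 1.4),
               "ordered")
})

test_that("score_cohort appends derived columns and names missing inputs", {
  co <- small_training_cohort(n = 144)
  expect_equal(nrow(co), 144)
  expect_true(all(co$mrix_score >= 0 & co$mrix_score <= 2))
  expect_true(all(abs(co$mrix_score / 0.05 - round(co$mrix_score / 0.05)) < 1e-9))
  rescored <- score_cohort(co)
  expect_equal(rescored$mrix_score, co$mrix_score)
  broken <- co[, setdiff(names(co), "ki67_pct")]
  expect_error(score_cohort(broken), "ki67_pct")
})
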