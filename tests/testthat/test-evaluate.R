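test_that("onset matching is one-to-one within the tolerance", {
  t_ref <- c(0.1, 0.5, 1.0)
  m <- match_events(t_ref, t_ref, tol = 1.2e-3)
  expect_equal(nrow(m$pairs), 3L)
  expect_length(m$unmatched_detected, 0L)
  expect_length(m$unmatched_reference, 0L)

  m_half <- match_events(t_ref + 0.5 * 1.2e-3, t_ref, tol = 1.2e-3)
  expect_equal(nrow(m_half$pairs), 3L)
  m_double <- match_events(t_ref + 2 * 1.2e-3, t_ref, tol = 1.2e-3)
  expect_equal(nrow(m_double$pairs), 0L)

  # two detections flanking one reference: exactly one pair
  tol <- 1e-3
  m_flank <- match_events(c(0.5 - 0.2 * tol, 0.5 + 0.2 * tol), 0.5, tol)
  expect_equal(nrow(m_flank$pairs), 1L)
  expect_length(m_flank$unmatched_detected, 1L)

  expect_error(match_events(1, 1, tol = -1), "non-negative")
})

test_that("greedy matching agrees with brute-force optimal matching", {
  # brute force: maximise pair count over all one-to-one assignments
  brute_max <- function(det, ref, tol) {
    best <- 0
    assign_next <- function(i, used) {
      if (i > length(det)) { best <<- max(best, sum(used >= 0)); return() }
      assign_next(i + 1, used)
      for (j in seq_along(ref)) {
        if (!(j %in% used) && abs(det[i] - ref[j]) <= tol) {
          assign_next(i + 1, c(used, j))
        }
      }
    }
    assign_next(1, integer(0))
    best
  }
  # the flanking instance reaches the optimum exactly
  tol <- 1e-3
  det <- c(0.5 - 0.2 * tol, 0.5 + 0.2 * tol)
  expect_equal(nrow(match_events(det, 0.5, tol)$pairs),
               brute_max(det, 0.5, tol))
  # on random instances the greedy pairing is always valid (one-to-one,
  # within tolerance) and never exceeds the optimal pair count
  withr::with_seed(17, {
    for (rep in 1:20) {
      det <- sort(runif(4))
      ref <- sort(runif(4))
      tol <- runif(1, 0.05, 0.4)
      m <- match_events(det, ref, tol)
      expect_lte(nrow(m$pairs), brute_max(det, ref, tol))
      expect_false(anyDuplicated(m$pairs$detected_idx) > 0)
      expect_false(anyDuplicated(m$pairs$reference_idx) > 0)
      expect_true(all(abs(m$pairs$detected_time -
                            m$pairs$reference_time) <= tol + 1e-12))
    }
  })
})

test_that("confusion counts follow the accepted/matched taxonomy", {
  ref <- c(1, 2, 3)
  cand <- c(1.0005, 2.0005, 5, 6)
  cc_all <- confusion_counts(cand, cand, ref, tol = 1.2e-3)
  expect_equal(unclass(cc_all), c(TP = 2, FP = 2, TN = 0, FN = 1),
               ignore_attr = TRUE)

  cc_none <- confusion_counts(numeric(0), numeric(0), ref)
  expect_equal(unclass(cc_none), c(TP = 0, FP = 0, TN = 0, FN = 3),
               ignore_attr = TRUE)

  # hand enumeration: 5 candidates, 3 references, one reference missed;
  # accepted = {1.0005, 5.0}; candidate 2.0005 matches ref 2 but rejected
  cand5 <- c(1.0005, 2.0005, 4, 5, 6)
  cc <- confusion_counts(cand5, c(1.0005, 5), ref, tol = 1.2e-3)
  # TP: 1.0005; FP: 5; TN: 4 and 6 (unmatched, rejected);
  # FN: refs 2 (rejected) and 3 (undetected)
  expect_equal(unclass(cc), c(TP = 1, FP = 1, TN = 2, FN = 2),
               ignore_attr = TRUE)
  expect_equal(cc[["TP"]] + cc[["FN"]], length(ref))

  expect_error(confusion_counts(cand, c(1.0005, 99), ref), "subset")
})

test_that("ROC metrics reproduce the defining formulas", {
  m <- roc_metrics(c(TP = 8, FP = 2, TN = 6, FN = 4))
  expect_equal(unname(m["FPR"]), 0.25)
  expect_equal(unname(m["TPR"]), 8 / 12)
  expect_equal(unname(m["accuracy"]), 0.70)
  expect_equal(unname(m["FDR"]), 0.20)

  clean <- roc_metrics(c(TP = 5, FP = 0, TN = 3, FN = 0))
  expect_equal(unname(clean["FPR"]), 0)
  expect_equal(unname(clean["FDR"]), 0)
  expect_equal(unname(clean["accuracy"]), 1)

  w <- capture_warnings(out <- roc_metrics(c(TP = 0, FP = 0, TN = 0,
                                             FN = 3)))
  expect_match(w, "undefined", all = TRUE)
  expect_true(is.na(out[["FPR"]]))
  expect_true(is.na(out[["FDR"]]))
})

test_that("MCC matches hand arithmetic and its conventions", {
  expect_equal(mcc(c(TP = 5, FP = 0, TN = 5, FN = 0)), 1)
  expect_equal(mcc(c(TP = 5, FP = 5, TN = 5, FN = 5)), 0)
  expect_equal(mcc(c(TP = 6, FP = 1, TN = 3, FN = 2)), 16 / sqrt(1120))
  expect_equal(mcc(c(TP = 3, FP = 0, TN = 0, FN = 0)), 0)  # zero marginal
})

test_that("the rater MCC grid is symmetric with unit diagonal", {
  pool <- c(1, 2, 3, 4, 5)
  raters <- list(
    list(candidates = pool, accepted = c(1, 2, 3)),
    list(candidates = pool, accepted = c(1, 2, 4)),
    list(candidates = pool, accepted = c(4, 5))   # disjoint from rater 1
  )
  g <- rater_mcc_grid(raters, tol = 0.1)
  expect_equal(diag(g), rep(1, 3))
  expect_equal(g, t(g))
  expect_lte(g[1, 3], 0)   # disjoint selections from a shared pool
  expect_gt(g[1, 2], 0)
  expect_error(rater_mcc_grid(raters[1]), "at least 2")
})

test_that("exhaustive permutation enumerates every sign assignment", {
  a <- c(0.40, 0.44, 0.52, 0.47)
  b <- c(0.70, 0.75, 0.80, 0.72)
  res <- paired_permutation_test(a, b)
  expect_equal(res$n_assignments, 16)
  expect_equal(res$observed_diff, mean(b - a))
  expect_equal(res$p, 2 / 16)   # all-same-sign tails only

  same <- paired_permutation_test(a, a)
  expect_equal(same$observed_diff, 0)
  expect_equal(same$p, 1)

  # p is floored at 2/2^n and invariant to swapping the conditions
  swap <- paired_permutation_test(b, a)
  expect_equal(swap$p, res$p)
  expect_equal(swap$observed_diff, -res$observed_diff)
  expect_gte(res$p, 2 / 2^length(a))

  expect_error(paired_permutation_test(rnorm(26), rnorm(26)), "n <= 25")
  expect_error(paired_permutation_test(1:3, 1:4), "equal length")
})

test_that("Monte-Carlo permutation p agrees with the exhaustive oracle", {
  withr::with_seed(23, {
    a <- rnorm(8)
    b <- a + rnorm(8, 0.4, 0.5)
  })
  ex <- paired_permutation_test(a, b, mode = "exhaustive")
  mc <- paired_permutation_test(a, b, mode = "monte_carlo", n_mc = 1e5,
                                seed = 2)
  se <- sqrt(ex$p * (1 - ex$p) / 1e5)
  expect_lt(abs(mc$p - ex$p), 3 * se + 2 / 1e5)
})

test_that("the subject-level grid permutation test behaves sanely", {
  mk_rater <- function(seed, p_accept) {
    withr::with_seed(seed, {
      cand <- sort(runif(20, 0, 10))
      list(candidates = cand,
           accepted = cand[runif(20) < p_accept])
    })
  }
  # condition b: all raters share one decision pattern (high agreement)
  shared <- mk_rater(100, 0.5)
  raters_b <- replicate(4, shared, simplify = FALSE)
  raters_a <- lapply(1:4, function(i) mk_rater(i, 0.5))
  res <- rater_consistency_test(raters_a, raters_b, tol = 0.05)
  expect_equal(res$n_assignments, 16)
  expect_gt(res$observed_diff, 0)       # shared model raises agreement
  expect_gte(res$p, 0); expect_lte(res$p, 1)
  expect_equal(diag(res$grid_b), rep(1, 4))
  # swapping the two conditions flips the sign, keeps the p-value
  res_sw <- rater_consistency_test(raters_b, raters_a, tol = 0.05)
  expect_equal(res_sw$observed_diff, -res$observed_diff)
  expect_equal(res_sw$p, res$p)
})
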