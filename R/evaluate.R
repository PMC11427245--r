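#' Match detected to reference event onsets
#'
#' Greedy nearest-neighbour one-to-one matching: candidate pairs within the
#' tolerance are ranked by absolute time difference (ties broken by earlier
#' reference time) and accepted while both members are still unmatched. No
#' detected or reference time is used twice.
#'
#' @param detected,reference Sorted numeric vectors of onset times (s).
#' @param tol Matching tolerance in seconds (>= 0). The default 1.2 ms is
#'   the onset tolerance used throughout the evaluation protocol.
#' @return List with `pairs` (data frame `detected_time`, `reference_time`,
#'   `detected_idx`, `reference_idx`), `unmatched_detected`,
#'   `unmatched_reference` (index vectors).
#' @export
match_events <- function(detected, reference, tol = 1.2e-3) {
  if (tol < 0) stop("`tol` must be non-negative")
  nd <- length(detected); nr <- length(reference)
  if (nd == 0L || nr == 0L) {
    return(list(pairs = data.frame(detected_time = numeric(0),
                                   reference_time = numeric(0),
                                   detected_idx = integer(0),
                                   reference_idx = integer(0)),
                unmatched_detected = seq_len(nd),
                unmatched_reference = seq_len(nr)))
  }
  cand <- do.call(rbind, lapply(seq_len(nd), function(i) {
    j <- which(abs(reference - detected[i]) <= tol + 1e-12)
    if (!length(j)) return(NULL)
    cbind(i = i, j = j, d = abs(reference[j] - detected[i]))
  }))
  pairs_i <- integer(0); pairs_j <- integer(0)
  if (!is.null(cand)) {
    ord <- order(cand[, "d"], reference[cand[, "j"]])
    used_i <- logical(nd); used_j <- logical(nr)
    for (r in ord) {
      i <- cand[r, "i"]; j <- cand[r, "j"]
      if (!used_i[i] && !used_j[j]) {
        used_i[i] <- TRUE; used_j[j] <- TRUE
        pairs_i <- c(pairs_i, i); pairs_j <- c(pairs_j, j)
      }
    }
  }
  list(pairs = data.frame(detected_time = detected[pairs_i],
                          reference_time = reference[pairs_j],
                          detected_idx = pairs_i, reference_idx = pairs_j),
       unmatched_detected = setdiff(seq_len(nd), pairs_i),
       unmatched_reference = setdiff(seq_len(nr), pairs_j))
}

#' Confusion counts for classified candidates against a reference
#'
#' Candidates are matched one-to-one to the reference onsets within `tol`;
#' each candidate is then scored by its classification: a matched accepted
#' candidate is a true positive, an unmatched accepted candidate a false
#' positive, an unmatched rejected candidate a true negative. False
#' negatives are reference events with no accepted match (missed at
#' detection, or detected but rejected), so `TP + FN` always equals the
#' number of reference events.
#'
#' @param candidates Numeric vector of all candidate onset times (s).
#' @param accepted Subset of `candidates`: the onsets classified as true
#'   events.
#' @param reference Ground-truth (or expert) onset times (s).
#' @param tol Matching tolerance in seconds.
#' @return Object of class `psc_confusion`: named integer vector
#'   `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(candidates, accepted, reference,
                             tol = 1.2e-3) {
  acc_idx <- match(round(accepted, 12), round(candidates, 12))
  if (anyNA(acc_idx)) stop("`accepted` must be a subset of `candidates`")
  is_acc <- seq_along(candidates) %in% acc_idx
  m <- match_events(candidates, reference, tol)
  matched <- logical(length(candidates))
  matched[m$pairs$detected_idx] <- TRUE
  tp <- sum(matched & is_acc)
  fp <- sum(!matched & is_acc)
  tn <- sum(!matched & !is_acc)
  fn <- length(reference) - tp
  structure(c(TP = tp, FP = fp, TN = tn, FN = fn), class = "psc_confusion")
}

#' ROC-style metrics from confusion counts
#'
#' `FPR = FP / (FP + TN)`, `TPR = TP / (TP + FN)`,
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`, `FDR = FP / (FP + TP)`.
#' A metric whose denominator is zero is undefined and returned as `NA`
#' with a warning rather than silently propagated.
#'
#' @param counts Named vector with elements `TP`, `FP`, `TN`, `FN` (e.g.
#'   from [confusion_counts()]).
#' @return Named vector `FPR`, `TPR`, `accuracy`, `FDR`.
#' @export
#' @examples
#' roc_metrics(c(TP = 8, FP = 2, TN = 6, FN = 4))
roc_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  safe_div <- function(num, den, name) {
    if (den == 0) {
      warning(name, " undefined: zero denominator")
      return(NA_real_)
    }
    num / den
  }
  c(FPR = safe_div(fp, fp + tn, "FPR"),
    TPR = safe_div(tp, tp + fn, "TPR"),
    accuracy = safe_div(tp + tn, tp + tn + fp + fn, "accuracy"),
    FDR = safe_div(fp, fp + tp, "FDR"))
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP * TN - FP * FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, a
#' balanced summary of a 2x2 confusion table in `[-1, 1]`. When any
#' marginal is zero the coefficient is 0 by convention.
#'
#' @inheritParams roc_metrics
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den2)
}

#' Pairwise MCC agreement grid between raters
#'
#' Each rater is a candidate pool (onset times) with an accepted subset.
#' For every rater pair, the two candidate pools are aligned by onset
#' matching within `tol`; each item of the aligned union carries the two
#' raters' accept/reject decisions (a candidate absent from a rater's pool
#' counts as rejected by that rater), giving a 2x2 table whose MCC fills
#' the grid. The diagonal is 1 and the grid is symmetric.
#'
#' @param raters List of raters, each a list with numeric vectors
#'   `candidates` and `accepted` (times in s, accepted a subset of
#'   candidates).
#' @param tol Onset matching tolerance in seconds.
#' @return Symmetric numeric matrix of MCCs.
#' @export
rater_mcc_grid <- function(raters, tol = 1.2e-3) {
  nr <- length(raters)
  if (nr < 2L) stop("need at least 2 raters")
  g <- diag(1, nr)
  for (i in seq_len(nr - 1L)) {
    for (j in (i + 1L):nr) {
      g[i, j] <- g[j, i] <- pair_mcc(raters[[i]], raters[[j]], tol)
    }
  }
  g
}

pair_mcc <- function(a, b, tol) {
  acc_a <- a$candidates %in% a$accepted |
    in_tol_set(a$candidates, a$accepted, 1e-9)
  acc_b <- b$candidates %in% b$accepted |
    in_tol_set(b$candidates, b$accepted, 1e-9)
  m <- match_events(a$candidates, b$candidates, tol)
  da <- acc_a[m$pairs$detected_idx]
  db <- acc_b[m$pairs$reference_idx]
  # unmatched candidates: present for one rater only, the other "rejects"
  da <- c(da, acc_a[m$unmatched_detected],
          rep(FALSE, length(m$unmatched_reference)))
  db <- c(db, rep(FALSE, length(m$unmatched_detected)),
          acc_b[m$unmatched_reference])
  mcc(c(TP = sum(da & db), FP = sum(da & !db),
        TN = sum(!da & !db), FN = sum(!da & db)))
}

in_tol_set <- function(x, set, tol) {
  if (!length(set)) return(rep(FALSE, length(x)))
  vapply(x, function(v) any(abs(set - v) <= tol), TRUE)
}

#' Exact paired permutation test
#'
#' Tests whether paired per-subject scores differ between two conditions.
#' The statistic is the mean paired difference `mean(b - a)`. Under the
#' null, each subject's pair of values is exchangeable, so the null
#' distribution is built from sign assignments of the differences:
#' exhaustively over all `2^n` unique assignments (the observed assignment
#' included), or by Monte-Carlo sampling. The two-tailed p-value is the
#' proportion of assignments whose statistic is at least as extreme in
#' absolute value as the observed one.
#'
#' @param scores_a,scores_b Equal-length numeric vectors of per-subject
#'   scores under the two conditions.
#' @param mode `"exhaustive"` (requires `n <= 25`) or `"monte_carlo"`.
#' @param n_mc Number of Monte-Carlo replicates (default `1e5`).
#' @param seed Seed for Monte-Carlo mode.
#' @return List: `observed_diff`, `p` (two-tailed), `n_assignments`
#'   (enumerated or sampled), `mode`.
#' @export
#' @examples
#' a <- c(0.40, 0.44, 0.52, 0.47)
#' b <- c(0.70, 0.75, 0.80, 0.72)
#' paired_permutation_test(a, b)$p   # 2/16: all mass in the two sign tails
paired_permutation_test <- function(scores_a, scores_b,
                                    mode = c("exhaustive", "monte_carlo"),
                                    n_mc = 1e5, seed = 1) {
  mode <- match.arg(mode)
  if (length(scores_a) != length(scores_b)) {
    stop("paired scores must have equal length")
  }
  n <- length(scores_a)
  if (n < 1L) stop("need at least one pair")
  d <- scores_b - scores_a
  obs <- mean(d)
  eps <- 1e-12
  if (mode == "exhaustive") {
    if (n > 25L) stop("exhaustive enumeration limited to n <= 25")
    total <- 2^n
    block <- 2^16
    n_extreme <- 0
    for (start in seq(0, total - 1, by = block)) {
      codes <- start:min(start + block - 1, total - 1)
      signs <- outer(codes, 0:(n - 1),
                     function(c0, b) 1 - 2 * (c0 %/% 2^b %% 2))
      stats <- as.vector(signs %*% d) / n
      n_extreme <- n_extreme + sum(abs(stats) >= abs(obs) - eps)
    }
    list(observed_diff = obs, p = n_extreme / total, n_assignments = total,
         mode = mode)
  } else {
    stats <- withr::with_seed(seed, {
      signs <- matrix(1 - 2 * rbinom(n_mc * n, 1, 0.5), nrow = n_mc)
      as.vector(signs %*% d) / n
    })
    # include the observed assignment in the reference set
    p <- (1 + sum(abs(stats) >= abs(obs) - eps)) / (n_mc + 1)
    list(observed_diff = obs, p = p, n_assignments = n_mc, mode = mode)
  }
}

#' Permutation test of rater agreement between two conditions
#'
#' Compares inter-rater agreement (mean off-diagonal MCC) between two
#' conditions, e.g. manual classification versus classification with a
#' shared model. Because pairwise MCCs are correlated, the exchange is
#' performed at the subject level: each permutation swaps whole
#' (candidates, accepted) event-time sets between conditions for a subset
#' of raters, and both MCC grids are recomputed per replicate.
#'
#' @param raters_a,raters_b Equal-length rater lists (see
#'   [rater_mcc_grid()]) for the two conditions, same rater order.
#' @param tol Onset matching tolerance in seconds.
#' @param mode `"exhaustive"` (all `2^n` swap patterns; `n <= 15`) or
#'   `"monte_carlo"`.
#' @param n_mc Monte-Carlo replicates.
#' @param seed Seed for Monte-Carlo mode.
#' @return List: `observed_diff` (mean off-diagonal MCC of condition b
#'   minus a), `p` (two-tailed), `n_assignments`, `mode`, and the two
#'   observed grids `grid_a`, `grid_b`.
#' @export
rater_consistency_test <- function(raters_a, raters_b, tol = 1.2e-3,
                                   mode = c("exhaustive", "monte_carlo"),
                                   n_mc = 1000, seed = 1) {
  mode <- match.arg(mode)
  n <- length(raters_a)
  if (length(raters_b) != n) stop("conditions must have the same raters")
  offdiag_mean <- function(g) mean(g[row(g) != col(g)])
  stat_for <- function(swap) {
    ra <- raters_a; rb <- raters_b
    ra[swap] <- raters_b[swap]; rb[swap] <- raters_a[swap]
    offdiag_mean(rater_mcc_grid(rb, tol)) -
      offdiag_mean(rater_mcc_grid(ra, tol))
  }
  grid_a <- rater_mcc_grid(raters_a, tol)
  grid_b <- rater_mcc_grid(raters_b, tol)
  obs <- offdiag_mean(grid_b) - offdiag_mean(grid_a)
  eps <- 1e-12
  if (mode == "exhaustive") {
    if (n > 15L) stop("exhaustive grid permutation limited to n <= 15")
    total <- 2^n
    stats <- vapply(0:(total - 1), function(code) {
      stat_for(which(bitwAnd(code, 2^(0:(n - 1))) > 0))
    }, numeric(1))
    p <- mean(abs(stats) >= abs(obs) - eps)
    list(observed_diff = obs, p = p, n_assignments = total, mode = mode,
         grid_a = grid_a, grid_b = grid_b)
  } else {
    stats <- withr::with_seed(seed, vapply(seq_len(n_mc), function(i) {
      stat_for(which(runif(n) < 0.5))
    }, numeric(1)))
    p <- (1 + sum(abs(stats) >= abs(obs) - eps)) / (n_mc + 1)
    list(observed_diff = obs, p = p, n_assignments = n_mc, mode = mode,
         grid_a = grid_a, grid_b = grid_b)
  }
}
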