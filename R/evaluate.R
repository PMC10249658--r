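# Matching predicted to experimental sites and computing TPR/PPV.
#
# A predicted site is a correct hit when it lies within a distance cutoff
# (3 A by default) of an experimental ion; matching is one-to-one, greedy
# nearest-first. TPR = hits / experimental sites, PPV = hits / predicted
# sites: the two are antagonistic except for a perfect model.

#' Greedy one-to-one matching of predicted to true sites
#'
#' Repeatedly pairs the globally closest unmatched (predicted, true) pair
#' with distance `<= cutoff` until none remains.
#'
#' @param pred,truth site tables with `x`, `y`, `z` columns.
#' @param cutoff hit distance cutoff (A), default 3.
#' @return a list of class `site_matching`: `pairs` (data.frame
#'   `pred_idx`, `true_idx`, `distance`), `unmatched_pred`,
#'   `unmatched_true`, `cutoff`.
#' @export
match_sites <- function(pred, truth, cutoff = 3.0) {
  stopifnot(cutoff > 0)
  np <- nrow(pred); nt <- nrow(truth)
  pairs <- data.frame(pred_idx = integer(0), true_idx = integer(0),
                      distance = numeric(0))
  if (np && nt) {
    D <- outer(seq_len(np), seq_len(nt), function(i, j)
      sqrt((pred$x[i] - truth$x[j])^2 + (pred$y[i] - truth$y[j])^2 +
             (pred$z[i] - truth$z[j])^2))
    D <- matrix(D, np, nt)
    repeat {
      m <- which.min(D)
      if (!length(m) || D[m] > cutoff) break
      i <- (m - 1) %% np + 1
      j <- (m - 1) %/% np + 1
      pairs <- rbind(pairs, data.frame(pred_idx = i, true_idx = j,
                                       distance = D[m]))
      D[i, ] <- Inf
      D[, j] <- Inf
      if (all(!is.finite(D))) break
    }
  }
  structure(list(pairs = pairs,
                 unmatched_pred = setdiff(seq_len(np), pairs$pred_idx),
                 unmatched_true = setdiff(seq_len(nt), pairs$true_idx),
                 cutoff = cutoff, n_pred = np, n_true = nt),
            class = "site_matching")
}

#' TPR/PPV report from a matching
#'
#' @param matching a `site_matching` from [match_sites()].
#' @return a list of class `eval_report` with `tpr`, `ppv`, `n_true`,
#'   `n_pred`, `n_hit`. When a denominator is zero the corresponding rate
#'   is `NA` (undefined), except `tpr = 0` for zero hits with true sites
#'   present.
#' @export
eval_report <- function(matching) {
  nh <- nrow(matching$pairs)
  nt <- matching$n_true
  np <- matching$n_pred
  structure(list(tpr = if (nt > 0) nh / nt else NA_real_,
                 ppv = if (np > 0) nh / np else NA_real_,
                 n_true = nt, n_pred = np, n_hit = nh,
                 cutoff = matching$cutoff),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d/%d true sites hit (TPR %.3f), %d/%d predictions correct (PPV %.3f), cutoff %.1f A\n",
              x$n_hit, x$n_true,
              ifelse(is.na(x$tpr), NaN, x$tpr),
              x$n_hit, x$n_pred,
              ifelse(is.na(x$ppv), NaN, x$ppv), x$cutoff))
  invisible(x)
}

#' Pooled TPR/PPV from counts
#'
#' Pure arithmetic on hit/true/predicted counts pooled over structures.
#'
#' @param n_hit,n_true,n_pred integers.
#' @return list with `tpr` and `ppv`.
#' @export
rates_from_counts <- function(n_hit, n_true, n_pred) {
  list(tpr = if (n_true > 0) n_hit / n_true else NA_real_,
       ppv = if (n_pred > 0) n_hit / n_pred else NA_real_)
}

#' TPR/PPV as a function of the number of top-ranked predictions
#'
#' For each n, the top-n predictions of every structure are pooled,
#' matched at `cutoff`, and micro-averaged TPR/PPV are reported.
#'
#' @param pred_list list of ranked site tables (one per structure).
#' @param true_list list of experimental site tables (same order).
#' @param n_max largest n.
#' @param cutoff hit cutoff (A).
#' @return data.frame with columns `n`, `tpr`, `ppv`, `n_hit`, `n_true`,
#'   `n_pred`.
#' @export
topn_curves <- function(pred_list, true_list, n_max, cutoff = 3.0) {
  stopifnot(length(pred_list) == length(true_list))
  out <- data.frame(n = 0:n_max, tpr = 0, ppv = NA_real_, n_hit = 0L,
                    n_true = sum(vapply(true_list, nrow, 1L)), n_pred = 0L)
  for (n in seq_len(n_max)) {
    nh <- 0L; np <- 0L
    for (s in seq_along(pred_list)) {
      ps <- topn(pred_list[[s]], n)
      np <- np + nrow(ps)
      nh <- nh + nrow(match_sites(ps, true_list[[s]], cutoff)$pairs)
    }
    out$n_hit[n + 1] <- nh
    out$n_pred[n + 1] <- np
    r <- rates_from_counts(nh, out$n_true[n + 1], np)
    out$tpr[n + 1] <- r$tpr
    out$ppv[n + 1] <- r$ppv
  }
  out
}

#' Success rate versus distance cutoff
#'
#' For each cutoff, the fraction of true sites with a matched prediction
#' (one-to-one matching recomputed per cutoff); non-decreasing in the
#' cutoff.
#'
#' @param pred,truth site tables.
#' @param cutoffs sorted positive cutoffs (A).
#' @return data.frame with `cutoff` and `success_rate`.
#' @export
success_vs_cutoff <- function(pred, truth, cutoffs) {
  stopifnot(all(cutoffs > 0), !is.unsorted(cutoffs))
  sr <- vapply(cutoffs, function(co) {
    m <- match_sites(pred, truth, co)
    if (m$n_true == 0) return(NA_real_)
    nrow(m$pairs) / m$n_true
  }, 1)
  data.frame(cutoff = cutoffs, success_rate = sr)
}

#' Seeded k-fold partition of structure ids
#'
#' @param ids character or integer vector of structure identifiers.
#' @param k number of folds (`2 <= k <= length(ids)`).
#' @param seed shuffle seed.
#' @return list of k disjoint id subsets covering `ids`, sizes differing
#'   by at most one.
#' @export
kfold <- function(ids, k, seed = 1) {
  n <- length(ids)
  if (k < 2 || k > n) stop("k must be in [2, length(ids)]")
  set.seed(seed)
  shuffled <- sample(ids)
  fold_of <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) shuffled[fold_of == f])
}
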