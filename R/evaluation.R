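#' Rank-based ROC and AUC
#'
#' AUC is computed as the Mann-Whitney rank statistic (probability that a
#' random positive scores above a random negative, ties counted as 1/2),
#' which equals trapezoidal integration of the ROC curve.  ROC points are
#' produced by sweeping a threshold over the observed scores.
#'
#' @param positive,negative Numeric score vectors; both must be non-empty.
#' @return A list of class `ranking_result` with `auc`, `roc` (data frame
#'   `fpr`, `tpr` from (0,0) to (1,1)), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(positive, negative) {
  if (length(positive) == 0L || length(negative) == 0L) {
    stop("both score lists must be non-empty")
  }
  np <- length(positive)
  nn <- length(negative)
  r <- rank(c(positive, negative), ties.method = "average")
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(c(positive, negative)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(positive >= t), 1)
  fpr <- vapply(thr, function(t) mean(negative >= t), 1)
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  structure(list(auc = auc, roc = roc, n_pos = np, n_neg = nn),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> AUC = %.4f", x$auc))
  if (!is.null(x$auc_std)) cat(sprintf(" +/- %.4f (sd over repeats)", x$auc_std))
  cat("\n")
  invisible(x)
}

# Midrank percentile of a test score within a candidate pool.
pool_percentile <- function(score, pool) {
  (sum(pool < score) + 0.5 * sum(pool == score)) / length(pool)
}

#' Cross-validation configuration
#'
#' @param folds Number of folds for k-fold CV (default 5).
#' @param repeats Number of random re-divisions for k-fold CV (default
#'   100; per-repeat seeds are derived as `seed + repeat_index - 1`).
#' @param seed Integer seed for fold assignment.
#' @param refresh_kernels If `TRUE` (default), every adjacency-dependent
#'   similarity (profile kernels, internally computed functional
#'   similarity, integrated matrices) is recomputed with the test
#'   associations removed in each fold, so no information leaks from test
#'   to train.  `FALSE` computes the similarities once from the full data,
#'   the cheaper fixed-similarity protocol common in this literature.
#' @param refresh_symnmf If `TRUE` (default), the symmetric-NMF
#'   interpolation is likewise rerun per fold; `FALSE` reuses the
#'   interpolation of the full data.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(folds = 5L, repeats = 100L, seed = 1L,
                      refresh_kernels = TRUE, refresh_symnmf = TRUE) {
  stopifnot(folds >= 2L, repeats >= 1L)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed),
                 refresh_kernels = isTRUE(refresh_kernels),
                 refresh_symnmf = isTRUE(refresh_symnmf)),
            class = "cv_config")
}

# Shared fold engine: mask each group of positives in turn, rerun the
# adjacency-dependent part of the pipeline per the refresh flags, and hand
# the fold's score matrix to `record_fn(fold_index, scores, masked_idx)`.
# `fold_sets` is a list of integer matrices (rows of cbind(i, j)).
run_masked_folds <- function(a_full, hierarchy, fs, config, cv, fold_sets,
                             record_fn) {
  sem <- pipeline_semantic(hierarchy, rownames(a_full), config)
  interp <- !identical(config$interpolate, FALSE)
  cache <- NULL
  if (!cv$refresh_kernels || !cv$refresh_symnmf) {
    base <- pipeline_score(a_full, sem$ss, fs, config, run_symnmf = interp,
                           no_dag = sem$no_dag)
    cache <- list(sd_star = base$sd_star, sm_star = base$sm_star,
                  kd = base$kd, km = base$km, fs = base$fs,
                  sd = base$sd, sm = base$sm)
  }
  for (k in seq_along(fold_sets)) {
    idx <- fold_sets[[k]]
    a <- a_full
    a[idx] <- 0
    if (cv$refresh_kernels) {
      res <- pipeline_score(a, sem$ss, fs, config,
                            run_symnmf = cv$refresh_symnmf && interp,
                            cache = cache, no_dag = sem$no_dag)
      s <- res$scores
    } else {
      s <- kronrls_solve(cache$sd_star, cache$sm_star, a, config$kronrls)
    }
    record_fn(k, s, idx)
  }
  invisible(NULL)
}

# Leave-one-out engine: one fold per known association, recording both the
# global percentile (pool = all unverified pairs) and the local percentile
# (pool = unverified pairs of the test disease).
loocv_records <- function(assoc, hierarchy, fs = NULL, config = mda_config(),
                          cv = cv_config()) {
  a_full <- if (is.matrix(assoc)) assoc else build_adjacency(assoc)
  pos <- which(a_full != 0, arr.ind = TRUE)
  if (nrow(pos) < 2L) stop("leave-one-out cross-validation needs at least 2 known associations")
  unknown_mask <- a_full == 0
  fold_sets <- lapply(seq_len(nrow(pos)), function(k) pos[k, , drop = FALSE])
  recs <- vector("list", nrow(pos))
  run_masked_folds(a_full, hierarchy, fs, config, cv, fold_sets,
                   function(k, s, idx) {
    i <- idx[1L, 1L]
    j <- idx[1L, 2L]
    test_score <- s[i, j]
    gpool <- s[unknown_mask]
    lpool <- s[i, unknown_mask[i, ]]
    recs[[k]] <<- data.frame(
      disease = rownames(a_full)[i], mirna = colnames(a_full)[j],
      score = test_score,
      global_percentile = pool_percentile(test_score, gpool),
      local_percentile = if (length(lpool) > 0L) {
        pool_percentile(test_score, lpool)
      } else NA_real_,
      global_pool = length(gpool), local_pool = length(lpool),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

# Pooled ROC over per-fold percentiles: each test sample's score is its
# percentile within its own fold's candidate pool, and TPR/FPR are swept
# over a shared threshold grid on [0, 1] (the pool percentile of a null
# sample is uniform, so FPR at threshold u is 1 - u).
percentile_ranking <- function(p) {
  p <- p[!is.na(p)]
  u <- seq(1, 0, length.out = 201L)
  roc <- data.frame(fpr = c(0, 1 - u, 1),
                    tpr = c(0, vapply(u, function(t) mean(p >= t), 1), 1))
  structure(list(auc = mean(p), roc = roc, n_pos = length(p)),
            class = "ranking_result")
}

#' Global and local leave-one-out cross-validation
#'
#' Each known association is left out in turn; the pipeline is rerun with
#' that association removed (recomputing adjacency-dependent similarities
#' per the `cv` refresh flags) and the held-out pair's score is ranked
#' against the candidate pool of unverified pairs -- all of them for
#' global LOOCV, only the test disease's for local LOOCV.  AUC is the mean
#' pool percentile of the test samples, the probability that a held-out
#' true association outranks a random unverified pair.
#'
#' `loocv_eval()` runs the folds once and returns both views; the
#' `global_loocv()` / `local_loocv()` wrappers return one.
#'
#' @param assoc Association data frame or adjacency matrix.
#' @param hierarchy A `disease_hierarchy`.
#' @param fs Optional precomputed miRNA functional similarity.
#' @param config An [mda_config()].
#' @param cv A [cv_config()].
#' @return `loocv_eval()`: list with `global` and `local` (each a
#'   `ranking_result`) and `records` (one row per fold).  The wrappers
#'   return the corresponding `ranking_result` with `records` attached.
#' @export
loocv_eval <- function(assoc, hierarchy, fs = NULL, config = mda_config(),
                       cv = cv_config()) {
  recs <- loocv_records(assoc, hierarchy, fs, config, cv)
  list(global = percentile_ranking(recs$global_percentile),
       local = percentile_ranking(recs$local_percentile),
       records = recs)
}

#' @rdname loocv_eval
#' @export
global_loocv <- function(assoc, hierarchy, fs = NULL, config = mda_config(),
                         cv = cv_config()) {
  out <- loocv_eval(assoc, hierarchy, fs, config, cv)
  res <- out$global
  res$records <- out$records
  res
}

#' @rdname loocv_eval
#' @export
local_loocv <- function(assoc, hierarchy, fs = NULL, config = mda_config(),
                        cv = cv_config()) {
  out <- loocv_eval(assoc, hierarchy, fs, config, cv)
  res <- out$local
  res$records <- out$records
  res
}

#' Repeated k-fold cross-validation
#'
#' Per repeat, the known associations are shuffled with a derived seed
#' (`cv$seed + repeat_index - 1`), split into `cv$folds` near-equal parts,
#' and each part is masked in turn; every masked association's score is
#' converted to its percentile within the pool of unverified pairs (the
#' global ranking rule) and the repeat's AUC is the mean percentile.
#' Reported are the mean and standard deviation of the AUC over repeats.
#'
#' @inheritParams loocv_eval
#' @return A `ranking_result` with `auc` (mean over repeats), `auc_std`,
#'   `per_repeat` (AUC vector) and `roc` (pooled over all repeats).
#' @export
kfold_cv <- function(assoc, hierarchy, fs = NULL, config = mda_config(),
                     cv = cv_config()) {
  a_full <- if (is.matrix(assoc)) assoc else build_adjacency(assoc)
  pos <- which(a_full != 0, arr.ind = TRUE)
  if (nrow(pos) < cv$folds) stop("fewer known associations than folds")
  unknown_mask <- a_full == 0
  aucs <- numeric(cv$repeats)
  all_p <- list()
  for (rep_i in seq_len(cv$repeats)) {
    perm <- with_local_seed(cv$seed + rep_i - 1L, sample.int(nrow(pos)))
    # fold labels 1..k,1..k,... dealt onto a shuffled order: near-equal
    # fold sizes (differing by at most 1)
    assign_fold <- rep_len(seq_len(cv$folds), nrow(pos))[perm]
    fold_sets <- lapply(seq_len(cv$folds), function(k) {
      pos[assign_fold == k, , drop = FALSE]
    })
    percs <- vector("list", cv$folds)
    run_masked_folds(a_full, hierarchy, fs, config, cv, fold_sets,
                     function(k, s, idx) {
      gpool <- s[unknown_mask]
      percs[[k]] <<- vapply(seq_len(nrow(idx)), function(r) {
        pool_percentile(s[idx[r, 1L], idx[r, 2L]], gpool)
      }, 1)
    })
    p <- unlist(percs)
    aucs[rep_i] <- mean(p)
    all_p[[rep_i]] <- p
  }
  res <- percentile_ranking(unlist(all_p))
  res$auc <- mean(aucs)
  res$auc_std <- stats::sd(aucs)
  if (cv$repeats == 1L) res$auc_std <- 0
  res$per_repeat <- aucs
  res
}
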