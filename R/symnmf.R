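#' Parameters for symmetric NMF interpolation
#'
#' @param alpha Damping factor in (0, 1) of the multiplicative update; close
#'   to 1 means nearly undamped steps.  Default 0.999.
#' @param rank Number of columns of the factor `P`: `"full"` (the matrix
#'   dimension, giving a factor the same size as the input) or a positive
#'   integer for low-rank runs.
#' @param max_iter Maximum number of update iterations (default 500).
#' @param tol Relative change in the squared Frobenius residual below which
#'   iteration stops (default 1e-6).
#' @param seed Integer seed controlling the random positive initialization.
#' @return A list of class `symnmf_params`.
#' @export
symnmf_params <- function(alpha = 0.999, rank = "full", max_iter = 500L,
                          tol = 1e-6, seed = 1L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            identical(rank, "full") || (is.numeric(rank) && rank >= 1),
            is.numeric(max_iter), max_iter >= 1, is.numeric(tol), tol > 0)
  structure(list(alpha = alpha, rank = rank, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed)),
            class = "symnmf_params")
}

# Deterministic 31-bit hash of a string; exact in double arithmetic.
str_hash31 <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

# Random positive initial factor.  Each row is drawn from a sub-stream
# keyed by (seed, row label) so that permuting the labelled input rows
# permutes the initialization -- and hence the whole factorization --
# identically.  Entries are uniform on (0, sqrt(mean(sd) / r)], which
# scale-matches the initial residual to the input.
symnmf_init <- function(sd, rank, seed) {
  n <- nrow(sd)
  upper <- sqrt(max(mean(sd), 1e-12) / rank)
  labels <- rownames(sd)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  p0 <- matrix(0, n, rank)
  for (i in seq_len(n)) {
    row_seed <- (seed %% 2147483647) * 1048583 + str_hash31(labels[i])
    p0[i, ] <- with_local_seed(row_seed %% 2147483647,
                               stats::runif(rank, min = 1e-8, max = upper))
  }
  rownames(p0) <- rownames(sd)
  p0
}

# Evaluate an expression under a temporary RNG seed, restoring the global
# RNG state afterwards; keeps all randomness local to the call.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# ||sd - p p^T||_F^2 without forming the n x n residual when r < n:
# ||sd||^2 - 2 <sd p, p> + ||p^T p||^2.
symnmf_residual <- function(sd_norm2, sd, p) {
  ptp <- crossprod(p)
  val <- sd_norm2 - 2 * sum((sd %*% p) * p) + sum(ptp^2)
  max(val, 0)
}

#' One symmetric-NMF update step
#'
#' Computes the multiplicative ratio `R = (SD P) / (P P^T P)` (entrywise
#' division, denominators floored at 1e-12), the damped candidate update
#' `P * (1 - alpha + alpha R)` and the cube-root fallback update
#' `P * R^(1/3)`.  The iteration driver accepts the candidate when it
#' lowers the squared Frobenius residual and otherwise takes the fallback,
#' whose fractional exponent guarantees a conservative, monotone step.
#'
#' @param sd Symmetric non-negative target matrix.
#' @param p Current factor, strictly positive entrywise.
#' @param alpha Damping factor.
#' @return List with `candidate`, `fallback` and `ratio`.
#' @export
symnmf_step <- function(sd, p, alpha) {
  num <- sd %*% p
  den <- p %*% crossprod(p)
  den[den < 1e-12] <- 1e-12
  r <- num / den
  list(candidate = p * (1 - alpha + alpha * r),
       fallback = p * r^(1 / 3),
       ratio = r)
}

#' Interpolate a similarity matrix by symmetric NMF
#'
#' Factorizes a symmetric non-negative matrix `SD` as `P P^T` with `P`
#' entrywise non-negative, by damped multiplicative updates with a
#' cube-root fallback (see [symnmf_step()]).  The returned `interpolated`
#' matrix `P P^T` is positive semidefinite by construction, which is what
#' makes the downstream Kronecker kernel well-behaved; it is consumed
#' as-is, without renormalization to unit diagonal.
#'
#' Iteration stops when the relative change of the squared residual drops
#' below `tol` or after `max_iter` iterations.  The run is deterministic
#' given `params$seed` and the row labels (the initialization is keyed by
#' label, so relabelled/permuted inputs give identically permuted output).
#'
#' @param sd Symmetric (to 1e-8) non-negative matrix with dimnames.
#' @param params A [symnmf_params()] object.
#' @return A list of class `symnmf_result`: `P` (n x r factor),
#'   `interpolated` (`P P^T`), `residual_trace` (squared Frobenius
#'   residuals, starting at the initial factor), `iterations`, and
#'   `rel_residual` (final `||SD - P P^T||_F / ||SD||_F`).
#' @export
symnmf_interpolate <- function(sd, params = symnmf_params()) {
  stopifnot(is.matrix(sd), nrow(sd) == ncol(sd))
  if (max(abs(sd - t(sd))) > 1e-8) stop("symnmf input is not symmetric")
  if (min(sd) < 0) stop("symnmf input has negative entries")
  n <- nrow(sd)
  r <- if (identical(params$rank, "full")) n else as.integer(params$rank)
  sd <- (sd + t(sd)) / 2

  p <- symnmf_init(sd, r, params$seed)
  sd_norm2 <- sum(sd^2)
  # residual bookkeeping reuses SD %*% P and P'P across iterations:
  # ||SD - P P'||_F^2 = ||SD||^2 - 2 <SD P, P> + ||P'P||_F^2
  sp <- sd %*% p
  ptp <- crossprod(p)
  e <- max(sd_norm2 - 2 * sum(sp * p) + sum(ptp^2), 0)
  trace <- numeric(params$max_iter + 1L)
  trace[1L] <- e
  iters <- 0L
  alpha <- params$alpha
  for (i in seq_len(params$max_iter)) {
    den <- p %*% ptp
    den[den < 1e-12] <- 1e-12
    ratio <- sp / den
    cand <- p * (1 - alpha + alpha * ratio)
    sp_new <- sd %*% cand
    ptp_new <- crossprod(cand)
    e_new <- max(sd_norm2 - 2 * sum(sp_new * cand) + sum(ptp_new^2), 0)
    if (e_new >= e) {
      cand <- p * ratio^(1 / 3)
      sp_new <- sd %*% cand
      ptp_new <- crossprod(cand)
      e_new <- max(sd_norm2 - 2 * sum(sp_new * cand) + sum(ptp_new^2), 0)
    }
    iters <- i
    rel_change <- abs(e - e_new) / max(e, .Machine$double.eps)
    p <- cand
    sp <- sp_new
    ptp <- ptp_new
    e <- e_new
    trace[i + 1L] <- e
    if (rel_change < params$tol) break
  }
  interp <- tcrossprod(p)
  dimnames(interp) <- dimnames(sd)
  structure(list(P = p, interpolated = interp,
                 residual_trace = trace[seq_len(iters + 1L)],
                 iterations = iters,
                 rel_residual = sqrt(e) / max(sqrt(sd_norm2), .Machine$double.eps)),
            class = "symnmf_result")
}

#' @export
print.symnmf_result <- function(x, ...) {
  cat(sprintf("<symnmf_result> %d x %d factor, %d iterations, relative residual %.3g\n",
              nrow(x$P), ncol(x$P), x$iterations, x$rel_residual))
  invisible(x)
}
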