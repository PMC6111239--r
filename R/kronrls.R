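#' Parameters for the Kronecker regularized least-squares solver
#'
#' @param lam Ridge regularization parameter, the trade-off between fitting
#'   the observed 0/1 associations and the smoothness of the pairwise
#'   kernel model.  Default 1.
#' @return A list of class `kronrls_params`.
#' @export
kronrls_params <- function(lam = 1) {
  stopifnot(is.numeric(lam), length(lam) == 1L, lam > 0)
  structure(list(lam = lam), class = "kronrls_params")
}

#' Eigendecomposition of a symmetric similarity matrix
#'
#' Thin wrapper over `eigen(symmetric = TRUE)` that validates symmetry and
#' returns eigenvalues in descending order with orthogonal eigenvectors.
#'
#' @param m Symmetric matrix (asymmetry beyond 1e-8 is an error).
#' @return List with `vectors` (orthogonal matrix) and `values` (descending
#'   eigenvalues).
#' @export
eigendecompose_sym <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8) stop("matrix is not symmetric")
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  list(vectors = e$vectors, values = e$values)
}

#' Score all disease-miRNA pairs by Kronecker regularized least squares
#'
#' Solves the kernel ridge problem over all pairs, where the pairwise
#' kernel is the Kronecker product of a disease similarity kernel and a
#' miRNA similarity kernel, in closed form via the two side
#' eigendecompositions: with `SD* = Vd Ld Vd'` and `SM* = Vm Lm Vm'`, each
#' Kronecker eigenvalue `ld*lm` is shrunk to `ld*lm / (ld*lm + lam)` and
#' applied in the eigenbasis, so the full `(nd*nm) x (nd*nm)` kernel is
#' never materialized.  The result equals `vec(S) = K (K + lam I)^-1
#' vec(A)` with `K` the Kronecker-product kernel.
#'
#' Kernels produced by [symnmf_interpolate()] are positive semidefinite up
#' to rounding; eigenvalues are clipped at zero by default so the pairwise
#' kernel stays PSD.  With `clip_negative = FALSE` (for raw, possibly
#' indefinite similarity inputs) negative eigenvalues are used as-is and a
#' warning is emitted when any are present.
#'
#' @param sd_star Disease kernel matrix (rows/cols = diseases of `a`).
#' @param sm_star miRNA kernel matrix (rows/cols = miRNAs of `a`).
#' @param a Adjacency matrix (diseases x miRNAs).
#' @param params A [kronrls_params()] object.
#' @param clip_negative Clip negative kernel eigenvalues at zero (default
#'   `TRUE`).
#' @return Score matrix with the same shape and dimnames as `a`.
#' @export
kronrls_solve <- function(sd_star, sm_star, a, params = kronrls_params(),
                          clip_negative = TRUE) {
  check_kernel_labels(sd_star, sm_star, a)
  ed <- eigendecompose_sym(sd_star)
  em <- eigendecompose_sym(sm_star)
  ld <- ed$values
  lm <- em$values
  if (clip_negative) {
    ld[ld < 0] <- 0
    lm[lm < 0] <- 0
  } else if (any(ld < 0) || any(lm < 0)) {
    warning("kernel has negative eigenvalues; the pairwise Kronecker kernel is indefinite")
  }
  # inner coefficient matrix in the joint eigenbasis (nm x nd)
  m <- crossprod(em$vectors, t(a)) %*% ed$vectors
  shrink <- outer(lm, ld, function(x, y) {
    xy <- x * y
    xy / (xy + params$lam)
  })
  z <- m * shrink
  s <- ed$vectors %*% t(z) %*% t(em$vectors)
  dimnames(s) <- dimnames(a)
  s
}

#' Direct (materialized-kernel) KronRLS reference solver
#'
#' Forms the full Kronecker-product pairwise kernel `K = SD* (x) SM*`,
#' solves `(K + lam I) x = vec(A)` with a dense linear solve and returns
#' `K x` reshaped.  Exponential in memory relative to the factorized
#' solver, so guarded to `nd * nm <= 2000`; it exists as the independent
#' reference implementation for equivalence tests.
#'
#' @inheritParams kronrls_solve
#' @return Score matrix with the same shape and dimnames as `a`.
#' @export
kronrls_direct <- function(sd_star, sm_star, a, params = kronrls_params()) {
  check_kernel_labels(sd_star, sm_star, a)
  n <- nrow(a) * ncol(a)
  if (n > 2000) stop("kronrls_direct is a small-problem reference solver (nd*nm <= 2000)")
  k <- kronecker(unname(sd_star), unname(sm_star))
  y <- as.vector(t(a))          # column-stacking of A^T: miRNA index fastest
  x <- solve(k + params$lam * diag(n), y)
  s <- t(matrix(k %*% x, nrow = ncol(a)))
  dimnames(s) <- dimnames(a)
  s
}

check_kernel_labels <- function(sd_star, sm_star, a) {
  if (!identical(rownames(sd_star), rownames(a)) ||
      !identical(colnames(sd_star), rownames(a))) {
    stop("disease kernel labels do not match the adjacency matrix rows")
  }
  if (!identical(rownames(sm_star), colnames(a)) ||
      !identical(colnames(sm_star), colnames(a))) {
    stop("miRNA kernel labels do not match the adjacency matrix columns")
  }
  invisible(TRUE)
}

#' Configuration for the full prediction pipeline
#'
#' Aggregates the per-stage parameters: the semantic contribution factor
#' and log base (disease DAG similarity), the Gaussian kernel bandwidth
#' parameters, the symmetric-NMF settings, and the ridge parameter of the
#' closed-form solver.  Defaults are the model's standard operating point:
#' `delta = 0.5`, `gamma_d = gamma_m = 1`, `alpha = 0.999`, full-rank
#' factorization with at most 500 iterations at tolerance 1e-6, `lam = 1`.
#'
#' @param delta,log_base See [semantic_params()].
#' @param gamma_d,gamma_m See [kernel_params()].
#' @param alpha,rank,max_iter,tol See [symnmf_params()].
#' @param lam See [kronrls_params()].
#' @param seed Integer seed for the symmetric-NMF initialization.
#' @param kernel_fallback If `TRUE`, disease pairs involving a disease
#'   without a DAG (absent from the hierarchy) take their integrated
#'   similarity from the profile kernel alone instead of averaging it with
#'   the zero semantic similarity.  Default `FALSE`: the plain average is
#'   applied uniformly.
#' @param interpolate If `FALSE`, skip the symmetric-NMF stage and feed the
#'   raw integrated similarities to the solver (negative eigenvalues are
#'   then used as-is, with a warning).
#' @return A list of class `mda_config`.
#' @export
mda_config <- function(delta = 0.5, log_base = exp(1),
                       gamma_d = 1, gamma_m = 1,
                       alpha = 0.999, rank = "full", max_iter = 500L,
                       tol = 1e-6, lam = 1, seed = 1L,
                       kernel_fallback = FALSE, interpolate = TRUE) {
  structure(list(
    semantic = semantic_params(delta = delta, log_base = log_base),
    kernel = kernel_params(gamma_d = gamma_d, gamma_m = gamma_m),
    symnmf = symnmf_params(alpha = alpha, rank = rank, max_iter = max_iter,
                           tol = tol, seed = seed),
    kronrls = kronrls_params(lam = lam),
    seed = as.integer(seed),
    kernel_fallback = isTRUE(kernel_fallback),
    interpolate = isTRUE(interpolate)
  ), class = "mda_config")
}

# Disease semantic similarity for an ordered disease list; A-independent.
pipeline_semantic <- function(hierarchy, diseases, config) {
  dags <- build_disease_dags(hierarchy, diseases, config$semantic)
  ss1 <- semantic_similarity(dags, model = 1, diseases = diseases)
  ss2 <- semantic_similarity(dags, model = 2, diseases = diseases)
  list(ss1 = ss1, ss2 = ss2, ss = combine_semantic(ss1, ss2),
       no_dag = setdiff(diseases, names(dags)))
}

# A-dependent half of the pipeline: kernels, functional similarity,
# integration, SymNMF interpolation, KronRLS scoring.
pipeline_score <- function(a, ss, fs, config,
                           run_symnmf = TRUE, cache = NULL, no_dag = NULL) {
  kd <- gaussian_kernel(a, "disease", config$kernel)
  km <- gaussian_kernel(a, "mirna", config$kernel)
  fs_eff <- if (is.null(fs)) mirna_functional_similarity(a, ss) else {
    fs[colnames(a), colnames(a), drop = FALSE]
  }
  sd <- integrate_similarity(ss, kd)
  sm <- integrate_similarity(fs_eff, km)
  if (isTRUE(config$kernel_fallback) && length(no_dag) > 0L) {
    # pairs with no semantic information fall back to the kernel alone
    hit <- rownames(a) %in% no_dag
    mask <- outer(hit, hit, `|`)
    diag(mask) <- FALSE
    sd[mask] <- kd[mask]
  }
  if (run_symnmf) {
    sd_star <- symnmf_interpolate(sd, config$symnmf)$interpolated
    sm_star <- symnmf_interpolate(sm, config$symnmf)$interpolated
  } else if (!is.null(cache)) {
    sd_star <- cache$sd_star
    sm_star <- cache$sm_star
  } else {
    sd_star <- sd
    sm_star <- sm
  }
  s <- kronrls_solve(sd_star, sm_star, a, config$kronrls,
                     clip_negative = run_symnmf || !is.null(cache))
  list(scores = s, kd = kd, km = km, fs = fs_eff, sd = sd, sm = sm,
       sd_star = sd_star, sm_star = sm_star)
}

#' Run the full association-prediction pipeline
#'
#' Chains every stage: adjacency construction, disease semantic similarity
#' (two DAG models averaged), Gaussian interaction-profile kernels on both
#' axes, miRNA functional similarity (computed from the data unless a
#' precomputed matrix is supplied, which then takes precedence), similarity
#' integration, symmetric-NMF interpolation of both integrated matrices,
#' and closed-form Kronecker RLS scoring of every disease-miRNA pair.
#'
#' @param assoc Association data frame (columns `disease`, `mirna`) or a
#'   precomputed adjacency matrix.
#' @param hierarchy A `disease_hierarchy`.
#' @param fs Optional precomputed miRNA functional similarity matrix; must
#'   cover every miRNA in `assoc`.
#' @param config An [mda_config()] object.
#' @param keep_intermediates If `TRUE`, return all intermediate matrices in
#'   addition to the scores.
#' @return The score matrix (diseases x miRNAs), or, with
#'   `keep_intermediates = TRUE`, a list with elements `scores`, `ss1`,
#'   `ss2`, `ss`, `kd`, `km`, `fs`, `sd`, `sm`, `sd_star`, `sm_star`.
#' @export
mda_predict <- function(assoc, hierarchy, fs = NULL, config = mda_config(),
                        keep_intermediates = FALSE) {
  a <- if (is.matrix(assoc)) assoc else build_adjacency(assoc)
  sem <- pipeline_semantic(hierarchy, rownames(a), config)
  res <- pipeline_score(a, sem$ss, fs, config,
                        run_symnmf = !identical(config$interpolate, FALSE),
                        no_dag = sem$no_dag)
  if (keep_intermediates) {
    c(list(scores = res$scores, ss1 = sem$ss1, ss2 = sem$ss2, ss = sem$ss),
      res[c("kd", "km", "fs", "sd", "sm", "sd_star", "sm_star")])
  } else {
    res$scores
  }
}

#' Rank candidate miRNAs for a disease treated as new
#'
#' Emulates prediction for a disease with no known associated miRNAs: the
#' disease's row of the adjacency matrix is zeroed, every quantity that
#' depends on the adjacency matrix (profile kernels, internally computed
#' functional similarity, integrated similarities, the symmetric-NMF
#' interpolation and the solver) is recomputed, and the disease's miRNAs
#' are returned sorted by descending score.
#'
#' @inheritParams mda_predict
#' @param disease Identifier of the disease to mask; must be present.
#' @return Data frame with columns `mirna`, `score`, `rank` (one row per
#'   modeled miRNA, best first).
#' @export
predict_new_disease <- function(assoc, hierarchy, fs = NULL,
                                config = mda_config(), disease) {
  a <- if (is.matrix(assoc)) assoc else build_adjacency(assoc)
  if (!(disease %in% rownames(a))) {
    stop(sprintf("unknown disease '%s'", disease))
  }
  a[disease, ] <- 0
  s <- mda_predict(a, hierarchy, fs = fs, config = config)
  o <- order(s[disease, ], decreasing = TRUE)
  data.frame(mirna = colnames(s)[o], score = s[disease, o],
             rank = seq_along(o), stringsAsFactors = FALSE, row.names = NULL)
}
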