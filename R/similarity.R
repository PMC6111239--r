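#' Parameters for DAG-based disease semantic similarity
#'
#' @param delta Semantic contribution factor in (0, 1): each step from a
#'   disease to its parent multiplies the ancestor's contribution by
#'   `delta` in model 1.  Default 0.5, the value used by the DAG similarity
#'   method this model follows.
#' @param log_base Base of the logarithm in model 2's information-content
#'   contribution.  The model-2 similarity is invariant to this base
#'   (numerator and denominator scale identically), so the default natural
#'   log is cosmetic.
#' @return A list of class `semantic_params`.
#' @export
semantic_params <- function(delta = 0.5, log_base = exp(1)) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0, delta < 1,
            is.numeric(log_base), length(log_base) == 1L, log_base > 0,
            log_base != 1)
  structure(list(delta = delta, log_base = log_base), class = "semantic_params")
}

#' Parameters for the Gaussian interaction-profile kernels
#'
#' `gamma_d` and `gamma_m` are the raw bandwidth parameters; the effective
#' bandwidth used in the kernel is obtained by normalizing them by the mean
#' squared norm of the interaction profiles on that axis, so that the
#' kernel scale adapts to the density of the association matrix.  Both
#' default to 1.
#'
#' @param gamma_d,gamma_m Positive reals.
#' @return A list of class `kernel_params`.
#' @export
kernel_params <- function(gamma_d = 1, gamma_m = 1) {
  stopifnot(is.numeric(gamma_d), gamma_d > 0, is.numeric(gamma_m), gamma_m > 0)
  structure(list(gamma_d = gamma_d, gamma_m = gamma_m), class = "kernel_params")
}

# Ancestor closure of `d` (including d itself) in the child -> parent edge
# set, as a character vector.
disease_ancestors <- function(h, d) {
  parents <- split(h$edges$parent, h$edges$child)
  seen <- d
  frontier <- d
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Number of disease DAGs containing each hierarchy node
#'
#' For every hierarchy node, counts how many of the modeled diseases have a
#' DAG (ancestor closure) containing that node.  Only diseases present in
#' the hierarchy contribute a DAG.  Used by semantic similarity model 2,
#' where a node shared by many disease DAGs is less specific and so
#' contributes less.
#'
#' @param h A `disease_hierarchy`.
#' @param diseases Character vector of modeled disease identifiers (the
#'   adjacency matrix's disease list).
#' @return Named integer vector over hierarchy nodes appearing in at least
#'   one modeled disease's DAG.
#' @export
dag_counts <- function(h, diseases) {
  present <- intersect(diseases, h$nodes)
  counts <- new.env(parent = emptyenv())
  for (d in present) {
    for (t in disease_ancestors(h, d)) {
      counts[[t]] <- (if (is.null(counts[[t]])) 0L else counts[[t]]) + 1L
    }
  }
  nms <- ls(counts)
  stats::setNames(vapply(nms, function(k) counts[[k]], 1L), nms)
}

#' Build one disease's semantic DAG with contribution maps
#'
#' Restricts the hierarchy to disease `d` plus its ancestors and computes
#' both per-node contribution schemes: model 1 decays geometrically with
#' DAG distance (`contribution1[d] = 1` at the disease itself, and each
#' other node takes `delta` times the maximum over its children inside the
#' DAG); model 2 is the information content `-log(dag_counts[t] /
#' n_diseases)`, independent of position.  `dv1`/`dv2` are the semantic
#' values, the sums of the respective contributions over the DAG.
#'
#' @param h A `disease_hierarchy`.
#' @param d Disease identifier; must be a hierarchy node.
#' @param params A [semantic_params()] object.
#' @param counts Output of [dag_counts()] for the modeled disease set.
#' @param n_diseases Number of modeled diseases (denominator of the model-2
#'   information content).
#' @return A list of class `disease_dag` with elements `root`, `nodes`,
#'   `edges`, `contribution1`, `contribution2`, `dv1`, `dv2`.
#' @export
disease_dag <- function(h, d, params = semantic_params(), counts, n_diseases) {
  if (!(d %in% h$nodes)) stop(sprintf("disease '%s' is not in the hierarchy", d))
  nodes <- disease_ancestors(h, d)
  edges <- h$edges[h$edges$child %in% nodes & h$edges$parent %in% nodes, , drop = FALSE]

  # model 1: propagate the decayed contribution upward from d; process each
  # node only once all of its in-DAG children are done (edges child->parent
  # are acyclic, so the loop below terminates).
  c1 <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  c1[d] <- 1
  children_of <- split(edges$child, edges$parent)
  pending <- setdiff(nodes, d)
  while (length(pending) > 0L) {
    ready <- pending[vapply(pending, function(t) {
      kids <- intersect(children_of[[t]], nodes)
      length(kids) > 0L && !anyNA(c1[kids])
    }, TRUE)]
    if (length(ready) == 0L) stop("hierarchy DAG is inconsistent (unreachable ancestor)")
    for (t in ready) {
      kids <- intersect(children_of[[t]], nodes)
      c1[t] <- params$delta * max(c1[kids])
    }
    pending <- setdiff(pending, ready)
  }

  if (missing(counts) || missing(n_diseases)) {
    c2 <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  } else {
    if (any(!(nodes %in% names(counts)))) {
      stop("dag_counts must cover every node of the disease's DAG")
    }
    c2 <- -log(counts[nodes] / n_diseases, base = params$log_base)
    names(c2) <- nodes
  }

  structure(list(root = d, nodes = nodes, edges = edges,
                 contribution1 = c1, contribution2 = c2,
                 dv1 = sum(c1), dv2 = sum(c2)),
            class = "disease_dag")
}

#' Build the semantic DAGs for a set of diseases
#'
#' Convenience wrapper: computes [dag_counts()] over the modeled disease
#' set and calls [disease_dag()] for every disease present in the
#' hierarchy.  Diseases absent from the hierarchy get no DAG (they receive
#' zero off-diagonal semantic similarity downstream).
#'
#' @inheritParams disease_dag
#' @param diseases Modeled disease identifiers, in matrix order.
#' @return Named list of `disease_dag` objects (subset of `diseases`).
#' @export
build_disease_dags <- function(h, diseases, params = semantic_params()) {
  present <- intersect(diseases, h$nodes)
  counts <- dag_counts(h, diseases)
  dags <- lapply(present, disease_dag, h = h, params = params,
                 counts = counts, n_diseases = length(diseases))
  stats::setNames(dags, present)
}

#' Disease semantic similarity from DAG overlap
#'
#' Similarity of two diseases is the summed contributions of their shared
#' DAG nodes, from both sides, normalized by the sum of the two semantic
#' values: the more of their DAGs two diseases share, the more similar they
#' are.  Model 1 uses the geometric-decay contributions, model 2 the
#' information-content contributions.  Diseases without a DAG (absent from
#' the hierarchy) get similarity 0 to everything and 1 to themselves.
#'
#' A degenerate model-2 denominator (both semantic values zero, possible
#' when both diseases' DAG nodes appear in every disease's DAG) is defined
#' as 0 off the diagonal and 1 on it, keeping the unit-diagonal convention;
#' each occurrence is reported via `message()`.
#'
#' @param dags Named list from [build_disease_dags()].
#' @param model 1 or 2.
#' @param diseases Full ordered disease list for the output matrix; defaults
#'   to `names(dags)`.
#' @return Symmetric similarity matrix over `diseases` with entries in
#'   \[0, 1\].
#' @export
semantic_similarity <- function(dags, model = 1, diseases = names(dags)) {
  stopifnot(model %in% c(1, 2))
  n <- length(diseases)
  ss <- matrix(0, n, n, dimnames = list(diseases, diseases))
  diag(ss) <- 1
  present <- intersect(diseases, names(dags))
  contrib <- if (model == 1) "contribution1" else "contribution2"
  dv <- if (model == 1) "dv1" else "dv2"
  degenerate <- 0L
  np <- length(present)
  if (np >= 1L && anyNA(dags[[present[1L]]][[contrib]])) {
    stop("model-2 contributions missing: build DAGs with dag_counts")
  }
  for (ii in seq_len(np)) {
    di <- dags[[present[ii]]]
    for (jj in ii:np) {
      dj <- dags[[present[jj]]]
      shared <- intersect(di$nodes, dj$nodes)
      denom <- di[[dv]] + dj[[dv]]
      if (denom <= 0) {
        val <- if (ii == jj) 1 else 0
        degenerate <- degenerate + 1L
      } else {
        val <- sum(di[[contrib]][shared] + dj[[contrib]][shared]) / denom
      }
      ss[present[ii], present[jj]] <- val
      ss[present[jj], present[ii]] <- val
    }
  }
  if (degenerate > 0L) {
    message(sprintf("semantic_similarity: %d degenerate zero-denominator pair(s) set to 0/1",
                    degenerate))
  }
  ss
}

#' Average the two semantic similarity models
#'
#' @param ss1,ss2 Semantic similarity matrices with identical dimnames.
#' @return Entrywise mean `(ss1 + ss2) / 2`.
#' @export
combine_semantic <- function(ss1, ss2) {
  if (!identical(dimnames(ss1), dimnames(ss2))) {
    stop("semantic similarity matrices have mismatched labels")
  }
  (ss1 + ss2) / 2
}

#' miRNA functional similarity from shared disease associations
#'
#' Implements the group-max rule: with `D1`, `D2` the disease groups
#' associated with two miRNAs, each disease in one group is matched to its
#' most similar disease in the other group under the disease semantic
#' similarity `ss`, and the matched similarities from both directions are
#' averaged over `|D1| + |D2|`.  A miRNA is fully similar to itself; a
#' miRNA with no associated disease has similarity 0 to every other miRNA.
#'
#' A precomputed functional similarity matrix (e.g. downloaded MISIM
#' scores) can be supplied to the pipeline instead; this function is the
#' fallback computed from the association data itself.
#'
#' @param a Binary adjacency matrix (diseases x miRNAs).
#' @param ss Disease similarity matrix covering every disease in `a`.
#' @return Symmetric miRNA similarity matrix with unit diagonal.
#' @export
mirna_functional_similarity <- function(a, ss) {
  if (!all(rownames(a) %in% rownames(ss))) {
    stop("disease similarity does not cover every disease in the adjacency matrix")
  }
  ss <- ss[rownames(a), rownames(a), drop = FALSE]
  nm <- ncol(a)
  sizes <- colSums(a != 0)
  # best[d, j] = max over diseases e associated with miRNA j of ss[d, e]
  best <- matrix(0, nrow(a), nm)
  for (j in seq_len(nm)) {
    grp <- which(a[, j] != 0)
    if (length(grp) > 0L) {
      best[, j] <- do.call(pmax, c(asplit(ss[, grp, drop = FALSE], 2), list(0)))
    }
  }
  # g[i, j] = sum over d in group(i) of best[d, j]
  g <- crossprod(a != 0, best)
  fs <- (g + t(g)) / outer(sizes, sizes, `+`)
  fs[!is.finite(fs)] <- 0
  diag(fs) <- 1
  dimnames(fs) <- list(colnames(a), colnames(a))
  fs
}

#' Gaussian interaction-profile kernel similarity
#'
#' Treats each disease's row (or each miRNA's column) of the adjacency
#' matrix as its binary interaction profile and applies a Gaussian kernel
#' `exp(-gamma * ||IP_i - IP_j||^2)`, with the bandwidth `gamma` obtained
#' by dividing the raw parameter by the mean squared profile norm on that
#' axis.
#'
#' @param a Binary adjacency matrix (diseases x miRNAs).
#' @param axis `"disease"` (rows) or `"mirna"` (columns).
#' @param params A [kernel_params()] object.
#' @return Symmetric kernel matrix with unit diagonal and entries in
#'   (0, 1].
#' @export
gaussian_kernel <- function(a, axis = c("disease", "mirna"),
                            params = kernel_params()) {
  axis <- match.arg(axis)
  prof <- if (axis == "disease") a else t(a)
  gp <- if (axis == "disease") params$gamma_d else params$gamma_m
  norms <- rowSums(prof^2)
  if (all(norms == 0)) stop("bandwidth undefined (all-zero adjacency)")
  gamma <- gp / mean(norms)
  # squared distances via the Gram matrix; clip tiny negatives from rounding
  gram <- tcrossprod(prof)
  d2 <- outer(norms, norms, `+`) - 2 * gram
  d2[d2 < 0] <- 0
  k <- exp(-gamma * d2)
  diag(k) <- 1
  dimnames(k) <- list(rownames(prof), rownames(prof))
  k
}

#' Integrate a semantic/functional similarity with its kernel counterpart
#'
#' Entrywise mean of the two matrices: `SD = (SS + KD) / 2` on the disease
#' side, `SM = (FS + KM) / 2` on the miRNA side.  The kernel term supplies
#' similarity for diseases that have no DAG (and miRNAs with sparse
#' functional information), which is the motivation for integrating at
#' all.
#'
#' @param sim Semantic (or functional) similarity matrix.
#' @param kernel Gaussian profile kernel matrix with identical dimnames.
#' @return The integrated similarity matrix.
#' @export
integrate_similarity <- function(sim, kernel) {
  if (!identical(dimnames(sim), dimnames(kernel))) {
    stop("similarity and kernel matrices have mismatched labels")
  }
  (sim + kernel) / 2
}
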