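#' Specification of a synthetic planted-block benchmark
#'
#' The generator emulates the statistical structure the prediction model
#' assumes -- functionally similar miRNAs associate with similar diseases
#' -- as a planted block model: diseases and miRNAs are partitioned into
#' latent communities, true associations occur with high probability
#' inside matching communities and low probability elsewhere, the disease
#' hierarchy groups each disease community into its own subtree (so DAG
#' semantic similarity is informative about communities), and a fraction
#' of the true associations is masked to form a held-out truth set.
#'
#' @param nd,nm Numbers of diseases and miRNAs.
#' @param n_blocks Number of latent communities on each side.
#' @param within_block_prob,background_prob Association probabilities for
#'   matching / non-matching community pairs; within must exceed
#'   background.
#' @param hierarchy_depth,branching Shape of each community's hierarchy
#'   subtree (internal levels below the shared root, children per node).
#' @param mask_fraction Fraction of true associations withheld from the
#'   observed table (uniformly at random).
#' @param seed Integer seed; all draws flow from it.
#' @param ensure_coverage Resample (up to 25 attempts, deterministically)
#'   if any disease or miRNA ends with zero observed associations.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(nd = 30L, nm = 40L, n_blocks = 3L,
                           within_block_prob = 0.35, background_prob = 0.02,
                           hierarchy_depth = 3L, branching = 3L,
                           mask_fraction = 0.2, seed = 1L,
                           ensure_coverage = TRUE) {
  stopifnot(nd >= n_blocks, nm >= n_blocks, n_blocks >= 1L,
            within_block_prob > background_prob,
            within_block_prob >= 0, within_block_prob <= 1,
            background_prob >= 0, background_prob <= 1,
            hierarchy_depth >= 1L, branching >= 1L,
            mask_fraction >= 0, mask_fraction < 1)
  structure(list(nd = as.integer(nd), nm = as.integer(nm),
                 n_blocks = as.integer(n_blocks),
                 within_block_prob = within_block_prob,
                 background_prob = background_prob,
                 hierarchy_depth = as.integer(hierarchy_depth),
                 branching = as.integer(branching),
                 mask_fraction = mask_fraction, seed = as.integer(seed),
                 ensure_coverage = isTRUE(ensure_coverage)),
            class = "synthetic_spec")
}

# Deterministic balanced community assignment: entity i -> block
# ((i - 1) %% n_blocks) + 1.
block_assignment <- function(n, n_blocks) {
  ((seq_len(n) - 1L) %% n_blocks) + 1L
}

synthetic_disease_ids <- function(nd) sprintf("disease_%02d", seq_len(nd))
synthetic_mirna_ids <- function(nm) sprintf("mirna_%02d", seq_len(nm))

#' Generate a block-structured disease hierarchy
#'
#' Builds a rooted tree: one shared root, one subtree per disease
#' community (internal nodes `grp_<block>_<level>_<index>` arranged with
#' the requested depth and branching), and each disease attached as a leaf
#' under a random internal node of its community's subtree.  Diseases of
#' one community therefore share ancestors, making DAG semantic similarity
#' higher within communities than between them.
#'
#' @param spec A [synthetic_spec()].
#' @return A `disease_hierarchy` covering every generated disease id.
#' @export
generate_hierarchy <- function(spec) {
  diseases <- synthetic_disease_ids(spec$nd)
  blocks <- block_assignment(spec$nd, spec$n_blocks)
  edges_child <- character()
  edges_parent <- character()
  block_internal <- vector("list", spec$n_blocks)
  for (b in seq_len(spec$n_blocks)) {
    top <- sprintf("grp_%d_1_1", b)
    edges_child <- c(edges_child, top)
    edges_parent <- c(edges_parent, "disease_root")
    level_nodes <- top
    all_nodes <- top
    for (lvl in seq_len(spec$hierarchy_depth - 1L) + 1L) {
      nxt <- character()
      for (parent in level_nodes) {
        kids <- sprintf("grp_%d_%d_%d", b, lvl,
                        length(nxt) + seq_len(spec$branching))
        edges_child <- c(edges_child, kids)
        edges_parent <- c(edges_parent, rep(parent, length(kids)))
        nxt <- c(nxt, kids)
      }
      level_nodes <- nxt
      all_nodes <- c(all_nodes, nxt)
      if (length(all_nodes) >= 4L * spec$branching) break  # keep subtrees small
    }
    block_internal[[b]] <- all_nodes
  }
  parents <- with_local_seed(spec$seed, {
    vapply(seq_len(spec$nd), function(i) {
      cand <- block_internal[[blocks[i]]]
      cand[sample.int(length(cand), 1L)]
    }, "")
  })
  edges <- data.frame(child = c(edges_child, diseases),
                      parent = c(edges_parent, parents),
                      stringsAsFactors = FALSE)
  disease_hierarchy(edges)
}

#' Generate a planted-block synthetic dataset
#'
#' Draws the true association matrix from the block model of `spec`, masks
#' `mask_fraction` of the true pairs uniformly at random, and packages the
#' observed associations, the hierarchy, the full truth and the masked
#' hold-out set.  Deterministic per seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_dataset` with elements
#'   `associations` (observed pairs, data frame), `hierarchy`, `truth`,
#'   `masked`, `diseases`, `mirnas`, `disease_blocks`, `mirna_blocks`,
#'   `spec`.
#' @export
generate_associations <- function(spec) {
  diseases <- synthetic_disease_ids(spec$nd)
  mirnas <- synthetic_mirna_ids(spec$nm)
  d_blocks <- block_assignment(spec$nd, spec$n_blocks)
  m_blocks <- block_assignment(spec$nm, spec$n_blocks)
  hierarchy <- generate_hierarchy(spec)
  match_block <- outer(d_blocks, m_blocks, `==`)
  probs <- ifelse(match_block, spec$within_block_prob, spec$background_prob)

  draw <- function(attempt) {
    with_local_seed(spec$seed + 1000L * attempt, {
      truth <- matrix(stats::runif(spec$nd * spec$nm) < probs,
                      spec$nd, spec$nm)
      t_idx <- which(truth, arr.ind = TRUE)
      n_mask <- floor(spec$mask_fraction * nrow(t_idx))
      m_sel <- if (n_mask > 0L) sample.int(nrow(t_idx), n_mask) else integer()
      list(truth = t_idx, masked = t_idx[m_sel, , drop = FALSE])
    })
  }
  for (attempt in 0:24) {
    d <- draw(attempt)
    obs <- d$truth[!paste(d$truth[, 1L], d$truth[, 2L]) %in%
                     paste(d$masked[, 1L], d$masked[, 2L]), , drop = FALSE]
    ok <- nrow(obs) > 0L &&
      (!spec$ensure_coverage ||
         (all(seq_len(spec$nd) %in% obs[, 1L]) &&
          all(seq_len(spec$nm) %in% obs[, 2L])))
    if (ok) break
  }
  if (!ok) stop("could not generate a dataset covering every disease and miRNA; lower mask_fraction or raise probabilities")

  as_table <- function(idx) {
    data.frame(disease = diseases[idx[, 1L]], mirna = mirnas[idx[, 2L]],
               stringsAsFactors = FALSE)
  }
  structure(list(associations = as_table(obs),
                 hierarchy = hierarchy,
                 truth = as_table(d$truth),
                 masked = as_table(d$masked),
                 diseases = diseases, mirnas = mirnas,
                 disease_blocks = d_blocks, mirna_blocks = m_blocks,
                 spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d x %d, %d true / %d observed / %d masked associations\n",
              x$spec$nd, x$spec$nm, nrow(x$truth), nrow(x$associations),
              nrow(x$masked)))
  invisible(x)
}

#' The frozen default synthetic benchmark
#'
#' The fixed operating point used throughout the package's own evaluation:
#' 30 diseases x 40 miRNAs in 3 communities, within-community association
#' probability 0.35 against a 0.02 background, a depth-3 branching-3
#' hierarchy, and 20% of true associations masked.
#'
#' @param seed Integer seed (the benchmark is reported over seeds 1-5).
#' @return A `synthetic_dataset`.
#' @export
default_benchmark <- function(seed = 1L) {
  generate_associations(synthetic_spec(seed = seed))
}

#' Degree-free null model: redraw associations uniformly at random
#'
#' Replaces the observed association table with the same number of
#' distinct pairs drawn uniformly over the full disease x miRNA grid,
#' destroying the planted structure while preserving the association
#' count.  Used as the shuffled-label null in evaluation.
#'
#' @param dataset A `synthetic_dataset` (or any list with `associations`,
#'   `diseases`, `mirnas`).
#' @param seed Integer seed for the redraw.
#' @return The dataset with `associations` replaced.
#' @export
shuffle_associations <- function(dataset, seed = 1L) {
  nd <- length(dataset$diseases)
  nm <- length(dataset$mirnas)
  n <- nrow(dataset$associations)
  pick <- with_local_seed(seed, sample.int(nd * nm, n))
  i <- ((pick - 1L) %% nd) + 1L
  j <- ((pick - 1L) %/% nd) + 1L
  dataset$associations <- data.frame(disease = dataset$diseases[i],
                                     mirna = dataset$mirnas[j],
                                     stringsAsFactors = FALSE)
  dataset
}
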