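# Shared in-code fixtures for the test suite.

# Labelled random PSD kernel with entries bounded away from degeneracy.
random_psd <- function(n, prefix, seed) {
  set.seed(seed)
  q <- matrix(runif(n * n, 0.1, 1), n)
  m <- crossprod(q) / n
  ids <- paste0(prefix, seq_len(n))
  dimnames(m) <- list(ids, ids)
  m
}

random_binary_adjacency <- function(nd, nm, seed, p = 0.4) {
  set.seed(seed)
  matrix(rbinom(nd * nm, 1, p), nd, nm,
         dimnames = list(paste0("d", seq_len(nd)), paste0("m", seq_len(nm))))
}

# Two-disease universe: B is a child of A.  The canonical hand-computable
# semantic-similarity fixture.
two_disease_hierarchy <- function() {
  disease_hierarchy(data.frame(child = "B", parent = "A",
                               stringsAsFactors = FALSE))
}

# A small but non-trivial planted dataset for evaluation tests: 8 diseases
# x 10 miRNAs in 2 communities with strong contrast, so the CV machinery
# runs in milliseconds per fold.
tiny_dataset <- function(seed = 7L) {
  generate_associations(synthetic_spec(
    nd = 8L, nm = 10L, n_blocks = 2L,
    within_block_prob = 0.6, background_prob = 0.05,
    hierarchy_depth = 2L, branching = 2L,
    mask_fraction = 0.1, seed = seed))
}

dataset_adjacency <- function(ds) {
  build_adjacency(ds$associations, ds$diseases, ds$mirnas)
}
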