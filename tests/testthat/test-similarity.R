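test_that("DAG contributions follow the geometric-decay and information-content rules", {
  h <- disease_hierarchy(data.frame(child = c("B", "C"), parent = c("A", "B"),
                                    stringsAsFactors = FALSE))
  p <- semantic_params(delta = 0.5)
  counts <- dag_counts(h, c("A", "B", "C"))
  d <- disease_dag(h, "C", p, counts, 3L)
  expect_setequal(d$nodes, c("A", "B", "C"))
  expect_equal(d$contribution1[["C"]], 1)
  expect_equal(d$contribution1[["B"]], 0.5)
  expect_equal(d$contribution1[["A"]], 0.25)
  expect_equal(d$dv1, 1.75)

  # isolated node: DAG is the node itself
  h2 <- disease_hierarchy(data.frame(child = c("B", "X"), parent = c("A", "Y"),
                                     stringsAsFactors = FALSE))
  d2 <- disease_dag(h2, "Y", p, dag_counts(h2, c("Y")), 1L)
  expect_equal(d2$nodes, "Y")
  expect_equal(d2$dv1, 1)

  # two-disease universe: the shared root appears in both DAGs
  h3 <- two_disease_hierarchy()
  c3 <- dag_counts(h3, c("A", "B"))
  expect_equal(c3[["A"]], 2L)
  expect_equal(c3[["B"]], 1L)
  dB <- disease_dag(h3, "B", p, c3, 2L)
  expect_equal(dB$contribution2[["A"]], 0)        # -log(2/2)
  expect_equal(dB$contribution2[["B"]], log(2))   # -log(1/2)
  expect_error(disease_dag(h3, "nope", p, c3, 2L), "not in the hierarchy")
})

test_that("semantic similarity matches hand-computed two-disease values", {
  h <- two_disease_hierarchy()
  p <- semantic_params(delta = 0.5)
  dags <- build_disease_dags(h, c("A", "B"), p)
  ss1 <- semantic_similarity(dags, model = 1)
  expect_equal(ss1["A", "B"], 0.6)                # (1 + 0.5) / (1 + 1.5)
  expect_equal(diag(ss1), c(A = 1, B = 1))
  expect_true(isSymmetric(ss1))

  ss2 <- suppressMessages(semantic_similarity(dags, model = 2))
  expect_equal(ss2["A", "B"], 0)
  expect_equal(diag(ss2), c(A = 1, B = 1))        # degenerate DV2(A)=0 handled

  ss <- combine_semantic(ss1, ss2)
  expect_equal(ss["A", "B"], 0.3)
  expect_equal(combine_semantic(ss1, ss1), ss1)
  expect_error(combine_semantic(ss1, ss2[2:1, 2:1]), "mismatch")
})

test_that("model-2 similarity is invariant to the logarithm base", {
  ds <- tiny_dataset()
  diseases <- ds$diseases
  d_e <- build_disease_dags(ds$hierarchy, diseases, semantic_params(log_base = exp(1)))
  d_2 <- build_disease_dags(ds$hierarchy, diseases, semantic_params(log_base = 2))
  s_e <- suppressMessages(semantic_similarity(d_e, 2, diseases))
  s_2 <- suppressMessages(semantic_similarity(d_2, 2, diseases))
  expect_lt(max(abs(s_e - s_2)), 1e-10)
})

test_that("model-1 similarity ignores hierarchy edge insertion order", {
  ds <- tiny_dataset()
  e <- ds$hierarchy$edges
  h_rev <- disease_hierarchy(e[rev(seq_len(nrow(e))), ])
  p <- semantic_params()
  s1 <- semantic_similarity(build_disease_dags(ds$hierarchy, ds$diseases, p), 1, ds$diseases)
  s2 <- semantic_similarity(build_disease_dags(h_rev, ds$diseases, p), 1, ds$diseases)
  expect_equal(s1, s2)
})

test_that("diseases absent from the hierarchy get identity-like semantic rows", {
  h <- two_disease_hierarchy()
  dags <- build_disease_dags(h, c("A", "B", "Z"), semantic_params())
  ss1 <- semantic_similarity(dags, 1, c("A", "B", "Z"))
  expect_equal(ss1["Z", "Z"], 1)
  expect_equal(ss1["Z", "A"], 0)
  expect_equal(ss1["B", "Z"], 0)
})

test_that("functional similarity implements the group-max rule", {
  ss <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  # m1 associated with A only, m2 with B only
  a <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("A", "B"), c("m1", "m2")))
  fs <- mirna_functional_similarity(a, ss)
  expect_equal(fs["m1", "m2"], 0.6)               # (0.6 + 0.6) / 2
  expect_equal(diag(fs), c(m1 = 1, m2 = 1))

  # identical one-disease groups
  a2 <- matrix(c(1, 0, 1, 0), 2, dimnames = list(c("A", "B"), c("m1", "m2")))
  expect_equal(mirna_functional_similarity(a2, ss)["m1", "m2"], 1)

  # disjoint groups with zero cross-similarity, and an empty group
  ss0 <- diag(2); dimnames(ss0) <- dimnames(ss)
  expect_equal(mirna_functional_similarity(a, ss0)["m1", "m2"], 0)
  a3 <- matrix(c(1, 0, 0, 0), 2, dimnames = list(c("A", "B"), c("m1", "m2")))
  fs3 <- mirna_functional_similarity(a3, ss)
  expect_equal(fs3["m1", "m2"], 0)
  expect_equal(fs3["m2", "m2"], 1)
})

test_that("Gaussian profile kernel matches the hand-computed 2x2 case", {
  a <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("d1", "d2"), c("m1", "m2")))
  kd <- gaussian_kernel(a, "disease")
  expect_equal(diag(kd), c(d1 = 1, d2 = 1))
  expect_equal(kd["d1", "d2"], exp(-2), tolerance = 1e-12)

  z <- matrix(0, 2, 2, dimnames = dimnames(a))
  expect_error(gaussian_kernel(z, "disease"), "bandwidth undefined")
})

test_that("kernel similarity decreases with profile Hamming distance", {
  a <- random_binary_adjacency(6, 20, seed = 5)
  km <- gaussian_kernel(a, "mirna")
  ham <- as.matrix(dist(t(a), method = "manhattan"))
  off <- upper.tri(km)
  o <- order(ham[off])
  k_sorted <- km[off][o]
  h_sorted <- ham[off][o]
  # strictly smaller Hamming distance implies strictly larger kernel value
  violations <- sum(diff(k_sorted) > 1e-14 & diff(h_sorted) > 0)
  expect_equal(violations, 0L)
})

test_that("adding a shared association leaves the kernel entry unchanged, a one-sided one lowers it", {
  # effective bandwidth used by gaussian_kernel on the miRNA axis
  attr_gamma <- function(a) 1 / mean(colSums(a^2))
  a <- random_binary_adjacency(8, 6, seed = 9, p = 0.3)
  a[1, 1] <- 0; a[1, 2] <- 0
  d2_before <- sum((a[, 1] - a[, 2])^2)
  shared <- a; shared[1, 1] <- 1; shared[1, 2] <- 1
  expect_equal(sum((shared[, 1] - shared[, 2])^2), d2_before)
  onesided <- a; onesided[1, 1] <- 1
  expect_gt(sum((onesided[, 1] - onesided[, 2])^2), d2_before)
  km_a <- gaussian_kernel(a, "mirna")
  km_s <- gaussian_kernel(shared, "mirna")
  # same squared distance, but the bandwidth renormalizes with density
  expect_equal(log(km_s[1, 2]) / attr_gamma(shared), log(km_a[1, 2]) / attr_gamma(a))
})

test_that("integration is the entrywise mean and preserves unit diagonals", {
  ds <- tiny_dataset()
  a <- dataset_adjacency(ds)
  p <- semantic_params()
  ss <- combine_semantic(
    semantic_similarity(build_disease_dags(ds$hierarchy, ds$diseases, p), 1, ds$diseases),
    suppressMessages(semantic_similarity(build_disease_dags(ds$hierarchy, ds$diseases, p), 2, ds$diseases)))
  kd <- gaussian_kernel(a, "disease")
  sd_ <- integrate_similarity(ss, kd)
  expect_equal(sd_, (ss + kd) / 2)
  expect_equal(unname(diag(sd_)), rep(1, nrow(sd_)))
  expect_equal(integrate_similarity(kd, kd), kd)
  expect_error(integrate_similarity(ss, kd[2:1, ]), "mismatch")

  # the worked fixture: SD entry = (0.6 + exp(-2)) / 2
  expect_equal((0.6 + exp(-2)) / 2, 0.3676676416183064, tolerance = 1e-12)
})

test_that("every produced similarity matrix is symmetric with entries in [0, 1]", {
  ds <- tiny_dataset()
  a <- dataset_adjacency(ds)
  out <- mda_predict(a, ds$hierarchy, keep_intermediates = TRUE)
  for (nm in c("ss1", "ss2", "ss", "kd", "km", "fs", "sd", "sm")) {
    m <- out[[nm]]
    expect_lt(max(abs(m - t(m))), 1e-10)
    expect_gte(min(m), 0)
    expect_lte(max(m), 1 + 1e-10)
  }
})
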