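test_that("symmetric eigendecomposition reconstructs and sorts descending", {
  m <- random_psd(6, "d", 1) - 0.2  # make some eigenvalues negative
  m <- (m + t(m)) / 2
  e <- eigendecompose_sym(m)
  expect_lt(max(abs(crossprod(e$vectors) - diag(6))), 1e-8)
  expect_lt(max(abs(e$vectors %*% diag(e$values) %*% t(e$vectors) - m)), 1e-10)
  expect_equal(e$values, sort(e$values, decreasing = TRUE))
  expect_error(eigendecompose_sym(matrix(1:4, 2)), "not symmetric")

  id <- diag(4)
  expect_equal(eigendecompose_sym(id)$values, rep(1, 4))
})

test_that("the scalar problem matches the closed form st*y/(st+lam)", {
  for (s in c(0.5, 1, 2)) for (t_ in c(0.3, 1)) for (y in c(0, 1)) {
    sd_ <- matrix(s, 1, 1, dimnames = list("d", "d"))
    sm_ <- matrix(t_, 1, 1, dimnames = list("m", "m"))
    a <- matrix(y, 1, 1, dimnames = list("d", "m"))
    expect_equal(kronrls_direct(sd_, sm_, a)[1, 1], s * t_ * y / (s * t_ + 1),
                 tolerance = 1e-12)
    expect_equal(kronrls_solve(sd_, sm_, a)[1, 1], s * t_ * y / (s * t_ + 1),
                 tolerance = 1e-12)
  }
})

test_that("spectral and direct solvers agree on random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    nd <- sample(2:6, 1); nm <- sample(2:6, 1)
    sd_ <- random_psd(nd, "d", seed * 3 + 1)
    sm_ <- random_psd(nm, "m", seed * 3 + 2)
    a <- random_binary_adjacency(nd, nm, seed * 3)
    dimnames(sd_) <- list(rownames(a), rownames(a))
    dimnames(sm_) <- list(colnames(a), colnames(a))
    s1 <- kronrls_solve(sd_, sm_, a)
    s2 <- kronrls_direct(sd_, sm_, a)
    expect_lt(max(abs(s1 - s2)), 1e-8)
  }
})

test_that("identity kernels with lam = 1 shrink the adjacency exactly by half", {
  set.seed(13)
  a <- random_binary_adjacency(7, 9, 13)
  id_d <- diag(7); dimnames(id_d) <- list(rownames(a), rownames(a))
  id_m <- diag(9); dimnames(id_m) <- list(colnames(a), colnames(a))
  expect_equal(kronrls_solve(id_d, id_m, a), a / 2, tolerance = 1e-12)
})

test_that("the solver is linear in A, contractive, and shrinks with lam", {
  sd_ <- random_psd(5, "d", 61)
  sm_ <- random_psd(6, "m", 62)
  set.seed(63)
  a1 <- matrix(runif(30), 5, 6, dimnames = list(rownames(sd_), rownames(sm_)))
  a2 <- matrix(runif(30), 5, 6, dimnames = dimnames(a1))
  s12 <- kronrls_solve(sd_, sm_, a1 + a2)
  expect_lt(max(abs(s12 - kronrls_solve(sd_, sm_, a1) - kronrls_solve(sd_, sm_, a2))), 1e-9)

  ab <- random_binary_adjacency(5, 6, 64)
  dimnames(ab) <- dimnames(a1)
  expect_lte(norm(kronrls_solve(sd_, sm_, ab), "F"), norm(ab, "F"))

  # every spectral coefficient shrinks monotonically with lam, so the
  # Frobenius norm of S does too
  s_by_lam <- vapply(c(0.1, 1, 10), function(l) {
    norm(kronrls_solve(sd_, sm_, ab, kronrls_params(l)), "F")
  }, 1)
  expect_true(all(diff(s_by_lam) < 0))

  # ridge limit: huge lam drives scores to zero
  s_big <- kronrls_solve(sd_, sm_, ab, kronrls_params(1e6))
  expect_lt(max(abs(s_big)), 1e-3 * max(abs(ab)))

  # zero adjacency maps to zero scores
  z <- ab * 0
  expect_equal(max(abs(kronrls_direct(sd_, sm_, z))), 0)

  expect_error(kronrls_params(-1))
  expect_error(kronrls_solve(sd_, sm_, ab[, 6:1]), "labels")
  expect_error(kronrls_direct(random_psd(50, "d", 1), random_psd(50, "m", 2),
                              matrix(0, 50, 50, dimnames = list(
                                rownames(random_psd(50, "d", 1)),
                                rownames(random_psd(50, "m", 2))))),
               "small-problem")
})

test_that("the full pipeline is deterministic and permutation-equivariant", {
  ds <- tiny_dataset()
  a <- dataset_adjacency(ds)
  cfg <- mda_config(seed = 11)
  s1 <- mda_predict(a, ds$hierarchy, config = cfg)
  s2 <- mda_predict(a, ds$hierarchy, config = cfg)
  expect_identical(s1, s2)

  set.seed(99)
  pd <- sample(nrow(a)); pm <- sample(ncol(a))
  s_perm <- mda_predict(a[pd, pm], ds$hierarchy, config = cfg)
  expect_lt(max(abs(s_perm - s1[pd, pm])), 1e-8)
})

test_that("planted associations outscore null pairs and masking a disease still ranks its truth", {
  ds <- tiny_dataset()
  a <- dataset_adjacency(ds)
  truth <- build_adjacency(ds$truth, ds$diseases, ds$mirnas)
  masked <- build_adjacency(ds$masked, ds$diseases, ds$mirnas)
  s <- mda_predict(a, ds$hierarchy)
  expect_gt(mean(s[masked == 1]), mean(s[truth == 0]))

  d <- rownames(a)[which.max(rowSums(a))]
  ranked <- predict_new_disease(a, ds$hierarchy, disease = d)
  expect_equal(nrow(ranked), ncol(a))
  expect_setequal(ranked$mirna, colnames(a))
  expect_equal(ranked$rank, seq_len(ncol(a)))
  expect_error(predict_new_disease(a, ds$hierarchy, disease = "missing"),
               "unknown disease")

  # a disease with no associations: masking its row is a no-op
  a0 <- a
  a0[d, ] <- 0
  s0 <- mda_predict(a0, ds$hierarchy)
  ranked0 <- predict_new_disease(a0, ds$hierarchy, disease = d)
  expect_equal(ranked0$score, unname(sort(s0[d, ], decreasing = TRUE)))
})

test_that("kernel fallback and interpolation bypass behave as configured", {
  h <- two_disease_hierarchy()
  a <- matrix(c(1, 0, 0, 0, 1, 0, 0, 1, 1), 3, 3,
              dimnames = list(c("A", "B", "Z"), c("m1", "m2", "m3")))
  out <- suppressMessages(
    mda_predict(a, h, config = mda_config(), keep_intermediates = TRUE))
  fb <- suppressMessages(
    mda_predict(a, h, config = mda_config(kernel_fallback = TRUE),
                keep_intermediates = TRUE))
  # Z has no DAG: with the fallback its pairs take the kernel value alone
  expect_equal(fb$sd["Z", "A"], fb$kd["Z", "A"])
  expect_equal(out$sd["Z", "A"], (0 + out$kd["Z", "A"]) / 2)
  # pairs with DAGs on both sides are untouched
  expect_equal(fb$sd["A", "B"], out$sd["A", "B"])

  raw <- suppressMessages(suppressWarnings(
    mda_predict(a, h, config = mda_config(interpolate = FALSE),
                keep_intermediates = TRUE)))
  expect_identical(raw$sd_star, raw$sd)
  expect_identical(raw$sm_star, raw$sm)
  expect_false(identical(out$sd_star, out$sd))
})
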