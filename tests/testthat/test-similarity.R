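# chain ontology d -> p -> r plus a sibling for pairwise fixtures
chain_forest <- function() {
  ontology_forest(rbind(c("d1", "r"), c("d2", "r")),
                  terms = c("d1", "d2", "d3", "r"),
                  disease_to_term = c(d1 = "d1", d2 = "d2", d3 = "d3"))
}

test_that("model-1 contributions decay by DAG level, max not sum", {
  single <- ontology_forest(matrix(character(), 0, 2), terms = "D",
                            disease_to_term = c(D = "D"))
  expect_identical(
    semantic_contributions_model1(disease_dag(single, "D"), 0.5), c(D = 1))

  chain <- ontology_forest(rbind(c("D", "p"), c("p", "r")),
                           disease_to_term = c(D = "D"))
  expect_equal(
    semantic_contributions_model1(disease_dag(chain, "D"), 0.5),
    c(D = 1, p = 0.5, r = 0.25)
  )

  diamond <- ontology_forest(rbind(c("D", "x"), c("D", "y"),
                                   c("x", "r"), c("y", "r")),
                             disease_to_term = c(D = "D"))
  contrib <- semantic_contributions_model1(disease_dag(diamond, "D"), 0.5)
  expect_equal(contrib[["r"]], 0.25)  # max over the two paths, not 0.5
})

test_that("model-1 contributions match the brute-force path-max oracle", {
  for (s in 1:10) {
    syn <- generate_synthetic(synthetic_config(
      n_d = 8, n_m = 8, k = 2, dag_depth = 4, dag_shape = "random", seed = s))
    d <- syn$dataset$disease_ids[1]
    dag <- disease_dag(syn$ontology, d)
    contrib <- semantic_contributions_model1(dag, 0.5)
    for (t in dag$terms) {
      expect_equal(contrib[[t]],
                   oracle_contribution_model1(dag$edges, dag$term, t, 0.5),
                   tolerance = 1e-12)
    }
    # definitional recurrence: each non-leaf term equals delta times the
    # maximum contribution among its children within the DAG
    for (p in setdiff(dag$terms, dag$term)) {
      children <- dag$edges[dag$edges[, 2] == p, 1]
      if (length(children) > 0) {
        expect_equal(contrib[[p]], 0.5 * max(contrib[children]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("model-1 similarity: identical DAGs 1, shared-root fixture 1/3, disjoint 0", {
  fo <- chain_forest()
  g1 <- disease_dag(fo, "d1")
  g2 <- disease_dag(fo, "d2")
  g3 <- disease_dag(fo, "d3")
  expect_equal(semantic_similarity_model1(g1, g1, 0.5), 1)
  expect_equal(semantic_similarity_model1(g1, g2, 0.5), 1 / 3,
               tolerance = 1e-12)
  expect_equal(semantic_similarity_model1(g1, g3, 0.5), 0)
})

test_that("model-2 contributions are DAG-frequency information content", {
  fo <- chain_forest()
  dags <- lapply(c("d1", "d2", "d3"), disease_dag, forest = fo)
  contrib <- semantic_contributions_model2(dags)
  expect_equal(contrib[["r"]], -log(2 / 3), tolerance = 1e-12)   # in 2 of 3
  expect_equal(contrib[["d1"]], -log(1 / 3), tolerance = 1e-12)  # in 1 of 3
  # a ubiquitous term contributes nothing
  all3 <- ontology_forest(rbind(c("a", "r"), c("b", "r"), c("c", "r")),
                          disease_to_term = c(a = "a", b = "b", c = "c"))
  dags3 <- lapply(c("a", "b", "c"), disease_dag, forest = all3)
  expect_equal(semantic_contributions_model2(dags3)[["r"]], 0)
})

test_that("model-2 similarity matches the hand evaluation and its edge cases", {
  fo <- chain_forest()
  dags <- lapply(c("d1", "d2", "d3"), disease_dag, forest = fo)
  contrib <- semantic_contributions_model2(dags)
  expected <- 2 * (-log(2 / 3)) / (2 * (-log(1 / 3) - log(2 / 3)))
  expect_equal(semantic_similarity_model2(dags[[1]], dags[[2]], contrib),
               expected, tolerance = 1e-10)
  expect_equal(expected, 0.2696, tolerance = 1e-4)
  expect_equal(semantic_similarity_model2(dags[[1]], dags[[1]], contrib), 1)
  expect_equal(semantic_similarity_model2(dags[[1]], dags[[3]], contrib), 0)
  # all terms ubiquitous: both diseases map to the shared root only, so
  # every semantic value is zero: warn and return 0
  same <- ontology_forest(matrix(character(), 0, 2), terms = "r",
                          disease_to_term = c(a = "r", b = "r"))
  dsame <- lapply(c("a", "b"), disease_dag, forest = same)
  csame <- semantic_contributions_model2(dsame)
  expect_warning(
    expect_equal(semantic_similarity_model2(dsame[[1]], dsame[[2]], csame), 0),
    "ubiquitous"
  )
})

test_that("GIP kernel matches the closed form and its algebraic identities", {
  A <- toy_dataset()$A
  K <- gip_similarity(A, 1)
  expect_equal(K["d1", "d2"], exp(-2), tolerance = 1e-12)
  expect_equal(diag(K), c(d1 = 1, d2 = 1))

  # identical profiles are maximally similar
  B <- rbind(p1 = c(1, 0, 1), p2 = c(1, 0, 1), p3 = c(0, 1, 0))
  expect_equal(gip_similarity(B, 1)["p1", "p2"], 1)

  # doubling gamma' squares the off-diagonal entries
  set.seed(7)
  P <- matrix(rbinom(30, 1, 0.4), 5, 6)
  P[1, 1] <- 1
  rownames(P) <- paste0("p", 1:5)
  K1 <- gip_similarity(P, 1)
  K2 <- gip_similarity(P, 2)
  off <- row(K1) != col(K1)
  expect_equal(K2[off], K1[off]^2, tolerance = 1e-12)

  expect_error(gip_similarity(matrix(0, 3, 4), 1), "zero")
})

test_that("GIP similarity is monotone in Hamming distance at fixed bandwidth", {
  set.seed(11)
  for (rep in 1:20) {
    base <- rbinom(12, 1, 0.5)
    k1 <- sample(0:6, 1); k2 <- sample(0:6, 1)
    flip <- function(v, k) {
      idx <- sample(12, k)
      v[idx] <- 1 - v[idx]
      v
    }
    P <- rbind(a = base, b = flip(base, k1), c = flip(base, k2))
    if (all(P == 0)) next
    K <- gip_similarity(P, 1)
    h_ab <- sum(P["a", ] != P["b", ])
    h_ac <- sum(P["a", ] != P["c", ])
    if (h_ab > h_ac) expect_lte(K["a", "b"], K["a", "c"])
    if (h_ab < h_ac) expect_gte(K["a", "b"], K["a", "c"])
  }
})

test_that("integration picks the semantic mean or the kernel fallback", {
  SS1 <- matrix(c(1, 1 / 3, 1 / 3, 1), 2, 2)
  SS2 <- matrix(c(1, 0.2696, 0.2696, 1), 2, 2)
  KD <- matrix(c(1, 0.1353, 0.1353, 1), 2, 2)
  ids <- c("d1", "d2")
  dimnames(SS1) <- dimnames(SS2) <- dimnames(KD) <- list(ids, ids)

  SD <- integrate_disease_similarity(SS1, SS2, KD, c(d1 = TRUE, d2 = TRUE))
  expect_equal(SD["d1", "d2"], (1 / 3 + 0.2696) / 2, tolerance = 1e-12)
  expect_equal(diag(SD), c(d1 = 1, d2 = 1))

  SD2 <- integrate_disease_similarity(SS1, SS2, KD, c(d1 = TRUE, d2 = FALSE))
  expect_equal(SD2["d1", "d2"], 0.1353)
  expect_error(integrate_disease_similarity(SS1[1, 1, drop = FALSE], SS2, KD,
                                            c(TRUE, TRUE)), "dimensions")

  FS <- matrix(c(1, 0.7, 0.7, 1), 2, 2,
               dimnames = list(c("m1", "m2"), c("m1", "m2")))
  KM <- matrix(c(1, 0.4, 0.4, 1), 2, 2,
               dimnames = list(c("m1", "m2"), c("m1", "m2")))
  expect_equal(integrate_mirna_similarity(FS, KM)["m1", "m2"], 0.7)
  expect_equal(integrate_mirna_similarity(NULL, KM)["m1", "m2"], 0.4)
  FS1 <- FS[1, 1, drop = FALSE]  # m2 absent from FS: fallback pairwise
  expect_equal(integrate_mirna_similarity(FS1, KM)["m1", "m2"], 0.4)
  # fully populated FS wins everywhere
  expect_equal(integrate_mirna_similarity(FS, KM), FS)
})

test_that("similarity bundles are symmetric, bounded and unit-diagonal", {
  for (s in 1:5) {
    syn <- generate_synthetic(synthetic_config(n_d = 10, n_m = 12, k = 3,
                                               seed = s))
    sims <- compute_similarities(syn$dataset, syn$ontology, syn$fs)
    for (nm in c("SS1", "SS2", "KD", "KM", "SD", "SM")) {
      M <- sims[[nm]]
      expect_lte(max(abs(M - t(M))), 1e-12)
      expect_gte(min(M), 0)
      expect_lte(max(M), 1 + 1e-12)
    }
    expect_equal(unname(diag(sims$SS1)), rep(1, 10))
    expect_equal(unname(diag(sims$KD)), rep(1, 10))
    expect_equal(unname(diag(sims$KM)), rep(1, 12))
  }
})
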