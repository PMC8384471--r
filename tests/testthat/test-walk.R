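fixture_tm <- function(lambda = 0.5) {
  A <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("d1", "d2"), c("m1", "m2")))
  net <- build_network(matrix(c(1, 0.5, 0.5, 1), 2, 2), diag(2), A)
  build_transition(net, degree_vectors(net), lambda)
}

test_that("seed vector splits mass between the disease and its known miRNAs", {
  ds <- association_dataset(
    c("d1", "d2"), c("m1", "m2", "m3", "m4"),
    rbind(c(1, 0, 1, 0), c(0, 1, 0, 0))
  )
  p0 <- seed_vector(ds, "d1", alpha = 0.5)
  expect_equal(unname(p0), c(0.5, 0, 0.25, 0, 0.25, 0))
  expect_equal(sum(p0), 1)

  expect_equal(unname(seed_vector(ds, "d1", alpha = 1)),
               c(1, 0, 0, 0, 0, 0))
  p0_m <- seed_vector(ds, "d1", alpha = 0)
  expect_equal(unname(p0_m), c(0, 0, 0.5, 0, 0.5, 0))

  ds_new <- association_dataset(c("d1", "d2"), c("m1", "m2"),
                                rbind(c(1, 1), c(0, 0)))
  expect_error(seed_vector(ds_new, "d2"), "new disease")
  expect_error(seed_vector(ds, "nope"), "unknown disease")
})

test_that("a restart probability near one pins the walk to the seed", {
  tm <- fixture_tm()
  p0 <- seed_vector(toy_dataset(), "d1")
  res <- iterate_walk(tm, p0, walk_params(delta = 1 - 1e-12))
  expect_equal(unname(res$p), unname(p0), tolerance = 1e-9)
})

test_that("a fixed point of the propagation converges immediately", {
  # regular similarity blocks + identity associations give a doubly
  # stochastic M, whose fixed point under t(M) is the uniform vector
  A <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("d1", "d2"), c("m1", "m2")))
  net <- build_network(matrix(c(1, 0.5, 0.5, 1), 2, 2),
                       matrix(c(1, 0.5, 0.5, 1), 2, 2), A)
  tm <- build_transition(net, constant_bias(net), 0.5)
  expect_lte(max(abs(colSums(tm$M) - 1)), 1e-12)
  p0 <- rep(0.25, 4)
  res <- iterate_walk(tm, p0, walk_params(tol = 1e-12))
  expect_equal(res$iterations, 1)
  expect_equal(res$p, p0, ignore_attr = TRUE)
})

test_that("the iterator matches the closed-form stationary solve", {
  tm <- fixture_tm()
  p0 <- seed_vector(toy_dataset(), "d1")
  for (delta in c(0.3, 0.7, 0.9)) {
    it <- iterate_walk(tm, p0, walk_params(delta = delta, tol = 1e-12))
    cf <- solve_stationary(tm, p0, delta)
    expect_equal(it$p, cf, tolerance = 1e-8)
    expect_equal(sum(cf), 1, tolerance = 1e-9)
  }
})

test_that("iterate and solve agree on 50 random networks", {
  for (s in 1:50) {
    net <- random_network(4, 6, seed = 200 + s)
    # guarantee a seedable disease
    net$Wdm[1, 1] <- 1
    tm <- build_transition(net, degree_vectors(net), 0.4)
    ds <- association_dataset(net$disease_ids, net$mirna_ids, net$Wdm)
    p0 <- seed_vector(ds, net$disease_ids[1])
    it <- iterate_walk(tm, p0, walk_params(tol = 1e-12))
    expect_equal(it$p, solve_stationary(tm, p0, 0.7), tolerance = 1e-8)
    expect_equal(sum(it$p), 1, tolerance = 1e-9)
  }
})

test_that("every iterate conserves probability and contracts in L1", {
  tm <- fixture_tm()
  p0 <- seed_vector(toy_dataset(), "d1")
  delta <- 0.7
  P <- t(tm$M)
  p <- p0
  resid_prev <- Inf
  for (i in 1:30) {
    p_next <- as.vector((1 - delta) * (P %*% p)) + delta * p0
    expect_equal(sum(p_next), 1, tolerance = 1e-9)
    resid <- sum(abs(p_next - p))
    expect_lte(resid, resid_prev + 1e-15)
    resid_prev <- resid
    p <- p_next
  }
  # geometric contraction bounds the iteration count
  res <- iterate_walk(tm, p0, walk_params(delta = delta, tol = 1e-6))
  expect_lte(res$iterations, ceiling(log(1e-6) / log(1 - delta)) + 1)
})

test_that("hitting the iteration cap raises a condition carrying the state", {
  tm <- fixture_tm()
  p0 <- seed_vector(toy_dataset(), "d1")
  err <- tryCatch(
    iterate_walk(tm, p0, walk_params(delta = 0.1, tol = 1e-14, max_iter = 2)),
    walk_no_convergence = function(e) e
  )
  expect_s3_class(err, "walk_no_convergence")
  expect_length(err$p, 4)
  expect_gt(err$residual, 0)
})

test_that("the literal orientation propagates along columns instead", {
  tm <- fixture_tm()
  p0 <- seed_vector(toy_dataset(), "d1")
  lit <- iterate_walk(tm, p0, walk_params(tol = 1e-12),
                      literal_orientation = TRUE)
  expect_equal(lit$p,
               solve_stationary(tm, p0, 0.7, literal_orientation = TRUE),
               tolerance = 1e-8)
})

test_that("candidate ranking excludes known miRNAs and breaks ties by id", {
  ds <- association_dataset(
    c("d1", "d2"), c("m1", "m2", "m3", "m4"),
    rbind(c(1, 0, 0, 0), c(0, 1, 1, 1))
  )
  p <- c("d:d1" = 0.4, "d:d2" = 0.1, "m:m1" = 0.3, "m:m2" = 0.05,
         "m:m3" = 0.1, "m:m4" = 0.05)
  r <- rank_candidates(p, ds, "d1")
  expect_false("m1" %in% r$mirna_id)               # known: excluded
  expect_equal(r$mirna_id[1], "m3")                # highest candidate score
  expect_equal(r$mirna_id[2:3], c("m2", "m4"))     # tie broken by id
  expect_equal(r$rank, 1:3)
  expect_true(all(diff(r$score) <= 0))
  expect_equal(attr(r, "excluded"), "m1")
})

test_that("end-to-end prediction is deterministic and favours the planted cluster", {
  syn <- generate_synthetic(synthetic_config(n_d = 12, n_m = 18, k = 3,
                                             seed = 5))
  d <- syn$dataset$disease_ids[1]
  r1 <- predict_mirnas(syn$dataset, d, syn$ontology, syn$fs)
  r2 <- predict_mirnas(syn$dataset, d, syn$ontology, syn$fs)
  expect_identical(r1, r2)
  expect_equal(predict_mirnas(syn$dataset, d, syn$ontology, syn$fs,
                              method = "solve")$score,
               r1$score, tolerance = 1e-6)
  # same-cluster candidates outscore other-cluster candidates on average
  cl <- syn$mirna_clusters[r1$mirna_id]
  same <- cl == syn$disease_clusters[[d]]
  if (any(same) && any(!same)) {
    expect_gt(mean(r1$score[same]), mean(r1$score[!same]))
  }
})
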