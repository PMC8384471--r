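# Midrank of the held-out score among all candidate scores (ties share the
# average rank); scores ordered descending.
midrank_of <- function(scores, target) {
  r <- rank(-scores, ties.method = "average")
  unname(r[target])
}

#' Fold-level AUC from rank records
#'
#' Each fold records the midrank `r` of the held-out positive among `N`
#' candidates (the positive plus `N - 1` negatives). The fold AUC
#' `(N - r) / (N - 1)` is the Mann-Whitney statistic: the probability that
#' the positive outscores a random negative, ties counting one half. The
#' pooled AUC weighs every fold equally.
#'
#' @param folds data frame with numeric columns `rank` and `n_candidates`.
#' @return Pooled AUC in [0, 1].
#' @export
auc_from_folds <- function(folds) {
  if (nrow(folds) == 0) stop("no folds to compute an AUC from")
  mean((folds$n_candidates - folds$rank) / (folds$n_candidates - 1))
}

#' Pooled ROC curve over LOOCV folds
#'
#' Sweeps a normalised rank-percentile threshold `t` over [0, 1]: a fold is
#' a true positive at `t` when its held-out item sits within the top
#' fraction `t` of its candidate list, and the fold's false positive rate is
#' the fraction of its negatives within that same cut. Folds contribute
#' equally regardless of candidate-list size.
#'
#' @param folds data frame with columns `rank`, `n_candidates`.
#' @param grid_size number of interior thresholds (the fold positions are
#'   always included).
#' @return Data frame with columns `fpr`, `tpr`, starting at (0, 0) and
#'   ending at (1, 1), both coordinates non-decreasing.
#' @export
pooled_roc <- function(folds, grid_size = 200) {
  if (nrow(folds) == 0) stop("no folds to build a ROC from")
  q_pos <- (folds$rank - 1) / (folds$n_candidates - 1)
  thresholds <- sort(unique(c(0, q_pos, seq(0, 1, length.out = grid_size + 1), 1)))
  eps <- 1e-12
  tpr <- vapply(thresholds, function(t) mean(q_pos <= t + eps), 0)
  fpr <- vapply(thresholds, function(t) {
    mean(mapply(function(r, N) {
      q_all <- (seq_len(N) - 1) / (N - 1)
      inside <- sum(q_all <= t + eps)
      pos_inside <- (r - 1) / (N - 1) <= t + eps
      (inside - as.numeric(pos_inside)) / (N - 1)
    }, folds$rank, folds$n_candidates))
  }, 0)
  out <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  out <- out[order(out$fpr, out$tpr), ]
  out <- out[!duplicated(out), ]
  rownames(out) <- NULL
  out
}

# Build per-fold candidate scores for one masked dataset and one disease.
fold_scores <- function(scorer, dataset_masked, disease, tm_builder,
                        walk, rng) {
  candidates <- dataset_masked$mirna_ids[dataset_masked$A[disease, ] == 0]
  scores <- switch(scorer,
    brwr = {
      tm <- tm_builder()
      p0 <- seed_vector(dataset_masked, disease, walk$alpha)
      p <- iterate_walk(tm, p0, walk)$p
      stats::setNames(p[paste0("m:", candidates)], candidates)
    },
    degree = stats::setNames(colSums(dataset_masked$A)[candidates], candidates),
    random = stats::setNames(rng(length(candidates)), candidates)
  )
  scores
}

#' Local leave-one-out cross-validation
#'
#' Each known association of every disease with at least two known miRNAs
#' is held out in turn: the association is masked from `A`, the kernel
#' similarities are recomputed from the masked matrix (unless
#' `recompute_gip = FALSE`), the walk is run seeded at the disease, and the
#' held-out miRNA's midrank among all miRNAs unobserved for that disease
#' (plus itself) is recorded. Diseases with a single known miRNA are skipped
#' because masking would leave no seed.
#'
#' @param dataset an [association_dataset()].
#' @param ontology optional [ontology_forest()].
#' @param fs optional miRNA functional similarity matrix.
#' @param walk a [walk_params()].
#' @param semantic a [semantic_params()].
#' @param gip a [gip_params()].
#' @param recompute_gip recompute the Gaussian kernels from the masked
#'   association matrix in every fold (default) or freeze the full-data
#'   similarities for speed.
#' @param bias `"degree"` or `"constant"`.
#' @param scorer `"brwr"` (the model), `"degree"` (rank by miRNA degree) or
#'   `"random"` (seeded uniform scores) for baseline comparisons.
#' @param seed RNG seed for the `"random"` scorer.
#' @return An object of class `loocv_result`: list with `folds` (data frame
#'   of `disease_id`, `mirna_id`, `rank`, `n_candidates`), `roc`, `auc`,
#'   `skipped` (diseases left out for having < 2 known miRNAs).
#' @export
run_local_loocv <- function(dataset, ontology = NULL, fs = NULL,
                            walk = walk_params(),
                            semantic = semantic_params(), gip = gip_params(),
                            recompute_gip = TRUE,
                            bias = c("degree", "constant"),
                            scorer = c("brwr", "degree", "random"),
                            seed = 1L) {
  stopifnot(inherits(dataset, "association_dataset"))
  bias <- match.arg(bias)
  scorer <- match.arg(scorer)
  A <- dataset$A
  known_per_disease <- rowSums(A)
  eligible <- dataset$disease_ids[known_per_disease >= 2]
  skipped <- dataset$disease_ids[known_per_disease %in% c(0, 1)]
  pairs <- which(A == 1, arr.ind = TRUE)
  pairs <- pairs[dataset$disease_ids[pairs[, 1]] %in% eligible, , drop = FALSE]
  if (nrow(pairs) == 0) {
    stop("no eligible LOOCV fold: every disease has fewer than 2 known miRNAs")
  }

  # semantic similarity does not depend on A: compute once
  if (is.null(ontology)) {
    nd <- length(dataset$disease_ids)
    SS1 <- SS2 <- matrix(0, nd, nd,
                         dimnames = list(dataset$disease_ids,
                                         dataset$disease_ids))
    has_semantic <- stats::setNames(rep(FALSE, nd), dataset$disease_ids)
  } else {
    sem <- semantic_similarity_matrices(ontology, dataset$disease_ids, semantic)
    SS1 <- sem$SS1; SS2 <- sem$SS2; has_semantic <- sem$has_semantic
  }
  has_functional <- stats::setNames(
    if (is.null(fs)) rep(FALSE, length(dataset$mirna_ids))
    else dataset$mirna_ids %in% rownames(fs),
    dataset$mirna_ids
  )
  if (!recompute_gip) {
    KD0 <- gip_similarity(A, gip$gamma_d_prime)
    KM0 <- gip_similarity(t(A), gip$gamma_m_prime)
    SD0 <- integrate_disease_similarity(SS1, SS2, KD0, has_semantic)
    SM0 <- integrate_mirna_similarity(fs, KM0, has_functional)
  }

  rng_state <- function(n) stats::runif(n)
  if (scorer == "random") set.seed(seed)

  records <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    d_id <- dataset$disease_ids[i]
    m_id <- dataset$mirna_ids[j]
    A2 <- A
    A2[i, j] <- 0
    ds2 <- association_dataset(dataset$disease_ids, dataset$mirna_ids, A2)
    if (recompute_gip) {
      KD <- gip_similarity(A2, gip$gamma_d_prime)
      KM <- gip_similarity(t(A2), gip$gamma_m_prime)
      SD <- integrate_disease_similarity(SS1, SS2, KD, has_semantic)
      SM <- integrate_mirna_similarity(fs, KM, has_functional)
    } else {
      SD <- SD0; SM <- SM0
    }
    tm_builder <- function() {
      net <- build_network(SD, SM, A2)
      b <- if (bias == "degree") degree_vectors(net) else constant_bias(net)
      build_transition(net, b, walk$lambda)
    }
    scores <- fold_scores(scorer, ds2, d_id, tm_builder, walk, rng_state)
    records[[k]] <- data.frame(
      disease_id = d_id, mirna_id = m_id,
      rank = midrank_of(scores, m_id),
      n_candidates = length(scores),
      stringsAsFactors = FALSE
    )
  }
  folds <- do.call(rbind, records)
  structure(
    list(folds = folds, roc = pooled_roc(folds), auc = auc_from_folds(folds),
         skipped = skipped),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("loocv_result: %d folds, AUC = %.4f (%d disease(s) skipped)\n",
              nrow(x$folds), x$auc, length(x$skipped)))
  invisible(x)
}

#' Evaluate a fixed train/test split of associations
#'
#' Ranks each held-out association against the unobserved miRNAs of its
#' disease using a model trained on the remaining associations. Unlike
#' leave-one-out, the training network is fixed, so the walk runs once per
#' distinct test disease.
#'
#' @param train an [association_dataset()] with the held-out entries already
#'   masked (e.g. from [holdout_split()]).
#' @param heldout data frame with columns `disease_id`, `mirna_id`.
#' @param ontology,fs,walk,semantic,gip,bias,scorer,seed as in
#'   [run_local_loocv()].
#' @return A `loocv_result` (folds, pooled ROC, AUC).
#' @export
evaluate_holdout <- function(train, heldout, ontology = NULL, fs = NULL,
                             walk = walk_params(),
                             semantic = semantic_params(), gip = gip_params(),
                             bias = c("degree", "constant"),
                             scorer = c("brwr", "degree", "random"),
                             seed = 1L) {
  stopifnot(inherits(train, "association_dataset"))
  bias <- match.arg(bias)
  scorer <- match.arg(scorer)
  if (nrow(heldout) == 0) stop("no held-out pairs to evaluate")
  bad <- !(heldout$disease_id %in% train$disease_ids) |
    !(heldout$mirna_id %in% train$mirna_ids)
  if (any(bad)) stop("held-out pair references unknown id(s)")
  seedable <- rowSums(train$A) > 0

  sims <- compute_similarities(train, ontology, fs, semantic, gip)
  net <- build_network(sims$SD, sims$SM, train$A)
  b <- if (bias == "degree") degree_vectors(net) else constant_bias(net)
  tm <- build_transition(net, b, walk$lambda)

  rng <- function(n) stats::runif(n)
  if (scorer == "random") set.seed(seed)

  records <- list()
  for (d_id in unique(heldout$disease_id)) {
    if (!seedable[d_id]) next  # new disease after masking: cannot seed
    candidates <- train$mirna_ids[train$A[d_id, ] == 0]
    scores <- switch(scorer,
      brwr = {
        p0 <- seed_vector(train, d_id, walk$alpha)
        p <- iterate_walk(tm, p0, walk)$p
        stats::setNames(p[paste0("m:", candidates)], candidates)
      },
      degree = stats::setNames(colSums(train$A)[candidates], candidates),
      random = stats::setNames(rng(length(candidates)), candidates)
    )
    for (m_id in heldout$mirna_id[heldout$disease_id == d_id]) {
      records[[length(records) + 1]] <- data.frame(
        disease_id = d_id, mirna_id = m_id,
        rank = midrank_of(scores, m_id),
        n_candidates = length(scores),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(records) == 0) stop("no scorable held-out pair")
  folds <- do.call(rbind, records)
  structure(
    list(folds = folds, roc = pooled_roc(folds), auc = auc_from_folds(folds),
         skipped = character()),
    class = "loocv_result"
  )
}
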