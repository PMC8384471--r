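#' Extract a disease's ancestor DAG from an ontology forest
#'
#' The DAG of a disease consists of its primary ontology term together with
#' every ancestor reachable through child-to-parent edges, plus the edges
#' among those terms.
#'
#' @param forest an [ontology_forest()].
#' @param disease disease identifier present in the forest's mapping.
#' @return An object of class `disease_dag` with elements `disease`, `term`
#'   (the primary term), `terms` (ancestor set including the term itself) and
#'   `edges` (two-column child/parent matrix restricted to `terms`).
#' @export
disease_dag <- function(forest, disease) {
  stopifnot(inherits(forest, "ontology_forest"))
  if (!disease %in% names(forest$disease_to_term)) {
    stop("disease not mapped to an ontology term: ", disease)
  }
  term <- unname(forest$disease_to_term[[disease]])
  pe <- forest$parent_edges
  # ancestor closure by upward BFS over child -> parent edges
  terms <- term
  frontier <- term
  while (length(frontier) > 0) {
    parents <- unique(pe[pe[, 1] %in% frontier, 2])
    frontier <- setdiff(parents, terms)
    terms <- c(terms, frontier)
  }
  edges <- pe[pe[, 1] %in% terms & pe[, 2] %in% terms, , drop = FALSE]
  structure(list(disease = disease, term = term, terms = terms, edges = edges),
            class = "disease_dag")
}

#' Model-1 semantic contributions of a disease's ancestor terms
#'
#' The disease's own term contributes 1; every other term `d` in the DAG
#' contributes the maximum of `delta` times the contribution of its children
#' within the DAG. Because `delta < 1`, this equals `delta` raised to the
#' shortest upward path length from the disease term.
#'
#' @param dag a [disease_dag()].
#' @param delta decay factor in (0, 1).
#' @return Named numeric vector of contributions over `dag$terms`, each in
#'   (0, 1].
#' @export
semantic_contributions_model1 <- function(dag, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"))
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  depth <- stats::setNames(rep(Inf, length(dag$terms)), dag$terms)
  depth[dag$term] <- 0
  frontier <- dag$term
  lev <- 0
  while (length(frontier) > 0) {
    lev <- lev + 1
    parents <- unique(dag$edges[dag$edges[, 1] %in% frontier, 2])
    frontier <- parents[is.infinite(depth[parents])]
    depth[frontier] <- lev
  }
  if (any(is.infinite(depth))) {
    stop("malformed DAG: term(s) unreachable from the disease term: ",
         paste(names(depth)[is.infinite(depth)], collapse = ", "))
  }
  delta^depth
}

#' Model-1 semantic similarity between two diseases
#'
#' Two diseases are similar in proportion to the shared part of their
#' ancestor DAGs: the sum over shared terms of both diseases' contributions,
#' normalised by the sum of their total semantic values.
#'
#' @param dag_i,dag_j [disease_dag()] objects from the same ontology.
#' @param delta decay factor in (0, 1).
#' @return Similarity score in [0, 1]; disjoint DAGs return 0.
#' @export
semantic_similarity_model1 <- function(dag_i, dag_j, delta = 0.5) {
  ci <- semantic_contributions_model1(dag_i, delta)
  cj <- semantic_contributions_model1(dag_j, delta)
  shared <- intersect(names(ci), names(cj))
  if (length(shared) == 0) return(0)
  sum(ci[shared] + cj[shared]) / (sum(ci) + sum(cj))
}

#' Model-2 semantic contributions (information content of terms)
#'
#' A term that appears in fewer disease DAGs is more specific and
#' contributes more: its contribution is `-log(k / n)` where `k` is the
#' number of DAGs containing the term and `n` the number of diseases.
#' A term present in every DAG contributes 0.
#'
#' @param dags list of [disease_dag()] objects, one per disease in the
#'   corpus.
#' @param log_base base of the logarithm (> 1); default natural log.
#' @return Named numeric vector of contributions over all terms occurring in
#'   at least one DAG.
#' @export
semantic_contributions_model2 <- function(dags, log_base = exp(1)) {
  if (length(dags) == 0) stop("model-2 contributions need at least one disease")
  if (log_base <= 1) stop("log_base must be > 1")
  counts <- table(unlist(lapply(dags, `[[`, "terms")))
  -log(as.numeric(counts) / length(dags), base = log_base) |>
    stats::setNames(names(counts))
}

#' Model-2 semantic similarity between two diseases
#'
#' @param dag_i,dag_j [disease_dag()] objects.
#' @param contributions named vector from [semantic_contributions_model2()],
#'   covering every term of both DAGs.
#' @return Similarity in [0, 1]. If both diseases' semantic values are zero
#'   (all their terms ubiquitous), returns 0 with a warning.
#' @export
semantic_similarity_model2 <- function(dag_i, dag_j, contributions) {
  missing_terms <- setdiff(c(dag_i$terms, dag_j$terms), names(contributions))
  if (length(missing_terms) > 0) {
    stop("term(s) without a model-2 contribution: ",
         paste(missing_terms, collapse = ", "))
  }
  dv_i <- sum(contributions[dag_i$terms])
  dv_j <- sum(contributions[dag_j$terms])
  if (dv_i + dv_j == 0) {
    warning("both semantic values are zero (all terms ubiquitous); returning 0")
    return(0)
  }
  shared <- intersect(dag_i$terms, dag_j$terms)
  if (length(shared) == 0) return(0)
  2 * sum(contributions[shared]) / (dv_i + dv_j)
}

#' Pairwise semantic similarity matrices for a set of diseases
#'
#' Computes the model-1 and model-2 similarity matrices over all diseases
#' that are mapped in the ontology. Diseases absent from the ontology get
#' zero rows/columns and `has_semantic = FALSE`; the integrated similarity
#' falls back to the kernel similarity for those pairs.
#'
#' @param forest an [ontology_forest()].
#' @param diseases character vector of disease ids (order defines the matrix
#'   order).
#' @param params a [semantic_params()].
#' @return List with `SS1`, `SS2` (symmetric matrices in [0, 1]) and
#'   `has_semantic` (named logical vector).
#' @export
semantic_similarity_matrices <- function(forest, diseases,
                                         params = semantic_params()) {
  stopifnot(inherits(params, "semantic_params"))
  has_semantic <- stats::setNames(
    diseases %in% names(forest$disease_to_term), diseases
  )
  n <- length(diseases)
  SS1 <- SS2 <- matrix(0, n, n, dimnames = list(diseases, diseases))
  mapped <- diseases[has_semantic]
  if (length(mapped) > 0) {
    dags <- lapply(mapped, disease_dag, forest = forest)
    names(dags) <- mapped
    all_terms <- sort(unique(unlist(lapply(dags, `[[`, "terms"))))
    # contribution matrix C1 (diseases x terms) and presence indicator Z
    C1 <- matrix(0, length(mapped), length(all_terms),
                 dimnames = list(mapped, all_terms))
    for (d in mapped) {
      contrib <- semantic_contributions_model1(dags[[d]], params$delta)
      C1[d, names(contrib)] <- contrib
    }
    Z <- (C1 > 0) + 0
    dv1 <- rowSums(C1)
    num1 <- C1 %*% t(Z) + Z %*% t(C1)
    SS1[mapped, mapped] <- num1 / outer(dv1, dv1, "+")

    g2 <- semantic_contributions_model2(dags, params$log_base)
    C2 <- Z * matrix(g2[all_terms], length(mapped), length(all_terms),
                     byrow = TRUE)
    dv2 <- rowSums(C2)
    den2 <- outer(dv2, dv2, "+")
    num2 <- C2 %*% t(Z) + Z %*% t(C2)
    s2 <- ifelse(den2 > 0, num2 / den2, 0)
    if (any(den2 == 0)) {
      warning("disease pair(s) with zero model-2 semantic value; similarity 0")
    }
    SS2[mapped, mapped] <- s2
  }
  SS1 <- (SS1 + t(SS1)) / 2
  SS2 <- (SS2 + t(SS2)) / 2
  list(SS1 = SS1, SS2 = SS2, has_semantic = has_semantic)
}

#' Gaussian interaction profile kernel similarity
#'
#' Treats each row of `profiles` as a binary interaction profile and returns
#' `exp(-gamma * ||IP(u) - IP(v)||^2)` with the bandwidth `gamma` obtained by
#' dividing `gamma_prime` by the mean squared profile norm. For disease
#' similarity pass the association matrix `A`; for miRNA similarity pass
#' `t(A)`.
#'
#' @param profiles numeric matrix; rows are entities, columns interaction
#'   partners.
#' @param gamma_prime raw bandwidth, positive.
#' @return Symmetric kernel matrix with unit diagonal and the row names of
#'   `profiles`.
#' @export
gip_similarity <- function(profiles, gamma_prime = 1) {
  profiles <- as.matrix(profiles)
  if (gamma_prime <= 0) stop("gamma_prime must be positive")
  norms2 <- rowSums(profiles^2)
  if (mean(norms2) == 0) {
    stop("all interaction profiles are zero: kernel bandwidth undefined")
  }
  gamma <- gamma_prime / mean(norms2)
  G <- tcrossprod(profiles)
  d2 <- outer(norms2, norms2, "+") - 2 * G
  d2[d2 < 0] <- 0  # numeric jitter from the cross-product expansion
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(profiles), rownames(profiles))
  K
}

#' Integrated disease similarity
#'
#' Where both diseases of a pair carry semantic similarity, the integrated
#' similarity is the mean of the two semantic models; otherwise the Gaussian
#' kernel similarity fills in.
#'
#' @param SS1,SS2 semantic similarity matrices.
#' @param KD disease kernel similarity matrix.
#' @param has_semantic logical vector, one entry per disease.
#' @return Symmetric matrix `SD`.
#' @export
integrate_disease_similarity <- function(SS1, SS2, KD, has_semantic) {
  if (!all(dim(SS1) == dim(KD)) || !all(dim(SS2) == dim(KD))) {
    stop("similarity matrices must share dimensions")
  }
  mask <- outer(has_semantic, has_semantic, "&")
  SD <- ifelse(mask, (SS1 + SS2) / 2, KD)
  dimnames(SD) <- dimnames(KD)
  SD
}

#' Integrated miRNA similarity
#'
#' Pairs present in the functional similarity matrix keep their functional
#' similarity; all other pairs fall back to the Gaussian kernel similarity.
#'
#' @param FS functional similarity matrix, possibly covering a subset of
#'   miRNAs (matched by row/column names); `NULL` for none.
#' @param KM miRNA kernel similarity matrix (defines the output order).
#' @param has_functional optional logical vector per miRNA; by default a
#'   miRNA "has" functional similarity when it appears in `FS`.
#' @return Symmetric matrix `SM` over the miRNAs of `KM`.
#' @export
integrate_mirna_similarity <- function(FS, KM, has_functional = NULL) {
  ids <- rownames(KM)
  if (is.null(FS)) {
    if (is.null(has_functional)) {
      has_functional <- stats::setNames(rep(FALSE, length(ids)), ids)
    }
    return(KM)
  }
  if (is.null(has_functional)) {
    has_functional <- stats::setNames(ids %in% rownames(FS), ids)
  }
  mask <- outer(has_functional, has_functional, "&")
  FS_full <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  common <- ids[has_functional]
  FS_full[common, common] <- FS[common, common]
  SM <- ifelse(mask, FS_full, KM)
  dimnames(SM) <- dimnames(KM)
  SM
}

#' Compute the full similarity bundle for a dataset
#'
#' Runs both semantic models, the two Gaussian interaction profile kernels,
#' and the integration rules, returning every intermediate matrix.
#'
#' @param dataset an [association_dataset()].
#' @param ontology an [ontology_forest()] or `NULL` (no semantic similarity:
#'   `SD` equals `KD`).
#' @param fs miRNA functional similarity matrix or `NULL` (no functional
#'   similarity: `SM` equals `KM`).
#' @param semantic a [semantic_params()].
#' @param gip a [gip_params()].
#' @return A list of class `similarity_bundle` with elements `SS1`, `SS2`,
#'   `KD`, `KM`, `FS`, `SD`, `SM`, `has_semantic`, `has_functional`.
#' @export
compute_similarities <- function(dataset, ontology = NULL, fs = NULL,
                                 semantic = semantic_params(),
                                 gip = gip_params()) {
  stopifnot(inherits(dataset, "association_dataset"))
  A <- dataset$A
  KD <- gip_similarity(A, gip$gamma_d_prime)
  KM <- gip_similarity(t(A), gip$gamma_m_prime)
  if (is.null(ontology)) {
    n <- length(dataset$disease_ids)
    SS1 <- SS2 <- matrix(0, n, n,
                         dimnames = list(dataset$disease_ids,
                                         dataset$disease_ids))
    has_semantic <- stats::setNames(rep(FALSE, n), dataset$disease_ids)
  } else {
    sem <- semantic_similarity_matrices(ontology, dataset$disease_ids, semantic)
    SS1 <- sem$SS1
    SS2 <- sem$SS2
    has_semantic <- sem$has_semantic
  }
  has_functional <- stats::setNames(
    if (is.null(fs)) rep(FALSE, length(dataset$mirna_ids))
    else dataset$mirna_ids %in% rownames(fs),
    dataset$mirna_ids
  )
  SD <- integrate_disease_similarity(SS1, SS2, KD, has_semantic)
  SM <- integrate_mirna_similarity(fs, KM, has_functional)
  structure(
    list(SS1 = SS1, SS2 = SS2, KD = KD, KM = KM, FS = fs, SD = SD, SM = SM,
         has_semantic = has_semantic, has_functional = has_functional),
    class = "similarity_bundle"
  )
}
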