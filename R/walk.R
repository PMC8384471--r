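#' Seed probability vector for a query disease
#'
#' The disease block is the indicator of the query disease weighted by
#' `alpha`; the miRNA block spreads the remaining `1 - alpha` uniformly over
#' the miRNAs known to be associated with the disease. A disease with no
#' known miRNA cannot be seeded (the model cannot rank candidates for new
#' diseases).
#'
#' @param dataset an [association_dataset()].
#' @param disease query disease id.
#' @param alpha disease-layer seed weight in [0, 1].
#' @return Named numeric vector of length `nd + nm` (ids prefixed
#'   `d:` / `m:`), summing to 1.
#' @export
seed_vector <- function(dataset, disease, alpha = 0.5) {
  stopifnot(inherits(dataset, "association_dataset"))
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (!disease %in% dataset$disease_ids) {
    stop("unknown disease id: ", disease)
  }
  known <- dataset$A[disease, ] == 1
  if (!any(known)) {
    stop("new disease (no known associated miRNA), cannot seed the walk: ",
         disease)
  }
  u0 <- as.numeric(dataset$disease_ids == disease)
  v0 <- as.numeric(known) / sum(known)
  p0 <- c(alpha * u0, (1 - alpha) * v0)
  names(p0) <- c(paste0("d:", dataset$disease_ids),
                 paste0("m:", dataset$mirna_ids))
  p0
}

#' Iterate the biased random walk with restart to convergence
#'
#' Repeats `p <- (1 - delta) * t(M) %*% p + delta * p0` until the L1 change
#' between successive iterates falls below `tol`. The transpose propagates
#' probability forward along the row-wise transitions (from `i` to `j`);
#' set `literal_orientation = TRUE` to multiply by `M` itself instead.
#'
#' @param tm a [build_transition()] result.
#' @param p0 seed probability vector from [seed_vector()].
#' @param params a [walk_params()] (uses `delta`, `tol`, `max_iter`).
#' @param literal_orientation propagate with `M %*% p` instead of
#'   `t(M) %*% p`.
#' @return List of class `walk_result` with elements `p` (the stationary
#'   probabilities), `iterations` and `residual`.
#' @export
iterate_walk <- function(tm, p0, params = walk_params(),
                         literal_orientation = FALSE) {
  stopifnot(inherits(tm, "transition_matrix"), inherits(params, "walk_params"))
  if (length(p0) != nrow(tm$M)) stop("seed vector length does not match M")
  P <- if (literal_orientation) tm$M else t(tm$M)
  delta <- params$delta
  p <- p0
  for (it in seq_len(params$max_iter)) {
    p_next <- as.vector((1 - delta) * (P %*% p)) + delta * p0
    resid <- sum(abs(p_next - p))
    p <- p_next
    if (resid < params$tol) {
      names(p) <- names(p0)
      return(structure(list(p = p, iterations = it, residual = resid),
                       class = "walk_result"))
    }
  }
  cond <- structure(
    class = c("walk_no_convergence", "error", "condition"),
    list(message = sprintf(
           "walk did not converge in %d iterations (residual %.3g)",
           params$max_iter, resid),
         call = sys.call(-1), p = p, residual = resid)
  )
  stop(cond)
}

#' Closed-form stationary distribution of the restart walk
#'
#' Solves `p = (1 - delta) t(M) p + delta p0` directly as
#' `delta (I - (1 - delta) t(M))^{-1} p0`. Since `M` is row-stochastic and
#' `1 - delta < 1`, the system is always nonsingular.
#'
#' @param tm a [build_transition()] result.
#' @param p0 seed probability vector.
#' @param delta restart probability in (0, 1).
#' @param literal_orientation solve the `M %*% p` fixed point instead.
#' @return Named stationary probability vector.
#' @export
solve_stationary <- function(tm, p0, delta = 0.7,
                             literal_orientation = FALSE) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  P <- if (literal_orientation) tm$M else t(tm$M)
  n <- nrow(P)
  p <- solve(diag(n) - (1 - delta) * P, delta * p0)
  stats::setNames(as.vector(p), names(p0))
}

#' Rank candidate miRNAs for a query disease
#'
#' Extracts the miRNA-block stationary scores, removes the miRNAs already
#' known to be associated with the disease, and sorts the remainder by
#' decreasing score (ties broken by miRNA id for a deterministic order).
#'
#' @param p stationary probability vector from [iterate_walk()] /
#'   [solve_stationary()] (or a `walk_result`).
#' @param dataset the [association_dataset()] the walk was seeded from.
#' @param disease query disease id.
#' @return A data frame of class `mirna_ranking` with columns `rank`,
#'   `mirna_id`, `score`; attributes `disease` and `excluded` (the known
#'   miRNA ids).
#' @export
rank_candidates <- function(p, dataset, disease) {
  if (inherits(p, "walk_result")) p <- p$p
  stopifnot(inherits(dataset, "association_dataset"))
  scores <- p[paste0("m:", dataset$mirna_ids)]
  names(scores) <- dataset$mirna_ids
  known <- dataset$mirna_ids[dataset$A[disease, ] == 1]
  cand <- setdiff(dataset$mirna_ids, known)
  s <- scores[cand]
  ord <- order(-s, cand)
  out <- data.frame(rank = seq_along(cand), mirna_id = cand[ord],
                    score = unname(s[ord]), stringsAsFactors = FALSE)
  attr(out, "disease") <- disease
  attr(out, "excluded") <- known
  class(out) <- c("mirna_ranking", class(out))
  out
}

#' Predict candidate miRNAs for a disease (end-to-end)
#'
#' Convenience wrapper: computes similarities, assembles the network and
#' transition matrix, runs the walk seeded at the query disease, and ranks
#' the candidate miRNAs.
#'
#' @param dataset an [association_dataset()].
#' @param disease query disease id.
#' @param ontology optional [ontology_forest()].
#' @param fs optional miRNA functional similarity matrix.
#' @param walk a [walk_params()].
#' @param semantic a [semantic_params()].
#' @param gip a [gip_params()].
#' @param bias `"degree"` (default) or `"constant"` for the unbiased control.
#' @param method `"iterate"` (default) or `"solve"` for the closed form.
#' @param top optionally truncate the ranking to the first `top` rows.
#' @return A `mirna_ranking` data frame (see [rank_candidates()]).
#' @export
predict_mirnas <- function(dataset, disease, ontology = NULL, fs = NULL,
                           walk = walk_params(),
                           semantic = semantic_params(), gip = gip_params(),
                           bias = c("degree", "constant"),
                           method = c("iterate", "solve"), top = NULL) {
  bias <- match.arg(bias)
  method <- match.arg(method)
  sims <- compute_similarities(dataset, ontology, fs, semantic, gip)
  net <- build_network(sims$SD, sims$SM, dataset$A)
  b <- if (bias == "degree") degree_vectors(net) else constant_bias(net)
  tm <- build_transition(net, b, walk$lambda)
  p0 <- seed_vector(dataset, disease, walk$alpha)
  p <- if (method == "iterate") iterate_walk(tm, p0, walk)$p
       else solve_stationary(tm, p0, walk$delta)
  out <- rank_candidates(p, dataset, disease)
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), ]
  out
}
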