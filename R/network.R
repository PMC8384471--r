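#' Assemble the multilayer heterogeneous network
#'
#' Stacks the disease similarity layer, the miRNA similarity layer and the
#' bipartite association layer into the 2x2 block weight matrix
#' `W = [[Wdd, Wdm], [Wmd, Wmm]]` over `nd + nm` nodes.
#'
#' @param SD integrated disease similarity (`nd x nd`, symmetric,
#'   nonnegative).
#' @param SM integrated miRNA similarity (`nm x nm`, symmetric, nonnegative).
#' @param A binary association matrix (`nd x nm`).
#' @param zero_diagonal drop the self-similarity diagonal from the two
#'   within-layer blocks. Default `FALSE` (the transition formulas place no
#'   exclusion on self-loops).
#' @return An object of class `hetero_network` with elements `Wdd`, `Wmm`,
#'   `Wdm`, `disease_ids`, `mirna_ids`.
#' @export
build_network <- function(SD, SM, A, zero_diagonal = FALSE) {
  A <- as.matrix(A)
  if (nrow(SD) != ncol(SD) || nrow(SM) != ncol(SM)) {
    stop("similarity blocks must be square")
  }
  if (nrow(A) != nrow(SD) || ncol(A) != nrow(SM)) {
    stop(sprintf(
      "dimension mismatch: A is %dx%d but SD is %dx%d and SM is %dx%d",
      nrow(A), ncol(A), nrow(SD), ncol(SD), nrow(SM), ncol(SM)
    ))
  }
  if (any(SD < 0) || any(SM < 0)) stop("similarity weights must be nonnegative")
  if (max(abs(SD - t(SD))) > 1e-8 || max(abs(SM - t(SM))) > 1e-8) {
    stop("similarity blocks must be symmetric")
  }
  if (zero_diagonal) {
    diag(SD) <- 0
    diag(SM) <- 0
  }
  disease_ids <- rownames(A)
  mirna_ids <- colnames(A)
  if (is.null(disease_ids)) disease_ids <- paste0("d", seq_len(nrow(A)))
  if (is.null(mirna_ids)) mirna_ids <- paste0("m", seq_len(ncol(A)))
  dimnames(SD) <- list(disease_ids, disease_ids)
  dimnames(SM) <- list(mirna_ids, mirna_ids)
  dimnames(A) <- list(disease_ids, mirna_ids)
  structure(
    list(Wdd = SD, Wmm = SM, Wdm = A,
         disease_ids = disease_ids, mirna_ids = mirna_ids),
    class = "hetero_network"
  )
}

#' @export
print.hetero_network <- function(x, ...) {
  cat(sprintf("hetero_network: %d diseases + %d miRNAs, %d association edges\n",
              length(x$disease_ids), length(x$mirna_ids), sum(x$Wdm)))
  invisible(x)
}

#' Full block weight matrix of a heterogeneous network
#'
#' @param net a [build_network()] result.
#' @return The `(nd+nm) x (nd+nm)` matrix `W` with node ids prefixed
#'   `d:` / `m:`.
#' @export
network_weight_matrix <- function(net) {
  W <- rbind(cbind(net$Wdd, net$Wdm), cbind(t(net$Wdm), net$Wmm))
  ids <- c(paste0("d:", net$disease_ids), paste0("m:", net$mirna_ids))
  dimnames(W) <- list(ids, ids)
  W
}

#' Degree bias vectors of a heterogeneous network
#'
#' The walk's bias function is node degree, computed per context: within the
#' disease layer the degree of disease `j` is the `j`-th column sum of
#' `Wdd`; within the miRNA layer, the column sum of `Wmm`; in the bipartite
#' layer the miRNA degree is the column sum of `Wdm` and the disease degree
#' its row sum.
#'
#' @param net a [build_network()] result.
#' @return A list of class `bias_vectors` with elements `dd`, `mm` (within
#'   layer) and `cross_m`, `cross_d` (bipartite layer).
#' @export
degree_vectors <- function(net) {
  structure(
    list(dd = colSums(net$Wdd),
         mm = colSums(net$Wmm),
         cross_m = colSums(net$Wdm),
         cross_d = rowSums(net$Wdm)),
    class = "bias_vectors"
  )
}

#' Constant (neutral) bias vectors
#'
#' With a constant bias the biased transition matrix reduces exactly to the
#' unbiased normalisation; useful as a control.
#'
#' @param net a [build_network()] result.
#' @param value the constant, positive.
#' @return A `bias_vectors` list.
#' @export
constant_bias <- function(net, value = 1) {
  if (value <= 0) stop("constant bias must be positive")
  nd <- length(net$disease_ids)
  nm <- length(net$mirna_ids)
  structure(
    list(dd = stats::setNames(rep(value, nd), net$disease_ids),
         mm = stats::setNames(rep(value, nm), net$mirna_ids),
         cross_m = stats::setNames(rep(value, nm), net$mirna_ids),
         cross_d = stats::setNames(rep(value, nd), net$disease_ids)),
    class = "bias_vectors"
  )
}

# Bias-weighted row normalisation of one block: row i of B scaled entrywise
# by f and divided by its biased row sum. Rows with zero biased mass are
# returned as zero (callers decide whether that is an error).
biased_rows <- function(B, f) {
  num <- sweep(B, 2, f, `*`)
  den <- rowSums(num)
  out <- num / ifelse(den > 0, den, 1)
  out[den <= 0, ] <- 0
  list(P = out, den = den)
}

#' Degree-biased transition matrix of the heterogeneous network
#'
#' Builds the row-stochastic block transition matrix of the biased random
#' walk. Within each layer the probability of stepping from `i` to `j` is
#' the bias-weighted edge weight `W(i,j) f_j` normalised over the row, scaled
#' by `1 - lambda` when node `i` also has bipartite edges; crossing between
#' layers happens with probability `lambda`, distributed over the bipartite
#' edges with the cross-layer degree as bias. A disease (or miRNA) without
#' any association keeps all its mass within its own layer, so every row
#' still sums to one.
#'
#' @param net a [build_network()] result.
#' @param bias a `bias_vectors` list, by default [degree_vectors()].
#' @param lambda jump probability in [0, 1].
#' @return An object of class `transition_matrix` with elements `M`
#'   (`(nd+nm) x (nd+nm)` with `d:`/`m:` prefixed ids), `lambda`, `nd`, `nm`.
#' @export
build_transition <- function(net, bias = degree_vectors(net), lambda = 0.5) {
  stopifnot(inherits(net, "hetero_network"))
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (any(unlist(bias) < 0)) stop("bias values must be nonnegative")
  nd <- length(net$disease_ids)
  nm <- length(net$mirna_ids)
  Wdm <- net$Wdm
  d_assoc <- rowSums(Wdm) > 0   # diseases with at least one association
  m_assoc <- colSums(Wdm) > 0   # miRNAs with at least one association

  dd <- biased_rows(net$Wdd, bias$dd)
  mm <- biased_rows(net$Wmm, bias$mm)
  dm <- biased_rows(Wdm, bias$cross_m)
  md <- biased_rows(t(Wdm), bias$cross_d)

  bad_d <- !d_assoc & dd$den <= 0
  bad_m <- !m_assoc & mm$den <= 0
  if (any(bad_d) || any(bad_m)) {
    stop("node(s) with zero biased transition mass: ",
         paste(c(paste0("d:", net$disease_ids[bad_d]),
                 paste0("m:", net$mirna_ids[bad_m])), collapse = ", "))
  }
  # within-layer rows without bipartite edges get no (1 - lambda) scaling
  Mdd <- dd$P * ifelse(d_assoc, 1 - lambda, 1)
  Mmm <- mm$P * ifelse(m_assoc, 1 - lambda, 1)
  Mdm <- dm$P * lambda
  Mmd <- md$P * lambda
  # a within-layer row with zero similarity mass but existing bipartite
  # edges must push all its mass across
  Mdm[d_assoc & dd$den <= 0, ] <- dm$P[d_assoc & dd$den <= 0, ] * 1
  Mmd[m_assoc & mm$den <= 0, ] <- md$P[m_assoc & mm$den <= 0, ] * 1

  M <- rbind(cbind(Mdd, Mdm), cbind(Mmd, Mmm))
  ids <- c(paste0("d:", net$disease_ids), paste0("m:", net$mirna_ids))
  dimnames(M) <- list(ids, ids)
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-10)) {
    stop("internal error: transition rows do not sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  structure(list(M = M, lambda = lambda, nd = nd, nm = nm,
                 disease_ids = net$disease_ids, mirna_ids = net$mirna_ids),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix: %d nodes (%d diseases, %d miRNAs), lambda = %g\n",
              x$nd + x$nm, x$nd, x$nm, x$lambda))
  invisible(x)
}
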