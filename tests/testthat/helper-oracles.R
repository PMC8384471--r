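# Independent brute-force oracles, kept free of the package's own
# implementation paths.

# Model-1 contribution by exhaustive path enumeration: the maximum over all
# upward paths from the disease term to `target` of delta^length.
oracle_contribution_model1 <- function(edges, start, target, delta) {
  if (start == target) return(1)
  parents <- edges[edges[, 1] == start, 2]
  if (length(parents) == 0) return(-Inf)
  delta * max(vapply(parents, function(p) {
    oracle_contribution_model1(edges, p, target, delta)
  }, 0))
}

# Direct evaluation of the four transition blocks from the block equations,
# one entry at a time.
oracle_transition <- function(Wdd, Wmm, Wdm, lambda, bias) {
  nd <- nrow(Wdd); nm <- nrow(Wmm)
  Mdd <- matrix(0, nd, nd); Mdm <- matrix(0, nd, nm)
  Mmd <- matrix(0, nm, nd); Mmm <- matrix(0, nm, nm)
  for (i in seq_len(nd)) {
    den_dd <- sum(Wdd[i, ] * bias$dd)
    has_assoc <- sum(Wdm[i, ]) != 0
    for (j in seq_len(nd)) {
      Mdd[i, j] <- if (!has_assoc) Wdd[i, j] * bias$dd[j] / den_dd
                   else (1 - lambda) * Wdd[i, j] * bias$dd[j] / den_dd
    }
    if (has_assoc) {
      den_dm <- sum(Wdm[i, ] * bias$cross_m)
      for (j in seq_len(nm)) {
        Mdm[i, j] <- lambda * Wdm[i, j] * bias$cross_m[j] / den_dm
      }
    }
  }
  for (i in seq_len(nm)) {
    den_mm <- sum(Wmm[i, ] * bias$mm)
    has_assoc <- sum(Wdm[, i]) != 0
    for (j in seq_len(nm)) {
      Mmm[i, j] <- if (!has_assoc) Wmm[i, j] * bias$mm[j] / den_mm
                   else (1 - lambda) * Wmm[i, j] * bias$mm[j] / den_mm
    }
    if (has_assoc) {
      den_md <- sum(Wdm[, i] * bias$cross_d)
      for (j in seq_len(nd)) {
        Mmd[i, j] <- lambda * Wdm[j, i] * bias$cross_d[j] / den_md
      }
    }
  }
  rbind(cbind(Mdd, Mdm), cbind(Mmd, Mmm))
}

# Mann-Whitney AUC of one fold by exhaustive pairwise win/tie counting.
oracle_pair_auc <- function(scores, positive) {
  neg <- scores[setdiff(names(scores), positive)]
  pos <- scores[[positive]]
  (sum(pos > neg) + 0.5 * sum(pos == neg)) / length(neg)
}

# A random but valid heterogeneous network: symmetric similarity blocks in
# [0, 1] with unit diagonal, binary association block.
random_network <- function(nd, nm, seed, p_assoc = 0.3) {
  set.seed(seed)
  sym01 <- function(n) {
    S <- matrix(runif(n * n), n, n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    S
  }
  A <- matrix(rbinom(nd * nm, 1, p_assoc), nd, nm) + 0
  dimnames(A) <- list(sprintf("d%02d", seq_len(nd)),
                      sprintf("m%02d", seq_len(nm)))
  build_network(sym01(nd), sym01(nm), A)
}

# Tiny fully-specified dataset used across tests: 2 diseases, 2 miRNAs,
# A = identity.
toy_dataset <- function() {
  association_dataset(
    c("d1", "d2"), c("m1", "m2"),
    matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  )
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
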