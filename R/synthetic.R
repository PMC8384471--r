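#' Configuration for the synthetic planted-cluster generator
#'
#' Describes a bipartite disease-miRNA benchmark with `k` planted clusters:
#' within-cluster associations appear with probability `p_in`,
#' between-cluster with `p_out`; diseases of a cluster share an ontology
#' ancestor chain, and the functional similarity of same-cluster miRNAs is
#' centred at `fs_signal` with symmetric truncated-Gaussian noise of scale
#' `fs_noise` (between-cluster pairs carry noise only).
#'
#' @param n_d,n_m numbers of diseases and miRNAs.
#' @param k number of planted clusters, at most `min(n_d, n_m)`.
#' @param p_in,p_out within/between-cluster association probabilities,
#'   `0 <= p_out <= p_in <= 1` (strictly `p_out < p_in` except for the
#'   structureless null where they coincide).
#' @param fs_signal within-cluster functional similarity mean in [0, 1].
#' @param fs_noise standard deviation of the symmetric similarity noise.
#' @param dag_depth length of each cluster's ontology ancestor chain
#'   (>= 1), below a shared global root.
#' @param dag_shape `"chain"` (default; similarities are hand-derivable) or
#'   `"random"`, which adds shortcut parent edges creating diamond-shaped
#'   DAGs.
#' @param ensure_connected resample any disease row left with zero
#'   associations (up to 100 retries).
#' @param seed RNG seed; everything the generator emits is a deterministic
#'   function of the config including this seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_d = 40, n_m = 60, k = 4,
                             p_in = 0.5, p_out = 0.02,
                             fs_signal = 0.8, fs_noise = 0.1,
                             dag_depth = 3, dag_shape = c("chain", "random"),
                             ensure_connected = FALSE, seed = 0L) {
  dag_shape <- match.arg(dag_shape)
  if (k > min(n_d, n_m)) stop("k must not exceed min(n_d, n_m)")
  if (p_out > p_in || p_in > 1 || p_out < 0) {
    stop("need 0 <= p_out <= p_in <= 1")
  }
  if (dag_depth < 1) stop("dag_depth must be >= 1")
  if (fs_signal < 0 || fs_signal > 1) stop("fs_signal must lie in [0, 1]")
  if (fs_noise < 0) stop("fs_noise must be nonnegative")
  structure(
    list(n_d = n_d, n_m = n_m, k = k, p_in = p_in, p_out = p_out,
         fs_signal = fs_signal, fs_noise = fs_noise, dag_depth = dag_depth,
         dag_shape = dag_shape, ensure_connected = ensure_connected,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# zero-padded ids keep lexicographic order equal to numeric order
padded_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(2, nchar(n)), seq_len(n))
}

#' Generate a synthetic planted-cluster dataset
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_dataset` with elements `dataset`
#'   ([association_dataset()]), `ontology` ([ontology_forest()]), `fs`
#'   (miRNA functional similarity matrix), `disease_clusters`,
#'   `mirna_clusters` (named integer vectors of ground-truth labels) and
#'   `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  disease_ids <- padded_ids("dis", config$n_d)
  mirna_ids <- padded_ids("mir", config$n_m)
  d_cl <- stats::setNames(
    sort(rep_len(seq_len(config$k), config$n_d)), disease_ids)
  m_cl <- stats::setNames(
    sort(rep_len(seq_len(config$k), config$n_m)), mirna_ids)

  same <- outer(d_cl, m_cl, "==")
  prob <- ifelse(same, config$p_in, config$p_out)
  draw_A <- function() {
    matrix(stats::rbinom(length(prob), 1, prob), nrow(prob), ncol(prob),
           dimnames = dimnames(prob)) + 0
  }
  A <- draw_A()
  if (config$ensure_connected) {
    for (attempt in seq_len(100)) {
      empty <- rowSums(A) == 0
      if (!any(empty)) break
      A[empty, ] <- draw_A()[empty, , drop = FALSE]
    }
    if (any(rowSums(A) == 0)) {
      stop("could not connect every disease within the retry cap; ",
           "raise p_in/p_out")
    }
  }

  # ontology: global root, one ancestor chain per cluster, diseases hang
  # off the bottom of their cluster's chain
  edges <- list()
  for (c_i in seq_len(config$k)) {
    anc <- sprintf("anc%d_%d", c_i, seq_len(config$dag_depth))
    chain_top <- cbind(anc[config$dag_depth], "ROOT")
    chain <- if (config$dag_depth > 1) {
      rbind(cbind(anc[-config$dag_depth], anc[-1]), chain_top)
    } else chain_top
    leaves <- cbind(names(d_cl)[d_cl == c_i], anc[1])
    edges[[c_i]] <- rbind(leaves, chain)
  }
  edges <- do.call(rbind, edges)
  if (config$dag_shape == "random" && config$dag_depth >= 2) {
    # diamond shortcuts: each disease may gain a second parent deeper in
    # its cluster's chain
    extra <- lapply(disease_ids, function(d) {
      if (stats::runif(1) < 0.5) {
        lvl <- sample(2:config$dag_depth, 1)
        cbind(d, sprintf("anc%d_%d", d_cl[[d]], lvl))
      }
    })
    edges <- rbind(edges, do.call(rbind, extra))
    edges <- edges[!duplicated(edges), , drop = FALSE]
  }
  mapping <- stats::setNames(disease_ids, disease_ids)
  ontology <- ontology_forest(edges, disease_to_term = mapping)

  # functional similarity: cluster-block signal plus symmetric noise
  base <- ifelse(outer(m_cl, m_cl, "=="), config$fs_signal, 0)
  noise <- matrix(stats::rnorm(config$n_m^2, sd = config$fs_noise),
                  config$n_m, config$n_m)
  noise <- (noise + t(noise)) / 2
  FS <- pmin(pmax(base + noise, 0), 1)
  diag(FS) <- 1
  dimnames(FS) <- list(mirna_ids, mirna_ids)

  structure(
    list(dataset = association_dataset(disease_ids, mirna_ids, A),
         ontology = ontology, fs = FS,
         disease_clusters = d_cl, mirna_clusters = m_cl, config = config),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d diseases x %d miRNAs, %d clusters, %d associations (seed %d)\n",
    x$config$n_d, x$config$n_m, x$config$k, sum(x$dataset$A), x$config$seed))
  invisible(x)
}

#' Hold out a fraction of known associations
#'
#' Removes a random `fraction` of the 1-entries from the association matrix
#' while guaranteeing that no disease loses all of its associations (it
#' could no longer seed a walk). The removal order is a seeded permutation;
#' entries whose removal would orphan a disease are passed over.
#'
#' @param dataset an [association_dataset()].
#' @param fraction fraction of associations to hold out, in (0, 1).
#' @param seed RNG seed for the permutation.
#' @return List with `train` (masked [association_dataset()]) and `heldout`
#'   (data frame of `disease_id`, `mirna_id`).
#' @export
holdout_split <- function(dataset, fraction, seed = 0L) {
  stopifnot(inherits(dataset, "association_dataset"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  set.seed(seed)
  ones <- which(dataset$A == 1, arr.ind = TRUE)
  target <- round(fraction * nrow(ones))
  if (target == 0) {
    return(list(train = dataset,
                heldout = data.frame(disease_id = character(),
                                     mirna_id = character())))
  }
  ones <- ones[sample(nrow(ones)), , drop = FALSE]
  A <- dataset$A
  removed <- matrix(0L, 0, 2)
  for (r in seq_len(nrow(ones))) {
    if (nrow(removed) == target) break
    i <- ones[r, 1]; j <- ones[r, 2]
    if (sum(A[i, ]) >= 2) {  # never orphan a disease
      A[i, j] <- 0
      removed <- rbind(removed, ones[r, ])
    }
  }
  if (nrow(removed) < target) {
    stop(sprintf(
      "cannot hold out %d association(s) without orphaning a disease (only %d removable)",
      target, nrow(removed)))
  }
  list(
    train = association_dataset(dataset$disease_ids, dataset$mirna_ids, A),
    heldout = data.frame(
      disease_id = dataset$disease_ids[removed[, 1]],
      mirna_id = dataset$mirna_ids[removed[, 2]],
      stringsAsFactors = FALSE
    )
  )
}
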