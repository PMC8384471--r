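#' Semantic similarity parameters
#'
#' @param delta semantic contribution decay factor applied per ancestor
#'   level in model 1; must lie in (0, 1). Default 0.5 (the usual convention
#'   for MeSH-style disease DAGs).
#' @param log_base base of the logarithm in the model-2 information-content
#'   contribution; must exceed 1. Default natural log. The base only rescales
#'   contributions, and one shared base keeps the model-2 ratio well defined.
#' @return A list of class `semantic_params`.
#' @export
semantic_params <- function(delta = 0.5, log_base = exp(1)) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta >= 1) {
    stop("delta must be a single number in (0, 1)")
  }
  if (!is.numeric(log_base) || length(log_base) != 1 || log_base <= 1) {
    stop("log_base must be a single number > 1")
  }
  structure(list(delta = delta, log_base = log_base),
            class = "semantic_params")
}

#' Gaussian interaction profile kernel parameters
#'
#' @param gamma_d_prime,gamma_m_prime raw kernel bandwidths for the disease
#'   and miRNA kernels; the effective bandwidth divides these by the mean
#'   squared interaction-profile norm. Both must be positive. Default 1.
#' @return A list of class `gip_params`.
#' @export
gip_params <- function(gamma_d_prime = 1, gamma_m_prime = 1) {
  if (!is.numeric(gamma_d_prime) || gamma_d_prime <= 0 ||
      !is.numeric(gamma_m_prime) || gamma_m_prime <= 0) {
    stop("GIP bandwidths must be positive")
  }
  structure(list(gamma_d_prime = gamma_d_prime, gamma_m_prime = gamma_m_prime),
            class = "gip_params")
}

#' Random walk with restart parameters
#'
#' @param delta restart probability in (0, 1): at each step the walker
#'   returns to the seed distribution with probability `delta`. Default 0.7.
#' @param alpha weight of the disease-layer seed in the initial probability
#'   vector; the miRNA-layer seeds share weight `1 - alpha`. Default 0.5.
#' @param lambda jump probability of crossing between the disease and miRNA
#'   layers, in [0, 1]. Default 0.5.
#' @param tol convergence tolerance on the L1 change between successive
#'   probability vectors. Default 1e-6.
#' @param max_iter iteration cap. Default 1000.
#' @return A list of class `walk_params`.
#' @export
walk_params <- function(delta = 0.7, alpha = 0.5, lambda = 0.5,
                        tol = 1e-6, max_iter = 1000) {
  if (!is.numeric(delta) || delta <= 0 || delta >= 1) {
    stop("restart probability delta must lie in (0, 1)")
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("seed weight alpha must lie in [0, 1]")
  }
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
    stop("jump probability lambda must lie in [0, 1]")
  }
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive")
  if (!is.numeric(max_iter) || max_iter < 1) stop("max_iter must be >= 1")
  structure(list(delta = delta, alpha = alpha, lambda = lambda,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "walk_params")
}
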