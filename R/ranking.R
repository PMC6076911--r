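#' Signed weighted network
#'
#' A directed network on `n` nodes stored as an `n x n` adjacency matrix in
#' which `A[i, j]` is the weight of the edge from node `i` to node `j`;
#' negative weights encode distrust (for connectivity networks, a coupling
#' gain estimated below its prior).  The diagonal is zero.
#'
#' @param A square numeric matrix, zero diagonal, finite entries
#' @param labels optional node labels (default from `A`'s dimnames or
#'   `"n1"..`)
#' @return object of class `signed_network`
#' @export
signed_network <- function(A, labels = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("signed_network: A must be square", call. = FALSE)
  if (!all(is.finite(A))) stop("signed_network: non-finite weights", call. = FALSE)
  if (any(diag(A) != 0)) stop("signed_network: diagonal must be zero", call. = FALSE)
  if (is.null(labels)) labels <- rownames(A)
  if (is.null(labels)) labels <- paste0("n", seq_len(nrow(A)))
  if (length(labels) != nrow(A))
    stop("signed_network: labels length mismatch", call. = FALSE)
  dimnames(A) <- list(labels, labels)
  structure(list(A = A, labels = labels), class = "signed_network")
}

as_adjacency <- function(net) {
  if (inherits(net, "signed_network")) net$A else as.matrix(net)
}

#' Node reputation under a trust distribution
#'
#' Reputation of node `i` is the trust-weighted sum of its incoming links:
#' `k_i = sum_j A[j, i] p_j`, i.e. `k = t(A) %*% p`.
#'
#' @param net a [signed_network()] (or plain adjacency matrix)
#' @param p trust vector, length `n`, non-negative
#' @return reputation vector `k`
#' @export
reputation <- function(net, p) {
  A <- as_adjacency(net)
  if (length(p) != nrow(A)) stop("reputation: p has wrong length", call. = FALSE)
  drop(crossprod(A, p))
}

#' Softmax trust probabilities from reputations
#'
#' `p_i = exp(k_i / mu) / sum_j exp(k_j / mu)` where `mu > 0` is the noise
#' parameter of the underlying discrete-choice model.  Computed with
#' max-subtraction so large reputations never overflow.
#'
#' @param k reputation vector (finite)
#' @param mu noise parameter, strictly positive
#' @return probability vector summing to one
#' @export
trust_probabilities <- function(k, mu = 1) {
  if (!is.numeric(mu) || length(mu) != 1 || !is.finite(mu) || mu <= 0)
    stop("trust_probabilities: mu must be a positive number", call. = FALSE)
  stopifnot(all(is.finite(k)))
  z <- k / mu
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Exponential ranking of a signed network
#'
#' Iterates the recursion `p <- softmax(t(A) %*% p / mu)` from an initial
#' trust distribution until the maximum absolute change falls below `tol`.
#' The fixed point assigns each node a trust probability that accounts
#' recursively for both positive and negative incoming links.  A period-2
#' oscillation (possible for small `mu`) is damped by averaging successive
#' iterates.
#'
#' @param net a [signed_network()] or adjacency matrix
#' @param mu noise parameter (> 0); the scale of `mu` is meaningful only
#'   relative to the edge weights
#' @param tol convergence tolerance on `max |p_new - p|`
#' @param max_iter iteration cap; on hitting it the result is returned with
#'   `converged = FALSE` rather than raising an error
#' @param p0 initial trust vector (default uniform)
#' @return object of class `ranking_result`: list with `k` (reputations at
#'   the fixed point), `p` (trust probabilities), `mu`, `iterations`,
#'   `converged`, `labels`
#' @export
exponential_ranking <- function(net, mu = 1, tol = 1e-10, max_iter = 10000L,
                                p0 = NULL) {
  A <- as_adjacency(net)
  labels <- if (inherits(net, "signed_network")) net$labels else rownames(A)
  n <- nrow(A)
  if (is.null(p0)) p0 <- rep(1 / n, n)
  if (length(p0) != n || any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
    stop("exponential_ranking: p0 must be a probability vector of length ", n,
         call. = FALSE)
  At <- t(A)
  p <- p0
  converged <- FALSE
  damping <- 1
  prev_delta <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    k <- unname(drop(At %*% p))
    p_new <- trust_probabilities(k, mu)
    if (damping < 1) p_new <- damping * p_new + (1 - damping) * p
    delta <- max(abs(p_new - p))
    if (delta < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    # period-2 oscillation: the step size stalls instead of contracting
    if (it > 10L && delta > 0.9 * prev_delta && damping == 1) damping <- 0.5
    prev_delta <- delta
    p <- p_new
  }
  k <- unname(drop(At %*% p))
  structure(list(k = k, p = p, mu = mu, iterations = it,
                 converged = converged, labels = labels),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("Exponential ranking (mu =", x$mu, ",",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", ")\n")
  df <- data.frame(node = if (is.null(x$labels)) seq_along(x$p) else x$labels,
                   reputation = x$k, trust = x$p)
  print(df[order(-df$trust), ], row.names = FALSE, ...)
  invisible(x)
}

#' Read / write a signed network as a labelled delimited matrix
#'
#' Tab-delimited square matrix with node labels as header row and first
#' column.
#'
#' @param net a [signed_network()]
#' @param path file path
#' @return `read_signed_network` returns a [signed_network()];
#'   `write_signed_network` returns `path` invisibly
#' @export
write_signed_network <- function(net, path) {
  A <- as_adjacency(net)
  utils::write.table(A, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_signed_network
#' @export
read_signed_network <- function(path) {
  A <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  signed_network(A, labels = rownames(A))
}

#' Write a ranking result as JSON
#'
#' @param res a `ranking_result`
#' @param path file path
#' @export
write_ranking <- function(res, path) {
  jsonlite::write_json(
    list(labels = res$labels, reputation = res$k, trust = res$p, mu = res$mu,
         iterations = res$iterations, converged = res$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
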