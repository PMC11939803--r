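#' Brute-force maximum-entropy oracle for small networks
#'
#' Solves the same program as [fit_transition_matrix()] — maximize the
#' entropy of the edge flows \eqn{f_{ij} = \pi_i p_{ij}} subject to row
#' marginals \eqn{\pi_i}, column marginals \eqn{\pi_j} and the support —
#' but by a completely different route, so it can serve as an independent
#' check on the scaling iteration:
#'
#' 1. edges that lie on no directed cycle can carry no stationary flow and
#'    are fixed to zero (with self-loops every diagonal entry is a 1-cycle);
#' 2. a strictly feasible interior flow is built from the diagonal plus a
#'    small circulation threading every remaining off-diagonal edge;
#' 3. the equality constraints are eliminated through an SVD null-space
#'    basis and the entropy is maximized over the reduced coordinates with
#'    [stats::constrOptim()] (log-barrier on \eqn{f > 0}, analytic gradient).
#'
#' Dense and deliberately small: refuses networks with more than 8 genes.
#'
#' @param net A self-loop-augmented [gene_network()].
#' @param pi Stationary distribution (named vector or
#'   [stationary_from_expression()] result) over the network's genes.
#' @return A list with `P` (dense transition matrix, dimnames = genes),
#'   `mce` (nats), and `flow` (the optimal flow matrix).
#' @export
oracle_max_entropy <- function(net, pi) {
  stopifnot(inherits(net, "gene_network"))
  if (!net$augmented) abort("network must be self-loop-augmented")
  if (inherits(pi, "stationary_dist")) pi <- pi$pi
  n <- length(net$genes)
  if (n > 8) abort("oracle refuses n > 8 (dense solve)")
  if (!all(sort(names(pi)) == sort(net$genes))) {
    abort("`pi` must cover exactly the network genes")
  }
  pi <- pi[net$genes]
  A <- as.matrix(adjacency_matrix(net))

  # forced-zero edges: off-diagonal (i, j) with no directed return path j -> i
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed", diag = FALSE)
  reach <- igraph::distances(g, mode = "out")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && A[i, j] == 1 && !is.finite(reach[j, i])) A[i, j] <- 0
  }

  idx <- which(A == 1, arr.ind = TRUE)
  m <- nrow(idx)
  off <- idx[idx[, 1] != idx[, 2], , drop = FALSE]

  # interior feasible flow: diag(pi) minus throughput, plus cycle circulations
  K <- matrix(0, n, n)
  if (nrow(off)) {
    for (e in seq_len(nrow(off))) {
      i <- off[e, 1]; j <- off[e, 2]
      back <- suppressWarnings(
        igraph::shortest_paths(g, from = j, to = i, mode = "out")$vpath[[1]]
      )
      cyc <- c(i, as.integer(back))
      for (s in seq_len(length(cyc) - 1)) {
        K[cyc[s], cyc[s + 1]] <- K[cyc[s], cyc[s + 1]] + 1
      }
      K[cyc[length(cyc)], cyc[1]] <- K[cyc[length(cyc)], cyc[1]] + 1
    }
  }
  thr <- rowSums(K)
  delta <- if (max(thr) > 0) 0.5 * min(pi) / max(thr) else 0
  F0 <- diag(pi - delta * thr) + delta * K
  f0 <- F0[idx]

  if (nrow(off) == 0) {
    P <- diag(1, n)
    dimnames(P) <- list(net$genes, net$genes)
    return(list(P = P, mce = -sum(pi * log(pi)), flow = diag(pi)))
  }

  # marginal constraints, eliminated via an SVD null-space basis
  Aeq <- matrix(0, 2 * n, m)
  for (e in seq_len(m)) {
    Aeq[idx[e, 1], e] <- 1
    Aeq[n + idx[e, 2], e] <- 1
  }
  sv <- svd(Aeq, nu = 0, nv = m)
  r <- sum(sv$d > 1e-10 * sv$d[1])
  if (r >= m) {
    # constraints pin the flow completely
    f <- f0
  } else {
    Z <- sv$v[, (r + 1):m, drop = FALSE]
    fn <- function(t) {
      f <- f0 + as.numeric(Z %*% t)
      sum(f * log(f))
    }
    gr <- function(t) {
      f <- f0 + as.numeric(Z %*% t)
      as.numeric(crossprod(Z, 1 + log(f)))
    }
    opt <- stats::constrOptim(
      rep(0, ncol(Z)), fn, gr, ui = Z, ci = -f0, method = "BFGS",
      outer.iterations = 200, outer.eps = 1e-12,
      control = list(maxit = 1000, reltol = 1e-15)
    )
    f <- f0 + as.numeric(Z %*% opt$par)
  }
  Fm <- matrix(0, n, n)
  Fm[idx] <- f
  P <- Fm / pi
  dimnames(P) <- list(net$genes, net$genes)
  dimnames(Fm) <- list(net$genes, net$genes)
  list(P = P, mce = -sum(f * log(f)), flow = Fm)
}
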