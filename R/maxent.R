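#' Fit the maximum-entropy transition matrix of a sample
#'
#' Among all Markov chains supported on the network's (self-loop-augmented)
#' adjacency and stationary at `pi`, this returns the one whose edge-flow
#' distribution \eqn{\{\pi_i p_{ij}\}} has maximum entropy. Writing
#' \eqn{p_{ij} = \alpha_i \beta_j a_{ij}}, the optimum is the fixed point of
#' the alternating diagonal scaling
#' \deqn{\alpha_i \leftarrow 1 / \sum_j a_{ij} \beta_j, \qquad
#'       \beta_j \leftarrow \pi_j / \sum_i \pi_i \alpha_i a_{ij},}
#' i.e. Sinkhorn scaling of the support matrix to flow marginals
#' \eqn{(\pi, \pi)}. The first update enforces row-stochasticity, the second
#' stationarity.
#'
#' Convergence is certified, not assumed: the returned object records the
#' maximum row-sum deviation and the maximum stationarity deviation of the
#' final matrix, and `converged` is `FALSE` (with a warning) when the
#' iteration cap is hit. Supports on which some edge can carry no stationary
#' flow (an edge on no directed cycle) push the iteration to a boundary
#' optimum and slow it to sublinear: symmetrized topologies avoid this.
#'
#' @param net A self-loop-augmented [gene_network()] (see [add_self_loops()];
#'   the identity chain is then always feasible).
#' @param pi A [stationary_from_expression()] result, or a named strictly
#'   positive vector summing to 1. Genes absent from `pi` are dropped from
#'   the network for this sample (the zero-expression policy).
#' @param tol Convergence tolerance on the max of the two residuals.
#' @param max_iter Iteration cap.
#' @param beta0 Optional positive starting vector for the column scalings
#'   (default all ones).
#' @return An object of class `mce_fit`: sparse transition matrix `P`
#'   (dimnames = genes), `pi`, scaling vectors `alpha` and `beta`, entropy
#'   `mce` (nats), `residuals` (named: `row`, `stationarity`), `iterations`,
#'   `converged`, `tol`.
#' @export
fit_transition_matrix <- function(net, pi, tol = 1e-8, max_iter = 10000,
                                  beta0 = NULL) {
  stopifnot(inherits(net, "gene_network"))
  if (!net$augmented) {
    abort("network must be self-loop-augmented; call add_self_loops() first")
  }
  if (inherits(pi, "stationary_dist")) pi <- pi$pi
  if (is.null(names(pi))) abort("`pi` must be named by gene symbol")
  if (any(pi <= 0)) abort("`pi` must be strictly positive")
  if (abs(sum(pi) - 1) > 1e-12) abort("`pi` must sum to 1")
  stopifnot(tol > 0, max_iter >= 1)

  genes <- intersect(net$genes, names(pi))
  if (!length(genes)) abort("no overlap between network genes and `pi`")
  if (length(genes) < length(net$genes)) {
    net <- add_self_loops(induced_subnetwork(net, genes))
  }
  pi <- pi[genes]
  pi <- pi / sum(pi)
  A <- adjacency_matrix(net)
  At <- Matrix::t(A)
  n <- length(genes)

  beta <- if (is.null(beta0)) rep(1, n) else {
    stopifnot(length(beta0) == n, all(beta0 > 0))
    as.numeric(beta0)
  }
  it <- 0L
  repeat {
    it <- it + 1L
    alpha <- 1 / as.numeric(A %*% beta)
    beta <- pi / as.numeric(At %*% (pi * alpha))
    # after the beta update stationarity is exact; rows are the open residual
    res_row <- max(abs(alpha * as.numeric(A %*% beta) - 1))
    if (res_row < tol || it >= max_iter) break
  }
  P <- Diagonal(x = alpha) %*% A %*% Diagonal(x = beta)
  P <- methods::as(P, "CsparseMatrix")
  dimnames(P) <- list(genes, genes)
  res <- c(row = max(abs(Matrix::rowSums(P) - 1)),
           stationarity = max(abs(as.numeric(Matrix::crossprod(P, pi)) - pi)))
  converged <- max(res) < tol
  if (!converged) {
    warn(sprintf(
      "scaling did not reach tol = %g in %d iterations (residual %.3g); boundary optimum likely",
      tol, max_iter, max(res)
    ))
  }
  fit <- structure(
    list(P = P, pi = pi, alpha = setNames(alpha, genes),
         beta = setNames(beta, genes), residuals = res,
         iterations = it, converged = converged, tol = tol),
    class = "mce_fit"
  )
  fit$mce <- markov_chain_entropy(fit)
  fit
}

#' @export
print.mce_fit <- function(x, ...) {
  cat(sprintf(
    "<mce_fit> %d genes, MCE = %.4f nats, residual %.2e (%s in %d iter)\n",
    length(x$pi), x$mce, max(x$residuals),
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  invisible(x)
}

#' Markov chain entropy of a fitted network
#'
#' The entropy (nats) of the edge-flow distribution
#' \eqn{\mathrm{MCE} = -\sum_{(i,j)} \pi_i p_{ij} \log(\pi_i p_{ij})},
#' with \eqn{0 \log 0 := 0}. Identity support gives \eqn{H(\pi)}; complete
#' support gives \eqn{2 H(\pi)}.
#'
#' @param fit An `mce_fit`, or a transition matrix if `pi` is supplied.
#' @param pi Stationary vector matching `fit` when `fit` is a bare matrix.
#' @return Entropy in nats (scalar, >= 0).
#' @export
markov_chain_entropy <- function(fit, pi = NULL) {
  if (inherits(fit, "mce_fit")) {
    P <- fit$P
    pi <- fit$pi
  } else {
    P <- fit
    if (is.null(pi)) abort("supply `pi` with a bare transition matrix")
    if (nrow(P) != length(pi)) abort("dimension mismatch between P and pi")
  }
  f <- pi * P
  v <- if (inherits(f, "sparseMatrix")) f@x else as.numeric(f)
  v <- v[v > 0]
  -sum(v * log(v))
}

#' @rdname tidy.mce_fit
#' @export
glance.mce_fit <- function(x, ...) {
  tibble(
    n_genes = length(x$pi),
    n_edges = length(x$P@x),
    mce = x$mce,
    row_residual = unname(x$residuals["row"]),
    stationarity_residual = unname(x$residuals["stationarity"]),
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Tidy a fitted maximum-entropy chain
#'
#' `tidy()` returns one row per supported edge with its transition
#' probability and flow; `glance()` returns the one-row fit summary.
#'
#' @param x An `mce_fit`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `p` (transition probability)
#'   and `flow` (\eqn{\pi_i p_{ij}}).
#' @export
tidy.mce_fit <- function(x, ...) {
  tm <- methods::as(x$P, "TsparseMatrix")
  genes <- rownames(x$P)
  out <- tibble(
    from = genes[tm@i + 1L],
    to = genes[tm@j + 1L],
    p = tm@x,
    flow = x$pi[tm@i + 1L] * tm@x
  )
  dplyr::arrange(out, .data$from, .data$to)
}

#' Export a fitted chain as a weighted network
#'
#' Writes the support with transition probabilities as weights: TSV
#' (`source, target, weight`) or GraphML. A JSON sidecar with the entropy,
#' residual certificates, iteration count and convergence flag is written
#' next to the network when `sidecar = TRUE`.
#'
#' @param fit An `mce_fit`.
#' @param path Output file.
#' @param format `"tsv"` or `"graphml"`.
#' @param sidecar Write `<path>.json` with fit metadata.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path, format = c("tsv", "graphml"), sidecar = TRUE) {
  stopifnot(inherits(fit, "mce_fit"))
  format <- match.arg(format)
  ed <- tidy(fit)
  net <- gene_network(
    tibble(from = ed$from, to = ed$to, weight = ed$p),
    genes = rownames(fit$P)
  )
  write_network(net, path, format = format)
  if (sidecar) {
    meta <- list(
      mce = fit$mce,
      row_residual = unname(fit$residuals["row"]),
      stationarity_residual = unname(fit$residuals["stationarity"]),
      iterations = fit$iterations,
      converged = fit$converged,
      tol = fit$tol
    )
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
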