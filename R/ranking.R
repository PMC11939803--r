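#' Weighted PageRank over a reconstructed network
#'
#' Ranks genes by a damped random walk over the weighted network. Two update
#' rules are available:
#'
#' * `row_stochastic` (default): the weights are transition probabilities
#'   (rows sum to 1, as produced by [fit_transition_matrix()]), and the
#'   update \eqn{PR(v) = (1-d)/N + d \sum_u w_{uv} PR(u)} conserves mass.
#' * `as_printed`: the classical weighted variant that divides each source's
#'   contribution by its in-degree,
#'   \eqn{PR(v) = (1-d)/N + d \sum_{u \in N(v)} w_{uv} PR(u) / C_{in}(u)},
#'   with \eqn{C_{in}(u) = 0} replaced by 1. This rule does not conserve
#'   mass, so the vector is renormalised every sweep.
#'
#' Iteration starts from the uniform vector and stops when the L1 change of
#' a sweep falls below `tol`.
#'
#' @param x An `mce_fit` (its transition matrix is the weight matrix) or a
#'   [gene_network()] whose edges carry a `weight` column (unit weights
#'   assumed when absent).
#' @param d Damping factor in \[0, 1) (default 0.85).
#' @param mode `"row_stochastic"` or `"as_printed"`.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A tibble of class `pagerank_scores` with columns `gene`, `score`
#'   (strictly positive, summing to 1); attributes `mode`, `d`,
#'   `iterations`, `residual`, `converged`.
#' @export
weighted_pagerank <- function(x, d = 0.85, mode = c("row_stochastic", "as_printed"),
                              tol = 1e-10, max_iter = 1000) {
  mode <- match.arg(mode)
  stopifnot(d >= 0, d < 1)
  if (inherits(x, "mce_fit")) {
    W <- x$P
    genes <- rownames(W)
  } else if (inherits(x, "gene_network")) {
    genes <- x$genes
    w <- if ("weight" %in% names(x$edges)) x$edges$weight else rep(1, nrow(x$edges))
    if (any(w < 0)) abort("edge weights must be nonnegative")
    W <- sparseMatrix(i = match(x$edges$from, genes),
                      j = match(x$edges$to, genes), x = w,
                      dims = c(length(genes), length(genes)),
                      dimnames = list(genes, genes))
  } else {
    abort("`x` must be an mce_fit or a gene_network")
  }
  n <- length(genes)
  Wt <- Matrix::t(W)
  if (mode == "as_printed") {
    cin <- pmax(Matrix::colSums(W != 0), 1)  # in-edge count of each source
  }
  pr <- rep(1 / n, n)
  it <- 0L
  repeat {
    it <- it + 1L
    contrib <- if (mode == "row_stochastic") pr else pr / cin
    pr2 <- (1 - d) / n + d * as.numeric(Wt %*% contrib)
    pr2 <- pr2 / sum(pr2)
    delta <- sum(abs(pr2 - pr))
    pr <- pr2
    if (delta < tol || it >= max_iter) break
  }
  converged <- delta < tol
  if (!converged) warn("PageRank did not converge within max_iter")
  out <- tibble(gene = genes, score = pr)
  class(out) <- c("pagerank_scores", class(out))
  attr(out, "mode") <- mode
  attr(out, "d") <- d
  attr(out, "iterations") <- it
  attr(out, "residual") <- delta
  attr(out, "converged") <- converged
  out
}

#' Cluster genes by their PageRank score
#'
#' One-dimensional k-means on the scores, with k-means++ seeding and
#' `restarts` random restarts (best within-cluster sum of squares kept).
#' Cluster ids are canonicalised by ascending cluster mean, so id `k` is
#' always the top-score cluster and assignments are comparable across
#' samples. Deterministic given `seed`.
#'
#' @param scores A `pagerank_scores` tibble (or any tibble with `gene` and
#'   `score` columns).
#' @param k Number of clusters (default 10); must not exceed the number of
#'   distinct scores.
#' @param seed Integer seed for the restarts.
#' @param restarts Number of k-means++ restarts (default 10).
#' @return A tibble `gene`, `cluster` (integer in 1..k, ascending score).
#' @export
kmeans_scores <- function(scores, k = 10, seed = 1, restarts = 10) {
  stopifnot(all(c("gene", "score") %in% names(scores)))
  x <- scores$score
  ux <- unique(x)
  if (k > length(ux)) abort("k exceeds the number of distinct score values")
  km <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      cen <- kmeanspp_centers(ux, k)
      fit <- suppressWarnings(
        kmeans(x, centers = cen, iter.max = 100, algorithm = "Lloyd")
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
  relabel <- match(km$cluster, order(km$centers))
  tibble(gene = scores$gene, cluster = as.integer(relabel))
}

# k-means++ seeding on distinct 1-d values
kmeanspp_centers <- function(ux, k) {
  cen <- numeric(k)
  cen[1] <- ux[sample.int(length(ux), 1)]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- vapply(ux, function(v) min((v - cen[seq_len(j - 1)])^2), 0)
      cen[j] <- if (sum(d2) > 0) {
        ux[sample.int(length(ux), 1, prob = d2)]
      } else {
        ux[sample.int(length(ux), 1)]
      }
    }
  }
  sort(cen)
}

#' Entropy of a cluster-size distribution
#'
#' Shannon entropy (nats) of the cluster occupancy
#' \eqn{-\sum_c (n_c/n) \log(n_c/n)}: 0 when everything is in one cluster,
#' \eqn{\log k} when the k clusters are equally filled. Used as a
#' diagnostic for choosing the cluster count.
#'
#' @param assignment A [kmeans_scores()] tibble (columns `gene`, `cluster`).
#' @return Entropy in nats.
#' @export
cluster_count_entropy <- function(assignment) {
  stopifnot("cluster" %in% names(assignment))
  if (!nrow(assignment)) abort("empty assignment")
  p <- as.numeric(table(assignment$cluster)) / nrow(assignment)
  -sum(p * log(p))
}

#' Cluster-count entropy curve
#'
#' Clusters every sample's scores for each k in `k_min:k_max` and reports
#' the mean cluster-size entropy per k. The elbow of this curve guides the
#' choice of the cluster count.
#'
#' @param score_list Named list of `pagerank_scores` (one per sample).
#' @param k_min,k_max Range of cluster counts (defaults 5 and 15).
#' @param seed Seed forwarded to [kmeans_scores()].
#' @return A tibble `k`, `entropy` (mean over samples).
#' @export
cluster_entropy_curve <- function(score_list, k_min = 5, k_max = 15, seed = 1) {
  stopifnot(k_min >= 1, k_max >= k_min)
  purrr::map_dfr(k_min:k_max, function(k) {
    ent <- purrr::map_dbl(score_list, function(sc) {
      cluster_count_entropy(kmeans_scores(sc, k = k, seed = seed))
    })
    tibble(k = k, entropy = mean(ent))
  })
}
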