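#' Classify methylation beta values
#'
#' Standard three-way thresholding of beta values: `>= upper` is fully
#' methylated, `<= lower` unmethylated, anything strictly between is
#' partially methylated. Missing values propagate as `NA`.
#'
#' @param beta Numeric vector of beta values in \[0, 1\] (NA allowed).
#' @param lower Unmethylated threshold (default 0.2, inclusive).
#' @param upper Fully-methylated threshold (default 0.6, inclusive).
#' @return A factor with levels `unmethylated`, `partially_methylated`,
#'   `fully_methylated`; `NA` where `beta` is missing.
#' @export
classify_beta <- function(beta, lower = 0.2, upper = 0.6) {
  stopifnot(lower >= 0, upper <= 1, lower < upper)
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) abort("beta values must lie in [0, 1]")
  lv <- c("unmethylated", "partially_methylated", "fully_methylated")
  out <- ifelse(is.na(beta), NA_character_,
                ifelse(beta >= upper, lv[3],
                       ifelse(beta <= lower, lv[1], lv[2])))
  factor(out, levels = lv)
}

#' Build the methylation-pruned network G1 of a sample
#'
#' Fully methylated genes are assumed transcriptionally silenced and are
#' deleted (with their incident edges) from the sample's network. Self-loops
#' are re-asserted on the survivors and the stationary distribution is
#' renormalised over them. Genes with a missing beta value are retained —
#' absence of evidence of methylation — and reported.
#'
#' @param net A self-loop-augmented [gene_network()] (the G0 topology).
#' @param beta Named beta-value vector for one sample (NA = missing).
#' @param x Named expression vector for the same sample.
#' @param lower,upper Thresholds passed to [classify_beta()].
#' @param policy,epsilon Zero-expression handling, as in
#'   [stationary_from_expression()].
#' @return A list of class `g1_network`: `network` (the pruned, re-augmented
#'   [gene_network()]), `pi` (a `stationary_dist` over survivors), `pruned`
#'   (character: deleted genes), `missing_beta` (character: genes retained
#'   for lack of a measurement).
#' @export
build_g1 <- function(net, beta, x, lower = 0.2, upper = 0.6,
                     policy = c("drop_zero", "pseudocount"), epsilon = 1e-6) {
  stopifnot(inherits(net, "gene_network"))
  policy <- match.arg(policy)
  if (is.null(names(beta)) || is.null(names(x))) {
    abort("`beta` and `x` must be named by gene symbol")
  }
  call <- classify_beta(beta[net$genes], lower, upper)
  pruned <- net$genes[!is.na(call) & call == "fully_methylated"]
  missing_beta <- net$genes[is.na(call)]
  survivors <- setdiff(net$genes, pruned)
  if (!length(survivors)) abort("empty G1: every gene is fully methylated")
  g1 <- add_self_loops(induced_subnetwork(net, survivors))
  xs <- x[survivors]
  xs[is.na(xs)] <- 0
  pi1 <- stationary_from_expression(xs, policy = policy, epsilon = epsilon)
  structure(
    list(network = g1, pi = pi1, pruned = pruned, missing_beta = missing_beta),
    class = "g1_network"
  )
}

#' Per-gene Markov flow entropy
#'
#' Decomposes the Markov chain entropy into per-gene contributions: for each
#' gene, the entropy of its outgoing flows,
#' \eqn{\mathrm{MFE}(i) = -\sum_j \pi_i p_{ij} \log(\pi_i p_{ij})}.
#' The contributions partition the total: their sum is exactly the MCE.
#' `direction = "in"` instead attributes each flow to its target gene
#' (\eqn{-\sum_j \pi_j p_{ji} \log(\pi_j p_{ji})}), the in-flow reading of
#' how strongly a gene is influenced by the rest of the network; it
#' partitions the MCE equally.
#'
#' @param fit An `mce_fit`.
#' @param direction `"out"` (default) or `"in"`.
#' @return A tibble with columns `gene`, `mfe` (nats, >= 0), in network
#'   gene order; attribute `"direction"` records the variant.
#' @export
markov_flow_entropy <- function(fit, direction = c("out", "in")) {
  stopifnot(inherits(fit, "mce_fit"))
  direction <- match.arg(direction)
  flow <- fit$pi * fit$P          # flow_ij = pi_i p_ij
  tm <- methods::as(flow, "TsparseMatrix")
  v <- tm@x
  term <- ifelse(v > 0, -v * log(v), 0)
  who <- if (direction == "out") tm@i + 1L else tm@j + 1L
  mfe <- rowsum_by(term, who, length(fit$pi))
  out <- tibble(gene = names(fit$pi), mfe = mfe)
  class(out) <- c("mfe_vector", class(out))
  attr(out, "direction") <- direction
  out
}

rowsum_by <- function(x, g, n) {
  out <- numeric(n)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Network methylation index
#'
#' Relative change of each gene's flow entropy when fully methylated genes
#' are removed from the network:
#' \eqn{\rho(i) = (\mathrm{MFE}_1(i) - \mathrm{MFE}_0(i)) / \mathrm{MFE}_0(i)}.
#' Negative values mean the methylation of other genes suppresses the flow
#' through gene `i` (inhibitory); positive values mean it concentrates flow
#' through it (facilitatory). `rho` is `NA` where the gene was pruned from
#' G1 or its G0 flow entropy is zero.
#'
#' @param mfe0 [markov_flow_entropy()] of the G0 fit.
#' @param mfe1 [markov_flow_entropy()] of the matching G1 fit.
#' @return A tibble `gene`, `mfe0`, `mfe1`, `rho` over the G0 genes.
#' @export
network_methylation_index <- function(mfe0, mfe1) {
  d0 <- attr(mfe0, "direction")
  d1 <- attr(mfe1, "direction")
  if (!is.null(d0) && !is.null(d1) && d0 != d1) {
    abort("mfe0 and mfe1 use different flow directions")
  }
  out <- dplyr::left_join(
    dplyr::rename(mfe0, mfe0 = "mfe"),
    dplyr::rename(mfe1, mfe1 = "mfe"),
    by = "gene"
  )
  dplyr::mutate(out, rho = dplyr::if_else(
    !is.na(.data$mfe1) & .data$mfe0 > 0,
    (.data$mfe1 - .data$mfe0) / .data$mfe0,
    NA_real_
  ))
}

#' Census of missing methylation indices
#'
#' Counts, per gene, the samples in which the methylation index is absent —
#' the gene was pruned from G1 (or carried no G0 flow). Genes with many
#' absences are recurrently silenced across the cohort.
#'
#' @param rho_table Long tibble with columns `gene`, `sample`, `rho`
#'   (see [run_methylation()]), `NA` marking absence.
#' @param genes Optional candidate list restricting and ordering the census;
#'   unknown genes draw a warning and count over available samples (0).
#' @return A tibble `gene`, `n_missing`, sorted by descending count, ties
#'   broken by symbol order.
#' @export
absence_census <- function(rho_table, genes = NULL) {
  stopifnot(all(c("gene", "sample", "rho") %in% names(rho_table)))
  if (!nrow(rho_table)) abort("rho table covers no samples")
  out <- dplyr::summarise(
    dplyr::group_by(rho_table, .data$gene),
    n_missing = sum(is.na(.data$rho)),
    .groups = "drop"
  )
  if (!is.null(genes)) {
    unknown <- setdiff(genes, out$gene)
    if (length(unknown)) {
      warn(sprintf("%d candidate gene(s) absent from the rho table", length(unknown)))
      out <- dplyr::bind_rows(out, tibble(gene = unknown, n_missing = 0L))
    }
    out <- out[out$gene %in% genes, , drop = FALSE]
  }
  dplyr::arrange(out, dplyr::desc(.data$n_missing), .data$gene)
}
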