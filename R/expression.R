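#' Read a gene x sample expression matrix
#'
#' Expects a TSV with the gene symbol in the first column and one column per
#' sample. Values must be nonnegative and finite.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix, genes in rows (rownames = symbols), samples in
#'   columns.
#' @export
read_expression_matrix <- function(path) {
  m <- read_gene_matrix(path)
  if (anyNA(m) || any(!is.finite(m))) abort("expression values must be finite")
  if (any(m < 0)) abort("expression values must be nonnegative")
  m
}

#' Read a gene x sample methylation beta matrix
#'
#' Same layout as [read_expression_matrix()]. Values must lie in \[0, 1\];
#' empty cells or `NA` mark missing measurements and are preserved as `NA`.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with `NA` for missing entries. When a symbol has
#'   several rows (probe-level leftovers) they are averaged with a warning.
#' @export
read_beta_matrix <- function(path) {
  m <- read_gene_matrix(path, dedupe = "mean")
  ok <- is.na(m) | (m >= 0 & m <= 1)
  if (!all(ok)) abort("beta values must lie in [0, 1]")
  m
}

read_gene_matrix <- function(path, dedupe = c("error", "mean")) {
  dedupe <- match.arg(dedupe)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, na = c("", "NA"))
  genes <- trimws(df[[1]])
  m <- as.matrix(df[-1])
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    if (dedupe == "error") abort("duplicate gene symbols in matrix")
    warn("averaging rows of duplicated gene symbols")
    m <- rowsum(m, group = genes, reorder = FALSE, na.rm = TRUE) /
      rowsum((!is.na(m)) * 1, group = genes, reorder = FALSE)
  }
  m
}

#' Write a gene x sample matrix as TSV
#'
#' First column `gene`, then one column per sample; `NA` is written for
#' missing entries.
#' @param m Matrix with gene rownames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_matrix <- function(m, path) {
  df <- dplyr::bind_cols(tibble(gene = rownames(m)), as_tibble(m))
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Align a matrix to a network's gene set
#'
#' Rows for genes absent from the network are dropped with a warning; network
#' genes with no row are filled with `fill` (default 0 — they are then
#' subject to the zero-expression policy of [stationary_from_expression()]).
#'
#' @param m Gene x sample matrix with rownames.
#' @param net A [gene_network()].
#' @param fill Value for network genes without a row.
#' @return Matrix with rows exactly `net$genes`, in network order.
#' @export
align_to_network <- function(m, net, fill = 0) {
  stopifnot(inherits(net, "gene_network"))
  extra <- setdiff(rownames(m), net$genes)
  if (length(extra)) {
    warn(sprintf("dropping %d gene(s) not in the network", length(extra)))
  }
  out <- matrix(fill, nrow = length(net$genes), ncol = ncol(m),
                dimnames = list(net$genes, colnames(m)))
  common <- intersect(net$genes, rownames(m))
  out[common, ] <- m[common, , drop = FALSE]
  out
}

#' Stationary distribution from an expression vector
#'
#' The L1-normalised expression of a sample serves as the invariant
#' distribution of its Markov chain. The stationary vector must be strictly
#' positive, so zero-expression genes are handled by policy: `drop_zero`
#' removes them (the gene is excluded from that sample's network before
#' fitting), `pseudocount` adds `epsilon` to every entry first.
#'
#' @param x Named nonnegative expression vector.
#' @param policy `"drop_zero"` (default) or `"pseudocount"`.
#' @param epsilon Pseudocount added under `policy = "pseudocount"`.
#' @return A list of class `stationary_dist`: `pi` (named, sums to 1,
#'   strictly positive) and `retained` (character vector of kept genes).
#' @export
stationary_from_expression <- function(x, policy = c("drop_zero", "pseudocount"),
                                       epsilon = 1e-6) {
  policy <- match.arg(policy)
  if (anyNA(x) || any(!is.finite(x))) abort("expression must be finite")
  if (any(x < 0)) abort("expression must be nonnegative")
  if (all(x == 0)) abort("degenerate sample: all-zero expression")
  if (is.null(names(x))) names(x) <- as.character(seq_along(x))
  if (policy == "pseudocount") x <- x + epsilon
  keep <- x > 0
  pi <- x[keep] / sum(x[keep])
  structure(list(pi = pi, retained = names(x)[keep]), class = "stationary_dist")
}

#' @export
print.stationary_dist <- function(x, ...) {
  cat(sprintf("<stationary_dist> %d genes, sum = %.6f\n",
              length(x$pi), sum(x$pi)))
  invisible(x)
}
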