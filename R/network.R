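#' Construct a gene network from an edge table
#'
#' A `gene_network` is a directed graph over a fixed, ordered set of gene
#' symbols. It is the support of every transition matrix fitted by
#' [fit_transition_matrix()]: an edge `(i, j)` permits probability flow from
#' gene `i` to gene `j`, and nothing flows where there is no edge.
#'
#' Gene symbols are case-sensitive and whitespace-trimmed. Duplicate edges
#' collapse with a warning. Self-loops may be present from the start or added
#' later with [add_self_loops()].
#'
#' @param edges A data frame with character columns `from` and `to` (extra
#'   columns are kept; a `weight` column is used by exporters).
#' @param genes Optional character vector fixing the gene universe and its
#'   order. Defaults to the genes appearing in `edges`, in order of first
#'   appearance. Must cover all edge endpoints.
#' @return A `gene_network` object: a list with elements `genes` (character),
#'   `edges` (tibble with columns `from`, `to`, ...), and `augmented`
#'   (logical, `TRUE` once self-loops have been asserted on every gene).
#' @seealso [read_network()], [add_self_loops()], [symmetrize_network()]
#' @export
gene_network <- function(edges, genes = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` must have columns `from` and `to`.")
  }
  edges$from <- trimws(as.character(edges$from))
  edges$to <- trimws(as.character(edges$to))
  dup <- duplicated(edges[c("from", "to")])
  if (any(dup)) {
    warn(sprintf("dropping %d duplicate edge(s)", sum(dup)))
    edges <- edges[!dup, , drop = FALSE]
  }
  if (is.null(genes)) {
    genes <- unique(c(rbind(edges$from, edges$to)))
  } else {
    genes <- trimws(as.character(genes))
    if (anyDuplicated(genes)) {
      warn("collapsing duplicate gene symbols")
      genes <- unique(genes)
    }
    missing <- setdiff(unique(c(edges$from, edges$to)), genes)
    if (length(missing)) {
      abort(sprintf(
        "edge endpoints not in `genes`: %s",
        paste(head(missing, 5), collapse = ", ")
      ))
    }
  }
  if (length(genes) < 1) abort("a network needs at least one gene")
  structure(
    list(genes = genes, edges = edges,
         augmented = all(genes %in% edges$from[edges$from == edges$to])),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "<gene_network> %d genes, %d edges%s\n",
    length(x$genes), nrow(x$edges),
    if (x$augmented) " (self-loops asserted)" else ""
  ))
  invisible(x)
}

#' Read a gene network from disk
#'
#' Two dialects are supported. `edge_tsv` is a plain tab-separated edge list:
#' one `source<TAB>target` pair per line, `#` lines ignored. `biogrid_tab3`
#' is the BioGRID TAB3 export; the official-symbol columns of interactors A
#' and B are used, oriented A -> B (set `symmetrize = TRUE` to mirror every
#' edge, which is the usual treatment of physical interactions whose
#' direction is not meaningful).
#'
#' @param path Path to the file.
#' @param format `"edge_tsv"` or `"biogrid_tab3"`.
#' @param symmetrize Mirror every edge after reading (default `FALSE`).
#' @return A [gene_network()]; self-loops are *not* added here.
#' @export
read_network <- function(path, format = c("edge_tsv", "biogrid_tab3"),
                         symmetrize = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  net <- switch(format,
    edge_tsv = read_edge_tsv(path),
    biogrid_tab3 = read_biogrid_tab3(path)
  )
  if (symmetrize) net <- symmetrize_network(net)
  net
}

read_edge_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) abort(sprintf("no edges in %s", path))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    bad <- which(keep)[which(nf < 2)[1]]
    abort(sprintf("parse error at line %d of %s: expected 2 tab-separated columns",
                  bad, path))
  }
  gene_network(tibble(
    from = vapply(fields, `[[`, "", 1L),
    to = vapply(fields, `[[`, "", 2L)
  ))
}

read_biogrid_tab3 <- function(path) {
  header <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  ia <- grep("^Official Symbol Interactor A$", cols)
  ib <- grep("^Official Symbol Interactor B$", cols)
  if (!length(ia) || !length(ib)) {
    abort("not a BioGRID TAB3 file: official symbol columns missing")
  }
  body <- readr::read_tsv(path, skip = 1L, col_names = cols,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  if (!nrow(body)) abort(sprintf("no edges in %s", path))
  gene_network(tibble(from = body[[ia]], to = body[[ib]]))
}

#' Assert a self-loop on every gene
#'
#' The fitted chain must be able to stay put: with a full diagonal the
#' identity matrix is always a feasible transition matrix, so the
#' maximum-entropy program has a solution on any topology. Idempotent and
#' monotone (never removes an edge).
#'
#' @param net A [gene_network()].
#' @return The network with `a_ii = 1` for every gene.
#' @export
add_self_loops <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  have <- unique(net$edges$from[net$edges$from == net$edges$to])
  need <- setdiff(net$genes, have)
  if (length(need)) {
    net$edges <- dplyr::bind_rows(net$edges, tibble(from = need, to = need))
  }
  net$augmented <- TRUE
  net
}

#' Mirror every directed edge
#'
#' Adds the reverse of each edge, so the support becomes symmetric. Useful
#' for physical-interaction networks whose records are not oriented, and
#' required for a well-behaved maximum-entropy fit: with every edge on a
#' 2-cycle (plus self-loops) the optimum is interior and the scaling
#' iteration converges geometrically.
#'
#' @param net A [gene_network()].
#' @return The symmetrized network.
#' @export
symmetrize_network <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  rev <- tibble(from = net$edges$to, to = net$edges$from)
  both <- dplyr::bind_rows(net$edges[c("from", "to")], rev)
  both <- both[!duplicated(both), , drop = FALSE]
  out <- net
  out$edges <- both
  out$augmented <- all(net$genes %in% both$from[both$from == both$to])
  out
}

#' Sparse adjacency matrix of a network
#'
#' @param net A [gene_network()].
#' @return A sparse 0/1 `dgCMatrix` with dimnames = gene symbols, rows =
#'   edge sources.
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  idx_from <- match(net$edges$from, net$genes)
  idx_to <- match(net$edges$to, net$genes)
  n <- length(net$genes)
  a <- sparseMatrix(i = idx_from, j = idx_to, x = 1,
                    dims = c(n, n), dimnames = list(net$genes, net$genes))
  a@x[] <- 1
  a
}

#' Restrict a network to a subset of genes
#'
#' Keeps the induced subgraph; gene order is preserved. Self-loops are not
#' re-asserted automatically.
#' @param net A [gene_network()].
#' @param genes Character vector of genes to keep.
#' @return The induced [gene_network()].
#' @export
induced_subnetwork <- function(net, genes) {
  stopifnot(inherits(net, "gene_network"))
  genes <- intersect(net$genes, genes)
  if (!length(genes)) abort("no genes left after restriction")
  keep <- net$edges$from %in% genes & net$edges$to %in% genes
  out <- net
  out$genes <- genes
  out$edges <- net$edges[keep, , drop = FALSE]
  out$augmented <- all(genes %in% out$edges$from[out$edges$from == out$edges$to])
  out
}

#' Write a network to disk
#'
#' `"tsv"` writes a (source, target\[, weight\]) tab-separated edge list;
#' `"graphml"` writes GraphML via igraph, carrying a `weight` edge attribute
#' when present.
#'
#' @param net A [gene_network()]; an optional `weight` column on the edges
#'   is exported.
#' @param path Output file.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(net, "gene_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    cols <- intersect(c("from", "to", "weight"), names(net$edges))
    writeLines(paste0("# ", paste(cols, collapse = "\t")), path)
    readr::write_tsv(net$edges[cols], path, col_names = FALSE,
                     append = TRUE, progress = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                       vertices = net$genes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' In-strength distribution of a fitted transition matrix
#'
#' Column sums of the transition matrix are the continuous analogue of
#' in-degrees ("in-strengths"). They are binned on a log scale, the natural
#' choice for the heavy-tailed strengths that scale-free topologies produce.
#'
#' @param fit An [mce_fit] from [fit_transition_matrix()].
#' @param n_bins Number of log-spaced bins (>= 1).
#' @return A tibble with columns `bin`, `lower`, `upper`, `count`; counts sum
#'   to the number of genes. The raw strengths are attached as attribute
#'   `"strengths"`.
#' @export
in_strength_distribution <- function(fit, n_bins = 20) {
  if (!inherits(fit, "mce_fit")) abort("`fit` must be a fitted mce_fit")
  stopifnot(n_bins >= 1)
  s <- Matrix::colSums(fit$P)
  lo <- min(s)
  hi <- max(s)
  if (hi - lo < .Machine$double.eps * max(1, hi)) {
    out <- tibble(bin = 1L, lower = lo, upper = hi, count = length(s))
  } else {
    breaks <- exp(seq(log(lo), log(hi), length.out = n_bins + 1))
    breaks[1] <- lo
    breaks[n_bins + 1] <- hi
    idx <- findInterval(s, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    out <- tibble(
      bin = seq_len(n_bins),
      lower = breaks[-(n_bins + 1)],
      upper = breaks[-1],
      count = tabulate(idx, n_bins)
    )
  }
  attr(out, "strengths") <- setNames(as.numeric(s), names(s))
  out
}
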