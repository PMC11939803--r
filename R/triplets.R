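#' Triplet co-occurrence of candidate genes across samples
#'
#' For every sample, each 3-subset of candidate genes that falls inside a
#' single cluster increments that triple's count by one. Triples are
#' order-free; only triples seen at least once are returned. A combinatorial
#' guard refuses candidate panels larger than 200 genes.
#'
#' @param assignments Long tibble with columns `sample`, `gene`, `cluster` —
#'   cluster assignments of one network label (G0 or G1) across samples.
#'   Genes absent from a sample (e.g. pruned from G1) simply carry no rows.
#' @param candidates Character vector of candidate genes (the panel entering
#'   the triplet analysis).
#' @return A tibble `gene1`, `gene2`, `gene3` (lexicographically sorted
#'   within each triple), `count`, arranged by descending count then
#'   lexicographic triple order.
#' @export
triplet_cooccurrence <- function(assignments, candidates) {
  stopifnot(all(c("sample", "gene", "cluster") %in% names(assignments)))
  candidates <- unique(candidates)
  if (length(candidates) > 200) {
    abort("candidate panel exceeds 200 genes; subset it before the triplet analysis")
  }
  sub <- assignments[assignments$gene %in% candidates, , drop = FALSE]
  counts <- new.env(parent = emptyenv())
  for (s in unique(sub$sample)) {
    rows <- sub[sub$sample == s, , drop = FALSE]
    for (cl in unique(rows$cluster)) {
      inc <- sort(rows$gene[rows$cluster == cl])
      if (length(inc) >= 3) {
        trips <- combn(inc, 3)
        keys <- apply(trips, 2, paste, collapse = "\t")
        for (key in keys) {
          counts[[key]] <- (counts[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    return(tibble(gene1 = character(), gene2 = character(),
                  gene3 = character(), count = integer()))
  }
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- tibble(
    gene1 = vapply(parts, `[[`, "", 1),
    gene2 = vapply(parts, `[[`, "", 2),
    gene3 = vapply(parts, `[[`, "", 3),
    count = vapply(keys, function(k) counts[[k]], 0L, USE.NAMES = FALSE)
  )
  dplyr::arrange(out, dplyr::desc(.data$count),
                 .data$gene1, .data$gene2, .data$gene3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable core genes from two triplet tables
#'
#' Takes the `top_n` highest-count triples from the G0 table and from the G1
#' table (ties at the boundary broken by lexicographic triple order, so the
#' cut is deterministic), flattens each into a deduplicated gene list, and
#' returns the intersection: genes that rank highly and co-cluster stably
#' whether or not methylated genes are present.
#'
#' @param table_g0,table_g1 [triplet_cooccurrence()] tables for the G0 and
#'   G1 networks.
#' @param top_n Number of top triples kept per table (default 100). When a
#'   table has fewer triples, all are used with a notice.
#' @return Sorted character vector of core genes; attributes `genes_g0` and
#'   `genes_g1` carry the two flattened lists. An empty intersection is a
#'   valid result and draws a warning.
#' @export
core_set <- function(table_g0, table_g1, top_n = 100) {
  if (!nrow(table_g0) || !nrow(table_g1)) abort("triplet tables must be nonempty")
  flatten_top <- function(tab, label) {
    if (nrow(tab) < top_n) {
      inform(sprintf("%s: only %d triples available (top_n = %d); using all",
                     label, nrow(tab), top_n))
    }
    tab <- dplyr::arrange(tab, dplyr::desc(.data$count),
                          .data$gene1, .data$gene2, .data$gene3)
    top <- head(tab, top_n)
    sort(unique(c(top$gene1, top$gene2, top$gene3)))
  }
  g0 <- flatten_top(table_g0, "G0")
  g1 <- flatten_top(table_g1, "G1")
  core <- intersect(g0, g1)
  if (!length(core)) warn("empty core: the G0 and G1 gene lists are disjoint")
  structure(sort(core), genes_g0 = g0, genes_g1 = g1)
}

#' Core subnetwork and bridge genes
#'
#' The core subnetwork is induced by the core genes together with their
#' first-order neighbors (in- and out-). Bridge genes are the non-core nodes
#' adjacent — ignoring edge direction and self-loops — to at least two
#' distinct core genes: they relay information between core modules.
#'
#' @param net A [gene_network()] (typically the G0 topology).
#' @param core Nonempty character vector of core genes, all in the network.
#' @return A list of class `core_gene_result`: `core_genes`, `bridge_genes`,
#'   `subnetwork` (a [gene_network()]).
#' @export
core_subnetwork_and_bridges <- function(net, core) {
  stopifnot(inherits(net, "gene_network"))
  core <- unique(as.character(core))
  if (!length(core)) abort("empty core gene set")
  if (!all(core %in% net$genes)) {
    abort(sprintf("core genes not in network: %s",
                  paste(head(setdiff(core, net$genes), 5), collapse = ", ")))
  }
  ed <- net$edges[net$edges$from != net$edges$to, c("from", "to")]
  nbrs <- unique(c(ed$to[ed$from %in% core], ed$from[ed$to %in% core]))
  members <- union(core, nbrs)
  sub <- induced_subnetwork(net, intersect(net$genes, members))
  # distinct core partners of each non-core node, direction-ignored
  touch <- dplyr::bind_rows(
    tibble(node = ed$from, partner = ed$to),
    tibble(node = ed$to, partner = ed$from)
  )
  touch <- touch[!(touch$node %in% core) & touch$partner %in% core, ]
  touch <- touch[!duplicated(touch), ]
  deg <- table(touch$node)
  bridges <- sort(names(deg)[deg >= 2])
  structure(
    list(core_genes = sort(core), bridge_genes = bridges, subnetwork = sub),
    class = "core_gene_result"
  )
}

#' @export
print.core_gene_result <- function(x, ...) {
  cat(sprintf("<core_gene_result> %d core, %d bridge, subnetwork of %d genes\n",
              length(x$core_genes), length(x$bridge_genes),
              length(x$subnetwork$genes)))
  invisible(x)
}

#' Tidy a core/bridge result
#'
#' One row per gene in the core subnetwork with its role.
#' @param x A `core_gene_result`.
#' @param ... Unused.
#' @return Tibble `gene`, `role` (`core`, `bridge`, or `neighbor`).
#' @export
tidy.core_gene_result <- function(x, ...) {
  tibble(gene = x$subnetwork$genes) |>
    dplyr::mutate(role = dplyr::case_when(
      .data$gene %in% x$core_genes ~ "core",
      .data$gene %in% x$bridge_genes ~ "bridge",
      TRUE ~ "neighbor"
    )) |>
    dplyr::arrange(.data$role, .data$gene)
}
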