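# small builders shared across the suite

toy_network <- function(edges, genes = NULL, loops = TRUE) {
  net <- gene_network(tibble::tibble(
    from = vapply(edges, `[[`, "", 1),
    to = vapply(edges, `[[`, "", 2)
  ), genes = genes)
  if (loops) net <- add_self_loops(net)
  net
}

# complete directed graph (self-loops included)
complete_network <- function(genes) {
  ed <- expand.grid(from = genes, to = genes, stringsAsFactors = FALSE)
  add_self_loops(gene_network(tibble::as_tibble(ed), genes = genes))
}

# self-loops only
loops_network <- function(genes) {
  add_self_loops(gene_network(
    tibble::tibble(from = genes, to = genes), genes = genes))
}

# random strongly connected digraph with self-loops, n <= 8
random_strong_network <- function(n, p = 0.5) {
  genes <- LETTERS[seq_len(n)]
  repeat {
    a <- matrix(stats::rbinom(n * n, 1, p), n, n)
    diag(a) <- 1
    g <- igraph::graph_from_adjacency_matrix(a, mode = "directed")
    if (igraph::is_connected(g, mode = "strong")) break
  }
  idx <- which(a == 1, arr.ind = TRUE)
  add_self_loops(gene_network(
    tibble::tibble(from = genes[idx[, 1]], to = genes[idx[, 2]]),
    genes = genes))
}

random_pi <- function(genes) {
  x <- stats::runif(length(genes), 0.05, 1)
  stats::setNames(x / sum(x), genes)
}

# shared study-scale fixture: symmetrized scale-free topology + expression
study_topology <- function(n, m_attach = 3, seed = 1) {
  add_self_loops(symmetrize_network(simulate_network(n, m_attach, seed = seed)))
}

# weighted star: 3 leaves -> center with p = 1; center -> leaves with p = 1/3
star_fit <- function() {
  genes <- c("c", "l1", "l2", "l3")
  ed <- tibble::tibble(
    from = c("l1", "l2", "l3", "c", "c", "c"),
    to = c("c", "c", "c", "l1", "l2", "l3"),
    weight = c(1, 1, 1, 1 / 3, 1 / 3, 1 / 3)
  )
  gene_network(ed, genes = genes)
}

# planted-module recovery harness: one generator seed -> core Jaccard vs truth
recover_core_jaccard <- function(seed, top_n = 20) {
  study <- simulate_study(seed = seed)
  cfg <- mce_config(
    network = study$network, expression = study$expression,
    beta = study$beta, candidates = study$candidates,
    top_n = top_n, seed = seed, max_iter = 50000
  )
  res <- suppressMessages(run_core(cfg))
  core <- res$core$core_genes
  truth <- study$truth$module
  length(intersect(core, truth)) / length(union(core, truth))
}
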