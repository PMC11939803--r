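#' Scale-free directed network by preferential attachment
#'
#' Barabási–Albert-style growth: a seed clique of `m_attach + 1` nodes
#' (directed i -> j for i < j), then each new node draws `m_attach` distinct
#' existing targets with probability proportional to degree + 1 and points
#' at them (new -> target). The resulting degree distribution has a
#' power-law tail. The raw orientation is acyclic; analyses that need a
#' well-posed stationary chain symmetrize the topology first
#' (see [symmetrize_network()]).
#'
#' @param n Number of genes.
#' @param m_attach Edges per new node (default 3); must satisfy
#'   `n > m_attach >= 1`.
#' @param seed Integer seed; the edge set is a pure function of
#'   `(n, m_attach, seed)`.
#' @param prefix Gene symbol prefix (symbols are `prefix` + zero-padded id).
#' @return A [gene_network()] with `n` genes and
#'   `m_attach * (n - m_attach - 1) + choose(m_attach + 1, 2)` edges,
#'   without self-loops.
#' @export
simulate_network <- function(n, m_attach = 3, seed = 1, prefix = "G") {
  stopifnot(n > m_attach, m_attach >= 1)
  genes <- sprintf(paste0(prefix, "%0", max(3, nchar(n)), "d"), seq_len(n))
  el <- withr::with_seed(seed, {
    n0 <- m_attach + 1
    seed_edges <- t(combn(n0, 2))
    deg <- tabulate(c(seed_edges), n)
    parts <- list(seed_edges)
    for (v in seq(n0 + 1, length.out = n - n0)) {
      tgt <- sample.int(v - 1, m_attach, prob = deg[seq_len(v - 1)] + 1)
      parts[[length(parts) + 1]] <- cbind(v, tgt)
      deg[tgt] <- deg[tgt] + 1
      deg[v] <- deg[v] + m_attach
    }
    do.call(rbind, parts)
  })
  gene_network(tibble(from = genes[el[, 1]], to = genes[el[, 2]]), genes = genes)
}

#' Synthetic expression with a planted co-expressed module
#'
#' Background genes draw i.i.d. log-normal(0, 1) values per sample. Module
#' genes instead share a common per-sample level of magnitude `effect` with
#' a small within-module dispersion (`module_sd` on the log scale),
#' emulating a tightly co-regulated, strongly over-expressed program — the
#' construction that makes their PageRank scores co-ranked. `effect = 0`
#' disables the planting (module genes become background).
#'
#' @param net A [gene_network()] naming the genes.
#' @param module Character vector of module genes (subset of the network).
#' @param q Number of samples (>= 2).
#' @param effect Module expression level relative to the unit background
#'   median (default 10); must be >= 0.
#' @param module_sd Within-module log-normal sd (default 0.05).
#' @param seed Integer seed.
#' @return Gene x sample matrix (strictly positive), rownames = genes,
#'   colnames `S01`, `S02`, ...
#' @export
simulate_expression <- function(net, module = character(), q, effect = 10,
                                module_sd = 0.05, seed = 1) {
  stopifnot(inherits(net, "gene_network"), q >= 2)
  if (effect < 0) abort("`effect` must be nonnegative")
  if (!all(module %in% net$genes)) abort("module genes must be in the network")
  n <- length(net$genes)
  withr::with_seed(seed, {
    x <- matrix(exp(rnorm(n * q)), n, q,
                dimnames = list(net$genes, sprintf("S%02d", seq_len(q))))
    if (length(module) && effect > 0) {
      x[module, ] <- effect *
        exp(matrix(rnorm(length(module) * q, 0, module_sd), length(module), q))
    }
    x
  })
}

#' Synthetic bimodal methylation beta values
#'
#' Free entries draw from the mixture
#' `w_low * Beta(3, 19) + w_high * Beta(19, 3) + w_mid * Uniform(0, 1)`,
#' whose component modes sit exactly at 0.1 and 0.9 — the bimodal shape
#' typical of array beta values. Entries for genes `forced` in a sample draw
#' from Beta(19, 3) truncated to \[0.6, 1\], so they always classify as
#' fully methylated at the default threshold; `unmethylated` genes draw from
#' Beta(3, 19) truncated below 0.6, so they never do.
#'
#' @param genes Character vector of gene symbols.
#' @param q Number of samples.
#' @param weights Mixture weights `(w_low, w_high, w_mid)`, nonnegative,
#'   summing to 1 (default `c(0.45, 0.45, 0.10)`).
#' @param forced Either a character vector (applied to every sample) or a
#'   list of length `q` of per-sample character vectors of genes forced to
#'   fully-methylated values.
#' @param unmethylated Genes held below the fully-methylated threshold in
#'   every sample.
#' @param seed Integer seed.
#' @return Gene x sample matrix of beta values in \[0, 1\].
#' @export
simulate_beta <- function(genes, q, weights = c(0.45, 0.45, 0.10),
                          forced = character(), unmethylated = character(),
                          seed = 1) {
  stopifnot(length(weights) == 3, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-12, q >= 1)
  if (!is.list(forced)) forced <- rep(list(forced), q)
  stopifnot(length(forced) == q)
  allf <- unique(c(unlist(forced), unmethylated))
  if (!all(allf %in% genes)) abort("forced/unmethylated genes must be in `genes`")
  n <- length(genes)
  withr::with_seed(seed, {
    comp <- matrix(sample.int(3, n * q, replace = TRUE, prob = weights), n, q)
    b <- matrix(0, n, q, dimnames = list(genes, sprintf("S%02d", seq_len(q))))
    b[comp == 1] <- rbeta(sum(comp == 1), 3, 19)
    b[comp == 2] <- rbeta(sum(comp == 2), 19, 3)
    b[comp == 3] <- runif(sum(comp == 3))
    if (length(unmethylated)) {
      b[unmethylated, ] <- rbeta_trunc(length(unmethylated) * q, 3, 19, 0, 0.6 - 1e-9)
    }
    for (s in seq_len(q)) {
      if (length(forced[[s]])) {
        b[forced[[s]], s] <- rbeta_trunc(length(forced[[s]]), 19, 3, 0.6, 1)
      }
    }
    b
  })
}

# inverse-CDF sampling from a truncated Beta
rbeta_trunc <- function(n, a, b, lo, hi) {
  plo <- stats::pbeta(lo, a, b)
  phi <- stats::pbeta(hi, a, b)
  stats::qbeta(plo + runif(n) * (phi - plo), a, b)
}

#' Simulate a full study with planted ground truth
#'
#' Builds the complete input set for the pipeline under the package's study
#' conditions, with a recoverable ground truth:
#'
#' * a scale-free background topology of `n - module_size` genes
#'   ([simulate_network()]);
#' * a planted module of `module_size` genes wired as a clique and attached
#'   to the highest-degree background gene (their shared hub regulator) —
#'   a co-regulated functional module whose members occupy interchangeable
#'   network positions, so the hub is the module's designated connector and
#'   the expected bridge gene;
#' * expression with the module strongly co-expressed
#'   ([simulate_expression()]);
#' * bimodal beta values with the module held unmethylated — the planted
#'   module *is* the methylation-stable core the method is designed to
#'   recover — and optional per-sample forced methylation
#'   ([simulate_beta()]);
#' * a candidate panel of the module plus `n_candidates - module_size`
#'   background genes drawn at random (the hub excluded).
#'
#' @param n Total genes (default 300).
#' @param q Samples (default 20).
#' @param module_size Planted module size (default 6).
#' @param n_candidates Candidate-panel size (default 30).
#' @param m_attach Attachment parameter of the background topology.
#' @param effect,module_sd Module expression parameters
#'   (see [simulate_expression()]).
#' @param beta_weights Mixture weights for [simulate_beta()].
#' @param forced Per-sample forced-methylation sets forwarded to
#'   [simulate_beta()].
#' @param seed Integer seed driving every draw.
#' @return A list of class `synthetic_study`: `network` (directed, raw
#'   orientation, no self-loops), `expression`, `beta`, `candidates`, and
#'   `truth` (list: `module`, `connector`, `forced`, `seed`, `params`).
#' @export
simulate_study <- function(n = 300, q = 20, module_size = 6, n_candidates = 30,
                           m_attach = 3, effect = 10, module_sd = 0.05,
                           beta_weights = c(0.45, 0.45, 0.10),
                           forced = character(), seed = 1) {
  stopifnot(module_size >= 3, n_candidates >= module_size,
            n > n_candidates, q >= 2)
  nb <- n - module_size
  bg <- simulate_network(nb, m_attach, seed = seed)
  width <- max(3, nchar(n))
  genes <- sprintf(paste0("G%0", width, "d"), seq_len(n))
  # background symbols are re-padded to the full-study width
  bg_map <- setNames(genes[seq_len(nb)], bg$genes)
  module <- genes[(nb + 1):n]
  deg <- table(c(bg$edges$from, bg$edges$to))
  hub <- unname(bg_map[names(deg)[which.max(deg)]])
  clique <- t(combn(module, 2))
  edges <- dplyr::bind_rows(
    tibble(from = unname(bg_map[bg$edges$from]), to = unname(bg_map[bg$edges$to])),
    tibble(from = clique[, 1], to = clique[, 2]),
    tibble(from = module, to = hub)
  )
  net <- gene_network(edges, genes = genes)
  candidates <- withr::with_seed(seed + 1L, {
    pool <- setdiff(genes, c(module, hub))
    sort(c(module, sample(pool, n_candidates - module_size)))
  })
  expr <- simulate_expression(net, module, q, effect = effect,
                              module_sd = module_sd, seed = seed + 2L)
  beta <- simulate_beta(genes, q, weights = beta_weights, forced = forced,
                        unmethylated = module, seed = seed + 3L)
  structure(
    list(
      network = net, expression = expr, beta = beta, candidates = candidates,
      truth = list(
        module = module, connector = hub,
        forced = if (is.list(forced)) forced else rep(list(forced), q),
        seed = seed,
        params = list(n = n, q = q, module_size = module_size,
                      n_candidates = n_candidates, m_attach = m_attach,
                      effect = effect, module_sd = module_sd,
                      beta_weights = beta_weights)
      )
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(
    "<synthetic_study> %d genes x %d samples; module of %d (connector %s), %d candidates\n",
    p$n, p$q, p$module_size, x$truth$connector, p$n_candidates
  ))
  invisible(x)
}

#' Write a simulated study to a directory
#'
#' Emits the three TSV inputs (`network.tsv`, `expression.tsv`, `beta.tsv`),
#' the candidate list (`candidates.txt`) and the ground truth
#' (`truth.json`).
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network(study$network, file.path(dir, "network.tsv"), format = "tsv")
  write_gene_matrix(study$expression, file.path(dir, "expression.tsv"))
  write_gene_matrix(study$beta, file.path(dir, "beta.tsv"))
  writeLines(study$candidates, file.path(dir, "candidates.txt"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
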