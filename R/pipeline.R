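#' Pipeline configuration
#'
#' Bundles inputs, output directory and every policy knob of the pipeline.
#' Inputs may be given as file paths (read with the package's readers) or as
#' in-memory objects ([gene_network()], matrices, character vectors). The
#' defaults are the method's standard operating point: beta thresholds
#' 0.2/0.6, damping 0.85, k = 10 clusters, top 100 triplets.
#'
#' @param network Edge-list TSV path or a [gene_network()].
#' @param expression Expression TSV path or a gene x sample matrix.
#' @param beta Beta TSV path or matrix (only needed by the methylation and
#'   core stages).
#' @param candidates Path to a one-symbol-per-line file or a character
#'   vector (core stage).
#' @param outdir Output directory; `NULL` keeps everything in memory.
#' @param symmetrize Mirror the topology before fitting (default `TRUE`;
#'   interaction records are rarely meaningfully oriented, and a symmetric
#'   support guarantees a well-behaved interior maximum-entropy fit).
#' @param policy,epsilon Zero-expression handling
#'   (see [stationary_from_expression()]).
#' @param lower,upper Beta classification thresholds.
#' @param mfe_direction `"out"` or `"in"` (see [markov_flow_entropy()]).
#' @param pagerank_mode,damping PageRank settings
#'   (see [weighted_pagerank()]).
#' @param k,top_n Cluster count and triplet cut for the core stage.
#' @param tol,max_iter Scaling-fit tolerances.
#' @param seed Master seed for the k-means restarts.
#' @param allow_unconverged Keep going when a sample's fit misses `tol`.
#' @return A list of class `mce_config`.
#' @export
mce_config <- function(network, expression, beta = NULL, candidates = NULL,
                       outdir = NULL, symmetrize = TRUE,
                       policy = "drop_zero", epsilon = 1e-6,
                       lower = 0.2, upper = 0.6, mfe_direction = "out",
                       pagerank_mode = "row_stochastic", damping = 0.85,
                       k = 10, top_n = 100, tol = 1e-8, max_iter = 10000,
                       seed = 1, allow_unconverged = FALSE) {
  structure(
    list(network = network, expression = expression, beta = beta,
         candidates = candidates, outdir = outdir, symmetrize = symmetrize,
         policy = policy, epsilon = epsilon, lower = lower, upper = upper,
         mfe_direction = mfe_direction, pagerank_mode = pagerank_mode,
         damping = damping, k = k, top_n = top_n, tol = tol,
         max_iter = max_iter, seed = seed,
         allow_unconverged = allow_unconverged),
    class = "mce_config"
  )
}

resolve_inputs <- function(config, need_beta = FALSE, need_candidates = FALSE) {
  net <- config$network
  if (is.character(net)) net <- read_network(net, format = "edge_tsv")
  stopifnot(inherits(net, "gene_network"))
  if (config$symmetrize) net <- symmetrize_network(net)
  net <- add_self_loops(net)

  expr <- config$expression
  if (is.character(expr)) expr <- read_expression_matrix(expr)
  expr <- align_to_network(expr, net)

  beta <- NULL
  if (need_beta) {
    beta <- config$beta
    if (is.null(beta)) abort("this stage needs a beta matrix")
    if (is.character(beta)) beta <- read_beta_matrix(beta)
    beta <- align_to_network(beta, net, fill = NA_real_)
    mismatch <- setdiff(colnames(expr), colnames(beta))
    if (length(mismatch)) {
      abort(sprintf("samples missing from beta matrix: %s",
                    paste(mismatch, collapse = ", ")))
    }
    beta <- beta[, colnames(expr), drop = FALSE]
  }

  cand <- NULL
  if (need_candidates) {
    cand <- config$candidates
    if (is.null(cand)) abort("this stage needs a candidate gene list")
    if (is.character(cand) && length(cand) == 1 && file.exists(cand)) {
      cand <- trimws(readLines(cand, warn = FALSE))
      cand <- cand[nzchar(cand)]
    }
    if (!length(cand)) abort("empty candidate list")
  }
  list(net = net, expr = expr, beta = beta, candidates = cand)
}

fit_sample <- function(net, x, config) {
  st <- stationary_from_expression(x, policy = config$policy,
                                   epsilon = config$epsilon)
  fit_transition_matrix(net, st, tol = config$tol, max_iter = config$max_iter)
}

fit_g1_sample <- function(net, b, x, config) {
  g1 <- build_g1(net, b, x, lower = config$lower, upper = config$upper,
                 policy = config$policy, epsilon = config$epsilon)
  fit <- fit_transition_matrix(g1$network, g1$pi, tol = config$tol,
                               max_iter = config$max_iter)
  list(fit = fit, pruned = g1$pruned, missing_beta = g1$missing_beta)
}

#' Reconstruct the weighted network of every sample
#'
#' Fits the maximum-entropy chain of each expression column on the shared
#' topology. With an `outdir`, each sample's weighted edge list, a JSON
#' sidecar of its certificates and a deterministic `manifest_reconstruct.json`
#' are written; reruns with the same config are byte-identical.
#'
#' @param config An [mce_config()].
#' @return A list of class `reconstruct_result`: `fits` (named list of
#'   `mce_fit`, failed samples omitted), `summary` (tibble: sample, status,
#'   n_genes, mce, residuals, iterations, converged).
#' @export
run_reconstruct <- function(config) {
  stopifnot(inherits(config, "mce_config"))
  inp <- resolve_inputs(config)
  samples <- colnames(inp$expr)
  fits <- list()
  rows <- list()
  for (s in samples) {
    res <- tryCatch({
      fit <- if (config$allow_unconverged) {
        suppressWarnings(fit_sample(inp$net, inp$expr[, s], config))
      } else {
        fit_sample(inp$net, inp$expr[, s], config)
      }
      fits[[s]] <- fit
      dplyr::bind_cols(tibble(sample = s, status = "ok"), glance(fit))
    }, error = function(e) {
      tibble(sample = s, status = paste("failed:", conditionMessage(e)))
    })
    rows[[s]] <- res
  }
  summary <- dplyr::bind_rows(rows)
  out <- structure(list(fits = fits, summary = summary),
                   class = "reconstruct_result")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(fits)) {
      write_fit(fits[[s]], file.path(config$outdir, paste0("network_", s, ".tsv")))
    }
    write_manifest(config, summary,
                   file.path(config$outdir, "manifest_reconstruct.json"))
  }
  out
}

#' Methylation stage: G1 fits, rho table and absence census
#'
#' For every sample, fits both the original network G0 and the
#' methylation-pruned network G1, contrasts the per-gene flow entropies into
#' the methylation index rho, and tallies the absence census. With an
#' `outdir`, writes `rho.tsv` (long: gene, sample, rho), `census.tsv` and a
#' manifest.
#'
#' @param config An [mce_config()] with a beta matrix.
#' @return A list of class `methylation_result`: `rho` (long tibble `gene`,
#'   `sample`, `mfe0`, `mfe1`, `rho`), `census`, `pruned` (named list per
#'   sample), `summary`.
#' @export
run_methylation <- function(config) {
  stopifnot(inherits(config, "mce_config"))
  inp <- resolve_inputs(config, need_beta = TRUE)
  samples <- colnames(inp$expr)
  rho_rows <- list()
  pruned <- list()
  rows <- list()
  for (s in samples) {
    res <- tryCatch({
      f0 <- fit_sample(inp$net, inp$expr[, s], config)
      g1 <- fit_g1_sample(inp$net, inp$beta[, s], inp$expr[, s], config)
      mfe0 <- markov_flow_entropy(f0, direction = config$mfe_direction)
      mfe1 <- markov_flow_entropy(g1$fit, direction = config$mfe_direction)
      tab <- network_methylation_index(mfe0, mfe1)
      rho_rows[[s]] <- dplyr::mutate(tab, sample = s, .after = "gene")
      pruned[[s]] <- g1$pruned
      tibble(sample = s, status = "ok", n_pruned = length(g1$pruned),
             g0_converged = f0$converged, g1_converged = g1$fit$converged)
    }, error = function(e) {
      tibble(sample = s, status = paste("failed:", conditionMessage(e)))
    })
    rows[[s]] <- res
  }
  rho <- dplyr::bind_rows(rho_rows)
  census <- absence_census(rho)
  summary <- dplyr::bind_rows(rows)
  out <- structure(
    list(rho = rho, census = census, pruned = pruned, summary = summary),
    class = "methylation_result"
  )
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(rho, file.path(config$outdir, "rho.tsv"), na = "NA",
                     progress = FALSE)
    readr::write_tsv(census, file.path(config$outdir, "census.tsv"),
                     progress = FALSE)
    write_manifest(config, summary,
                   file.path(config$outdir, "manifest_methylation.json"))
  }
  out
}

#' Core stage: ranking, clustering, triplets, core and bridge genes
#'
#' Runs weighted PageRank and k-means score clustering on the G0 and G1 fits
#' of every sample, counts candidate-triplet co-occurrence within clusters,
#' intersects the flattened top-triplet gene lists of G0 and G1 into the
#' core set, and extracts the core subnetwork with its bridge genes. The
#' k-means seed of each sample is derived deterministically from
#' `config$seed` and the sample index.
#'
#' @param config An [mce_config()] with beta matrix and candidate list.
#' @return A list of class `core_result`: `core` (a `core_gene_result`),
#'   `scores` (long tibble: sample, network, gene, score), `assignments`
#'   (long tibble: sample, network, gene, cluster), `triplets_g0`,
#'   `triplets_g1`, `summary`.
#' @export
run_core <- function(config) {
  stopifnot(inherits(config, "mce_config"))
  inp <- resolve_inputs(config, need_beta = TRUE, need_candidates = TRUE)
  samples <- colnames(inp$expr)
  if (length(samples) < 2) abort("co-occurrence needs at least 2 samples")
  score_rows <- list()
  assign_rows <- list()
  for (si in seq_along(samples)) {
    s <- samples[si]
    f0 <- fit_sample(inp$net, inp$expr[, s], config)
    g1 <- fit_g1_sample(inp$net, inp$beta[, s], inp$expr[, s], config)
    for (lab in c("G0", "G1")) {
      fit <- if (lab == "G0") f0 else g1$fit
      sc <- weighted_pagerank(fit, d = config$damping,
                              mode = config$pagerank_mode)
      cl <- kmeans_scores(sc, k = config$k,
                          seed = config$seed * 1000L + si)
      score_rows[[paste(s, lab)]] <-
        dplyr::mutate(as_tibble(sc), sample = s, network = lab,
                      .before = "gene")
      assign_rows[[paste(s, lab)]] <-
        dplyr::mutate(cl, sample = s, network = lab, .before = "gene")
    }
  }
  scores <- dplyr::bind_rows(score_rows)
  assignments <- dplyr::bind_rows(assign_rows)
  t0 <- triplet_cooccurrence(
    assignments[assignments$network == "G0", ], inp$candidates)
  t1 <- triplet_cooccurrence(
    assignments[assignments$network == "G1", ], inp$candidates)
  core_genes <- core_set(t0, t1, top_n = config$top_n)
  core <- core_subnetwork_and_bridges(inp$net, core_genes)
  summary <- tibble(
    n_samples = length(samples),
    n_candidates = length(inp$candidates),
    n_triples_g0 = nrow(t0), n_triples_g1 = nrow(t1),
    n_core = length(core$core_genes), n_bridge = length(core$bridge_genes)
  )
  out <- structure(
    list(core = core, scores = scores, assignments = assignments,
         triplets_g0 = t0, triplets_g1 = t1, summary = summary),
    class = "core_result"
  )
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(scores, file.path(config$outdir, "pagerank.tsv"),
                     progress = FALSE)
    readr::write_tsv(assignments, file.path(config$outdir, "clusters.tsv"),
                     progress = FALSE)
    readr::write_tsv(t0, file.path(config$outdir, "triplets_g0.tsv"),
                     progress = FALSE)
    readr::write_tsv(t1, file.path(config$outdir, "triplets_g1.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(core_genes = core$core_genes, bridge_genes = core$bridge_genes),
      file.path(config$outdir, "core.json"),
      auto_unbox = FALSE, digits = NA, pretty = TRUE
    )
    write_network(core$subnetwork,
                  file.path(config$outdir, "core_subnetwork.graphml"),
                  format = "graphml")
    write_manifest(config, summary,
                   file.path(config$outdir, "manifest_core.json"))
  }
  out
}

# resolved config + per-sample status, written deterministically
write_manifest <- function(config, summary, path) {
  resolved <- config[setdiff(names(config), c("network", "expression", "beta",
                                              "candidates", "outdir"))]
  inputs <- lapply(config[c("network", "expression", "beta", "candidates")],
                   function(x) if (is.character(x)) x else class(x)[1])
  jsonlite::write_json(
    list(config = resolved, inputs = inputs, samples = summary),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}
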