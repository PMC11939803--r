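test_that("beta classification thresholds are inclusive and total on [0,1]", {
  cls <- function(b) as.character(classify_beta(b))
  expect_identical(cls(0.61), "fully_methylated")
  expect_identical(cls(0.60), "fully_methylated")
  expect_identical(cls(0.20), "unmethylated")
  expect_identical(cls(0.35), "partially_methylated")
  expect_identical(cls(NA_real_), NA_character_)
  expect_error(classify_beta(1.2), "\\[0, 1\\]")
  expect_error(classify_beta(0.5, lower = 0.7, upper = 0.6))

  # the three intervals partition [0,1] exactly
  grid <- seq(0, 1, by = 0.001)
  calls <- classify_beta(grid)
  expect_false(anyNA(calls))
  expect_identical(sort(unique(as.character(calls))),
                   sort(c("unmethylated", "partially_methylated",
                          "fully_methylated")))
})

test_that("G1 removes fully methylated genes and renormalises pi", {
  net <- toy_network(list(c("A", "B"), c("B", "C")))
  x <- c(A = 2, B = 3, C = 5)
  g1 <- build_g1(net, c(A = 0.1, B = 0.9, C = 0.3), x)
  expect_identical(g1$pruned, "B")
  expect_setequal(g1$network$genes, c("A", "C"))
  # only self-loops remain after B's removal
  expect_identical(sort(paste(g1$network$edges$from, g1$network$edges$to)),
                   c("A A", "C C"))
  expect_equal(unname(g1$pi$pi), c(0.2, 0.5) / 0.7, tolerance = 1e-12)

  # nothing fully methylated: G1 = G0
  g1n <- build_g1(net, c(A = 0.1, B = 0.59, C = 0.3), x)
  expect_identical(g1n$pruned, character(0))
  expect_setequal(g1n$network$genes, net$genes)

  # missing beta retains the gene
  g1m <- build_g1(net, c(A = NA, B = 0.9, C = 0.3), x)
  expect_identical(g1m$missing_beta, "A")
  expect_true("A" %in% g1m$network$genes)

  expect_error(build_g1(net, c(A = 0.9, B = 0.9, C = 0.99), x), "empty G1")
})

test_that("pruning is monotone in the fully-methylated threshold", {
  net <- study_topology(40, seed = 5)
  beta <- withr::with_seed(5, stats::setNames(stats::runif(40), net$genes))
  x <- stats::setNames(rep(1, 40), net$genes)
  pruned_at <- function(u) length(build_g1(net, beta, x, upper = u)$pruned)
  uppers <- c(0.4, 0.5, 0.6, 0.7, 0.9)
  counts <- vapply(uppers, pruned_at, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("flow entropies partition the chain entropy", {
  genes <- c("a", "b")
  fit <- fit_transition_matrix(loops_network(genes),
                               stats::setNames(c(0.5, 0.5), genes))
  mfe <- markov_flow_entropy(fit)
  expect_equal(mfe$mfe, rep(-0.5 * log(0.5), 2), tolerance = 1e-12)

  g4 <- letters[1:4]
  fit4 <- fit_transition_matrix(complete_network(g4),
                                stats::setNames(rep(0.25, 4), g4))
  mfe4 <- markov_flow_entropy(fit4)
  expect_equal(mfe4$mfe, rep(0.25 * log(16), 4), tolerance = 1e-10)

  withr::local_seed(17)
  for (trial in 1:4) {
    net <- random_strong_network(sample(4:6, 1))
    fit_r <- fit_transition_matrix(net, random_pi(net$genes))
    for (dir in c("out", "in")) {
      mfe_r <- markov_flow_entropy(fit_r, direction = dir)
      expect_equal(sum(mfe_r$mfe), fit_r$mce, tolerance = 1e-10)
      expect_true(all(mfe_r$mfe >= 0))
    }
  }
})

test_that("the methylation index contrasts G1 against G0 with NA for pruned genes", {
  mk <- function(genes, vals) {
    out <- tibble::tibble(gene = genes, mfe = vals)
    class(out) <- c("mfe_vector", class(out))
    attr(out, "direction") <- "out"
    out
  }
  # identical networks: rho identically zero
  same <- network_methylation_index(mk(c("A", "B"), c(0.4, 0.2)),
                                    mk(c("A", "B"), c(0.4, 0.2)))
  expect_equal(same$rho, c(0, 0))

  tab <- network_methylation_index(mk(c("A", "B"), c(0.40, 0.30)),
                                   mk("A", 0.30))
  expect_equal(tab$rho[tab$gene == "A"], -0.25)
  expect_true(is.na(tab$rho[tab$gene == "B"]))  # pruned from G1

  # zero G0 flow entropy cannot be a denominator
  z <- network_methylation_index(mk(c("A", "B"), c(0, 0.3)),
                                 mk(c("A", "B"), c(0.1, 0.3)))
  expect_true(is.na(z$rho[z$gene == "A"]))

  out <- mk("A", 0.1); attr(out, "direction") <- "in"
  expect_error(network_methylation_index(mk("A", 0.1), out),
               "different flow directions")
})

test_that("rho is invariant to positive rescaling of expression", {
  net <- study_topology(30, seed = 9)
  x <- withr::with_seed(9, stats::setNames(exp(stats::rnorm(30)), net$genes))
  beta <- withr::with_seed(10, stats::setNames(stats::runif(30), net$genes))
  rho_for <- function(xv) {
    f0 <- fit_transition_matrix(net, stationary_from_expression(xv))
    g1 <- build_g1(net, beta, xv)
    f1 <- fit_transition_matrix(g1$network, g1$pi)
    network_methylation_index(markov_flow_entropy(f0),
                              markov_flow_entropy(f1))$rho
  }
  expect_equal(rho_for(x), rho_for(x * 42), tolerance = 1e-9)
})

test_that("the absence census reproduces a planted missingness pattern", {
  genes <- c("g1", "g2", "g3", "g4")
  samples <- sprintf("s%d", 1:5)
  # planted pattern: g1 missing in 3 samples, g2 in 1, g3 in 3, g4 never
  missing <- list(g1 = c(1, 2, 5), g2 = 3, g3 = c(2, 3, 4), g4 = integer(0))
  tab <- tidyr::expand_grid(gene = genes, sample = samples)
  tab$rho <- ifelse(
    mapply(function(g, s) match(s, samples) %in% missing[[g]],
           tab$gene, tab$sample),
    NA_real_, 0.1
  )
  cen <- absence_census(tab)
  expect_identical(cen$gene, c("g1", "g3", "g2", "g4"))  # ties by symbol
  expect_identical(cen$n_missing, c(3L, 3L, 1L, 0L))

  expect_warning(cen2 <- absence_census(tab, genes = c("g1", "gX")),
                 "absent")
  expect_identical(cen2$n_missing[cen2$gene == "gX"], 0L)
  expect_error(absence_census(tab[0, ]), "no samples")
})
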