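test_that("stationary distribution is the L1-normalised expression", {
  s <- stationary_from_expression(c(a = 2, b = 3, c = 5))
  expect_equal(unname(s$pi), c(0.2, 0.3, 0.5))
  expect_identical(s$retained, c("a", "b", "c"))

  s0 <- stationary_from_expression(c(a = 0, b = 1, c = 3))
  expect_identical(s0$retained, c("b", "c"))
  expect_equal(unname(s0$pi), c(0.25, 0.75))

  sp <- stationary_from_expression(c(a = 0, b = 1), policy = "pseudocount",
                                   epsilon = 1)
  expect_equal(unname(sp$pi), c(1 / 3, 2 / 3))

  expect_error(stationary_from_expression(c(a = 0, b = 0)), "degenerate")
  expect_error(stationary_from_expression(c(a = -1, b = 2)), "nonnegative")
})

test_that("self-loops-only support forces the identity chain", {
  genes <- c("a", "b", "c")
  fit <- fit_transition_matrix(loops_network(genes),
                               stats::setNames(c(0.2, 0.3, 0.5), genes))
  expect_equal(as.matrix(fit$P), diag(3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_lt(max(fit$residuals), 1e-12)
  expect_true(fit$converged)
})

test_that("complete support yields the i.i.d. chain with rows equal to pi", {
  genes <- c("a", "b", "c")
  pi <- stats::setNames(c(0.2, 0.3, 0.5), genes)
  fit <- fit_transition_matrix(complete_network(genes), pi)
  P <- as.matrix(fit$P)
  for (i in 1:3) expect_equal(unname(P[i, ]), unname(pi), tolerance = 1e-8)
})

test_that("a support admitting no off-diagonal stationary flow is reported honestly", {
  # A->B has no return path: column balance forces p_AA = 1, a boundary
  # optimum the scaling approaches sublinearly
  net <- toy_network(list(c("A", "B")), genes = c("A", "B"))
  pi <- c(A = 0.4, B = 0.6)
  expect_warning(fit <- fit_transition_matrix(net, pi), "did not reach")
  expect_false(fit$converged)
  expect_lt(fit$P["A", "B"], 1e-4)
})

test_that("MCE closed forms: identity gives H(pi), complete support 2 H(pi)", {
  genes <- letters[1:3]
  pi <- stats::setNames(c(0.2, 0.3, 0.5), genes)
  h <- -sum(pi * log(pi))
  fit_id <- fit_transition_matrix(loops_network(genes), pi)
  expect_equal(fit_id$mce, h, tolerance = 1e-8)
  expect_equal(h, 1.029653, tolerance = 1e-6)

  g4 <- letters[1:4]
  fit_u <- fit_transition_matrix(complete_network(g4),
                                 stats::setNames(rep(0.25, 4), g4))
  expect_equal(fit_u$mce, 2 * log(4), tolerance = 1e-8)

  fit_c <- fit_transition_matrix(complete_network(genes), pi)
  expect_equal(fit_c$mce, 2 * h, tolerance = 1e-8)
})

test_that("fit agrees with the brute-force oracle on random small graphs", {
  withr::local_seed(421)
  for (trial in 1:12) {
    net <- random_strong_network(sample(3:5, 1))
    pi <- random_pi(net$genes)
    fit <- fit_transition_matrix(net, pi)
    orc <- oracle_max_entropy(net, pi)
    expect_lt(abs(fit$mce - orc$mce), 1e-5)
    expect_lt(max(abs(as.matrix(fit$P) - orc$P)), 1e-4)
    # no feasible perturbation improves the entropy: spot-check the optimum
    expect_gte(fit$mce + 1e-6, orc$mce)
  }
})

test_that("oracle handles degenerate supports and refuses large ones", {
  genes <- letters[1:3]
  pi <- stats::setNames(c(0.2, 0.3, 0.5), genes)
  orc <- oracle_max_entropy(loops_network(genes), pi)
  expect_equal(orc$P, diag(3), ignore_attr = TRUE)

  orc2 <- oracle_max_entropy(complete_network(c("a", "b")),
                             c(a = 0.3, b = 0.7))
  expect_equal(unname(orc2$P[1, ]), c(0.3, 0.7), tolerance = 1e-6)

  expect_error(oracle_max_entropy(loops_network(letters[1:9]),
                                  random_pi(letters[1:9])), "n > 8")
})

test_that("fitted chains carry valid certificates and support containment", {
  withr::local_seed(7)
  for (trial in 1:5) {
    net <- random_strong_network(5)
    pi <- random_pi(net$genes)
    fit <- fit_transition_matrix(net, pi)
    expect_true(fit$converged)
    expect_lt(max(fit$residuals), fit$tol)
    # p_ij > 0 only where a_ij = 1
    a <- as.matrix(adjacency_matrix(net))
    expect_true(all(as.matrix(fit$P)[a == 0] == 0))
    expect_gte(fit$mce, 0)
    expect_lte(fit$mce, 2 * log(length(pi)) - sum(pi * log(pi)) + 1e-9)
  }
})

test_that("the fit is scale-invariant and deterministic", {
  net <- study_topology(50, seed = 3)
  x <- withr::with_seed(3, stats::setNames(exp(stats::rnorm(50)), net$genes))
  f1 <- fit_transition_matrix(net, stationary_from_expression(x))
  f2 <- fit_transition_matrix(net, stationary_from_expression(x * 137.5))
  expect_equal(f1$pi, f2$pi, tolerance = 1e-12)
  expect_equal(f1$P@x, f2$P@x, tolerance = 1e-10)
  f3 <- fit_transition_matrix(net, stationary_from_expression(x))
  expect_identical(f1$P@x, f3$P@x)
  expect_identical(f1$mce, f3$mce)
})

test_that("tidy/glance expose edges and certificates", {
  genes <- letters[1:3]
  pi <- stats::setNames(c(0.2, 0.3, 0.5), genes)
  fit <- fit_transition_matrix(complete_network(genes), pi)
  td <- tidy(fit)
  expect_identical(names(td), c("from", "to", "p", "flow"))
  expect_equal(nrow(td), 9)
  expect_equal(sum(td$flow), 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$mce, fit$mce)
})

test_that("unaugmented networks and bad stationary vectors are refused", {
  net <- gene_network(tibble::tibble(from = "A", to = "B"))
  expect_error(fit_transition_matrix(net, c(A = 0.5, B = 0.5)), "self-loop")
  aug <- add_self_loops(net)
  expect_error(fit_transition_matrix(aug, c(A = 0.2, B = 0.3)), "sum to 1")
  expect_error(fit_transition_matrix(aug, c(A = -0.2, B = 1.2)), "positive")
})
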