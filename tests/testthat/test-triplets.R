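assign_tbl <- function(...) {
  # assign_tbl(s1 = list(c("g1","g2","g3"), "g4"), s2 = ...)
  samples <- list(...)
  rows <- list()
  for (s in names(samples)) {
    for (ci in seq_along(samples[[s]])) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = s, gene = samples[[s]][[ci]], cluster = ci)
    }
  }
  dplyr::bind_rows(rows)
}

test_that("triplet counts enumerate co-clustered 3-subsets exactly", {
  tab <- triplet_cooccurrence(
    assign_tbl(s1 = list(c("g1", "g2", "g3"), "g4"),
               s2 = list(c("g1", "g2", "g3", "g4"))),
    candidates = c("g1", "g2", "g3", "g4")
  )
  expect_equal(nrow(tab), 4)
  key <- paste(tab$gene1, tab$gene2, tab$gene3)
  expect_identical(tab$count[key == "g1 g2 g3"], 2L)
  expect_identical(sort(tab$count), c(1L, 1L, 1L, 2L))

  # one sample, 4 candidates in one cluster: C(4,3) triples, each once
  tab1 <- triplet_cooccurrence(
    assign_tbl(s1 = list(c("a", "b", "c", "d"))),
    candidates = c("a", "b", "c", "d"))
  expect_equal(nrow(tab1), 4)
  expect_true(all(tab1$count == 1L))

  # never co-clustered: empty table
  tab0 <- triplet_cooccurrence(
    assign_tbl(s1 = list("a", "b", "c")), candidates = c("a", "b", "c"))
  expect_equal(nrow(tab0), 0)

  expect_error(
    triplet_cooccurrence(assign_tbl(s1 = list("a")),
                         candidates = sprintf("g%03d", 1:201)),
    "200")
})

test_that("triplet counts are invariant to sample and gene order", {
  a1 <- assign_tbl(s1 = list(c("g1", "g2", "g3"), "g4"),
                   s2 = list(c("g1", "g2", "g3", "g4")))
  a2 <- a1[rev(seq_len(nrow(a1))), ]
  t1 <- triplet_cooccurrence(a1, c("g1", "g2", "g3", "g4"))
  t2 <- triplet_cooccurrence(a2, c("g4", "g3", "g2", "g1"))
  expect_identical(t1, t2)
})

test_that("core set is the intersection of flattened top-triple gene lists", {
  t0 <- tibble::tibble(gene1 = c("a", "a"), gene2 = c("b", "c"),
                       gene3 = c("c", "d"), count = c(5L, 4L))
  t1 <- tibble::tibble(gene1 = "b", gene2 = "c", gene3 = "e", count = 3L)
  core <- core_set(t0, t1, top_n = 100)
  expect_identical(as.character(core), c("b", "c"))
  expect_identical(attr(core, "genes_g0"), c("a", "b", "c", "d"))

  far <- tibble::tibble(gene1 = "x", gene2 = "y", gene3 = "z", count = 1L)
  expect_warning(empty <- core_set(t0, far, top_n = 100), "disjoint")
  expect_length(empty, 0)
})

test_that("the top_n boundary is cut lexicographically and is monotone", {
  # engineered tie at the cut: three triples share the top count
  tied <- tibble::tibble(
    gene1 = c("b", "a", "c", "a"), gene2 = c("d", "b", "d", "c"),
    gene3 = c("e", "c", "e", "d"), count = c(7L, 7L, 7L, 2L))
  other <- tibble::tibble(gene1 = "a", gene2 = "b", gene3 = "c", count = 1L)
  core1 <- suppressMessages(core_set(tied, other, top_n = 1))
  # rank-1 triple must be (a,b,c): smallest lexicographically among count-7 ties
  expect_identical(attr(core1, "genes_g0"), c("a", "b", "c"))
  core_again <- suppressMessages(core_set(tied, other, top_n = 1))
  expect_identical(attr(core_again, "genes_g0"), c("a", "b", "c"))

  # enlarging top_n never shrinks the flattened lists
  prev <- character(0)
  for (tn in 1:4) {
    g0 <- attr(suppressMessages(core_set(tied, other, top_n = tn)), "genes_g0")
    expect_true(all(prev %in% g0))
    prev <- g0
  }
})

test_that("bridge genes connect at least two distinct core genes", {
  net <- toy_network(list(c("c1", "x"), c("x", "c2"), c("c1", "y")))
  res <- core_subnetwork_and_bridges(net, c("c1", "c2"))
  expect_identical(res$bridge_genes, "x")
  expect_true("y" %in% res$subnetwork$genes)      # neighbor but not bridge
  expect_false("y" %in% res$bridge_genes)
  expect_length(intersect(res$core_genes, res$bridge_genes), 0)

  # adjacent cores with no shared neighbor: no bridges
  net2 <- toy_network(list(c("c1", "c2"), c("c2", "z")))
  res2 <- core_subnetwork_and_bridges(net2, c("c1", "c2"))
  expect_length(res2$bridge_genes, 0)

  expect_error(core_subnetwork_and_bridges(net, character(0)), "empty")
  expect_error(core_subnetwork_and_bridges(net, "nope"), "not in network")
})

test_that("a planted connector is recovered as the unique bridge", {
  study <- simulate_study(n = 120, q = 2, seed = 5)
  net <- add_self_loops(symmetrize_network(study$network))
  res <- core_subnetwork_and_bridges(net, study$truth$module)
  expect_identical(res$bridge_genes, study$truth$connector)
})

test_that("tidy() labels core, bridge and neighbor roles", {
  net <- toy_network(list(c("c1", "x"), c("x", "c2"), c("c1", "y")))
  td <- tidy(core_subnetwork_and_bridges(net, c("c1", "c2")))
  expect_identical(td$role[td$gene == "x"], "bridge")
  expect_identical(td$role[td$gene == "y"], "neighbor")
  expect_setequal(td$gene[td$role == "core"], c("c1", "c2"))
})
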