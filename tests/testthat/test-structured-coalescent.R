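test_that("single-population coalescent matches classical theory", {
  set.seed(71)
  sp <- single_population(2)
  g <- simulate_gene_tree(sp, 5)
  expect_s3_class(g, "phylo")
  expect_true(ape::is.binary(g))
  expect_equal(g$Nnode, 4)
  expect_equal(count_migrations(g), 0)
  # mean TMRCA of k samples is 2 nu (1 - 1/k)
  tm <- replicate(2500, root_height(simulate_gene_tree(sp, 5)))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2 * 2 * (1 - 1 / 5)), 3 * se)
  # pairwise TMRCA is Exponential(1/nu): the constant-rate reduction
  tm2 <- replicate(10000, root_height(simulate_gene_tree(single_population(1), 2)))
  expect_gt(ks_compare(tm2, function(q) stats::pexp(q, 1))$p.value, 0.01)
})

test_that("strict divergence contains coalescences within species branches", {
  set.seed(81)
  st <- two_pop_tree(m = 0, T = 1.5)
  for (i in 1:60) {
    g <- simulate_gene_tree(st, c(a = 3, b = 3))
    expect_equal(count_migrations(g), 0)
    expect_equal(count_inconsistent_coalescences(g, st), 0)
    # cross-species coalescences sit above the divergence
    h <- g$node.heights
    n <- length(g$tip.label)
    po <- ape::reorder.phylo(g, "postorder")
    sp <- g$tip.species[g$tip.label]
    sets <- c(as.list(sp), vector("list", g$Nnode))
    for (k in seq_len(nrow(po$edge))) {
      p <- po$edge[k, 1]; ch <- po$edge[k, 2]
      sets[[p]] <- union(sets[[p]], sets[[ch]])
    }
    for (v in (n + 1):(n + g$Nnode))
      if (length(sets[[v]]) > 1) expect_gte(h[v], 1.5)
  }
})

test_that("lineage bookkeeping is conserved through migrations and merges", {
  set.seed(91)
  for (i in 1:25) {
    st <- gradual_separation_scenario(4, M = runif(1, 0.5, 2),
                                      S = runif(1, 0.3, 0.8))
    g <- simulate_gene_tree(st, 4)
    n <- length(g$tip.label)
    expect_equal(n, 16)
    expect_equal(g$Nnode, n - 1)              # coalescences reduce by one each
    expect_true(ape::is.binary(g))
    expect_true(ape::is.rooted(g))
    # internal node times strictly positive and increasing along paths
    h <- g$node.heights
    expect_true(all(h[(n + 1):(2 * n - 1)] > 0))
    expect_true(all(h[g$edge[, 1]] > h[g$edge[, 2]]))
    # migration events lie inside decorated windows
    if (nrow(g$migrations)) {
      for (r in seq_len(nrow(g$migrations))) {
        v <- coalmig:::st_mrca(st, g$migrations$from[r], g$migrations$to[r])
        d <- st$mig[[v]]
        expect_false(is.null(d))
        expect_gte(g$migrations$time[r], d$ts)
        expect_lte(g$migrations$time[r], d$td)
      }
    }
  }
})

test_that("constant-rate configuration reduces to competing exponentials", {
  set.seed(101)
  # 1 + 1 lineages, migration only below the divergence: the first event
  # is the minimum of two exponential migration clocks
  st <- two_pop_tree(nu_a = 1, nu_b = 2, m = 0.1, T = 30)
  rate <- 0.1 * 2 / 1 + 0.1 * 1 / 2          # f_ab + f_ba
  first <- replicate(3000, {
    g <- simulate_gene_tree(st, c(a = 1, b = 1))
    # no migration before the (distant) divergence happens with
    # probability exp(-rate * 30), a negligible censoring
    if (nrow(g$migrations)) min(g$migrations$time) else NA_real_
  })
  first <- first[!is.na(first)]
  expect_gt(ks_compare(first, function(q) stats::pexp(q, rate))$p.value, 0.01)
})

test_that("inconsistent coalescences are detected against the weak tree", {
  st <- two_pop_tree(m = 0.1, T = 1)
  # hand-built gene tree: one cross-species coalescence below the divergence
  g <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2),
                      edge.length = c(0.5, 0.5),
                      tip.label = c("a_1", "b_1"), Nnode = 1L,
                      node.heights = c(0, 0, 0.5),
                      tip.species = c(a_1 = "a", b_1 = "b"),
                      migrations = data.frame()),
                 class = c("gene_tree", "phylo"))
  expect_equal(count_inconsistent_coalescences(g, st), 1)
  expect_equal(count_inconsistent_coalescences(g, st, per = "pair"), 1)
  # the same coalescence above the divergence is consistent
  g2 <- g; g2$node.heights[3] <- 1.4; g2$edge.length <- c(1.4, 1.4)
  expect_equal(count_inconsistent_coalescences(g2, st), 0)
  # bound: at most one inconsistency per coalescence
  set.seed(111)
  for (i in 1:20) {
    st <- gradual_separation_scenario(4, M = 2, S = 0.8)
    gg <- simulate_gene_tree(st, 3)
    expect_lte(count_inconsistent_coalescences(gg, st),
               length(gg$tip.label) - 1)
  }
})

test_that("unsampled species still act as migration destinations", {
  set.seed(121)
  st <- two_pop_tree(nu_a = 1, nu_b = 1, m = 1, T = 8)
  hops <- replicate(200, {
    g <- simulate_gene_tree(st, c(a = 2, b = 0))
    sum(g$migrations$to == match("b", st$phy$tip.label))
  })
  expect_gt(mean(hops > 0), 0.5)             # lineages do visit species b
})
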