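test_that("Yule trees have the theoretical mean root height", {
  set.seed(21)
  # n = 2: a single Exponential(2 lambda) wait
  h2 <- replicate(4000, max(simulate_yule(2, 0.8)$heights))
  se <- sd(h2) / sqrt(length(h2))
  expect_lt(abs(mean(h2) - 1 / 1.6), 3 * se)
  # ultrametric validity and structure
  st <- simulate_yule(6, 0.5)
  expect_s3_class(st, "species_tree")
  expect_true(ape::is.ultrametric(st$phy, tol = 1e-8))
  expect_equal(st$heights[seq_len(6)], rep(0, 6))
  expect_true(all(st$heights[st$phy$edge[, 1]] > st$heights[st$phy$edge[, 2]]))
})

test_that("population assignment builds positive linear branch histories", {
  set.seed(31)
  # degenerate draw: everything constant at the tip mean
  st <- assign_populations(simulate_yule(4, 1), tip_mean = 0.3,
                           sd_log = 0, expansion = 1)
  for (v in seq_len(st$n_nodes))
    expect_equal(plf_eval(st$nu[[v]], st$heights[v]), 0.3)
  # expansion factor: older end = expansion x younger end on finite branches
  st <- assign_populations(simulate_yule(5, 1), tip_mean = 1,
                           sd_log = 0.4, expansion = 0.7)
  for (v in seq_len(st$n_nodes)) {
    f <- st$nu[[v]]
    expect_true(all(f$y > 0))
    if (!is.na(st$parent[v]))
      expect_equal(f$y[2], 0.7 * f$y[1])
    else
      expect_length(f$y, 1)                 # constant ancestral population
  }
  # ancestral branch starts at the mean of its children's older ends
  v <- st$root
  ch <- st$children[[v]]
  expect_equal(plf_eval(st$nu[[v]], st$heights[v]),
               mean(vapply(ch, function(c)
                 plf_eval(st$nu[[c]], st$heights[v]), 0)))
  # log-space spread of tip values
  tips <- unlist(lapply(1:1000, function(i) {
    s <- assign_populations(simulate_yule(5, 1), tip_mean = 0.85, sd_log = 0.4)
    vapply(1:5, function(v) s$nu[[v]]$y[1], 0)
  }))
  expect_lt(abs(var(log(tips)) - 0.16), 0.015)
  expect_lt(abs(mean(tips) - 0.85), 0.02)   # real-space mean is tip_mean
})

test_that("gradual separation decorates divergences with declining migration", {
  set.seed(41)
  st <- assign_gradual_separation(simulate_yule(5, 0.8), M = 0.3, S = 0.4,
                                  lambda = 0.8)
  decorated <- which(!vapply(st$mig, is.null, logical(1)))
  expect_gt(length(decorated), 0)
  for (v in decorated) {
    d <- st$mig[[v]]
    expect_equal(d$td, st$heights[v])
    expect_gte(d$ts, 0)
    expect_lt(d$ts, d$td)
    expect_equal(plf_eval(d$m12, d$td), 0.3)            # M at divergence
    expect_equal(plf_eval(d$m12, d$ts), 0)              # zero at separation
    expect_equal(plf_eval(d$m12, (d$ts + d$td) / 2), 0.15)  # linear decline
    expect_equal(d$m12$y, d$m21$y)                      # reciprocal scenario
  }
  # no migration when M = 0 or S = 0
  st0 <- assign_gradual_separation(simulate_yule(5, 0.8), M = 0, S = 0.4,
                                   lambda = 0.8)
  expect_true(all(vapply(st0$mig, is.null, logical(1))))
})

test_that("separation intervals respect the nesting constraint", {
  set.seed(51)
  for (i in 1:300) {
    st <- assign_gradual_separation(simulate_yule(sample(3:7, 1), 0.8),
                                    M = runif(1, 0.05, 3),
                                    S = runif(1, 0.05, 1), lambda = 0.8)
    expect_true(coalmig:::check_nesting(st))
    # strong tree keeps nonnegative branch lengths; zero-length branches
    # can only arise from separation intervals truncated at the present
    # or clamped to the parent's separation time
    sg <- strong_tree(st)
    expect_true(all(sg$heights[sg$phy$edge[, 1]] >=
                      sg$heights[sg$phy$edge[, 2]] - 1e-12))
  }
})

test_that("weak and strong trees bracket the separation interval", {
  set.seed(61)
  st <- assign_gradual_separation(simulate_yule(5, 0.8), M = 1, S = 0.5,
                                  lambda = 0.8)
  w <- weak_tree(st); sg <- strong_tree(st)
  expect_equal(w$heights, st$heights)
  expect_true(all(sg$heights <= w$heights + 1e-12))
  # no separation: both trees coincide
  st0 <- assign_gradual_separation(simulate_yule(5, 0.8), M = 0, S = 0.5,
                                   lambda = 0.8)
  expect_equal(strong_tree(st0)$heights, weak_tree(st0)$heights)
})

test_that("backward migration rate resolves the split-sharing rule", {
  # two populations: f_{a->b} = m_{b->a} nu_b / nu_a
  st <- two_pop_tree(nu_a = 1, nu_b = 2, m = 0.1, T = 2)
  ia <- match("a", st$phy$tip.label); ib <- match("b", st$phy$tip.label)
  expect_equal(backward_migration_rate(st, ia, ib, 1), 0.2)
  expect_equal(backward_migration_rate(st, ib, ia, 1), 0.05)
  # a vs (b1, b2): equal sizes share forward emigrants 50/50
  st3 <- cherry_tree(nu_a = 1, nu_b1 = 0.5, nu_b2 = 0.5, m = 0.2)
  ids <- match(c("b1", "b2", "a"), st3$phy$tip.label)
  r1 <- backward_migration_rate(st3, ids[1], ids[3], 0.5)
  r2 <- backward_migration_rate(st3, ids[2], ids[3], 0.5)
  flow1 <- r1 * 0.5; flow2 <- r2 * 0.5      # arrivals into b1, b2
  expect_equal(flow1, flow2)
  # total forward flow a -> (b1 u b2) equals the unsplit flow for any sizes
  st4 <- cherry_tree(nu_a = 1.3, nu_b1 = 0.4, nu_b2 = 1.1, m = 0.2)
  ids <- match(c("b1", "b2", "a"), st4$phy$tip.label)
  f1 <- backward_migration_rate(st4, ids[1], ids[3], 0.5) * 0.4
  f2 <- backward_migration_rate(st4, ids[2], ids[3], 0.5) * 1.1
  expect_equal(f1 + f2, 0.2 * 1.3)          # m * nu_a
  # representing an undivided clade as an equal-split cherry is neutral:
  # the total backward rate a -> b-side is unchanged
  st2 <- two_pop_tree(nu_a = 1, nu_b = 1, m = 0.2, T = 2)
  ia <- match("a", st2$phy$tip.label); ib <- match("b", st2$phy$tip.label)
  whole <- backward_migration_rate(st2, ia, ib, 0.5)
  stc <- cherry_tree(nu_a = 1, nu_b1 = 0.5, nu_b2 = 0.5, m = 0.2)
  ids <- match(c("b1", "b2", "a"), stc$phy$tip.label)
  split <- backward_migration_rate(stc, ids[3], ids[1], 0.5) +
    backward_migration_rate(stc, ids[3], ids[2], 0.5)
  expect_equal(split, whole)
  # migration vanishes outside the decorated window
  st5 <- two_pop_tree(m = 0.1, T = 2)
  st5 <- set_migration(st5, 3, 0.1, window = c(1, 2))
  expect_equal(backward_migration_rate(st5, 1, 2, 0.5), 0)
  expect_gt(backward_migration_rate(st5, 1, 2, 1.5), 0)
  # non-coextant branches are an error
  expect_error(backward_migration_rate(cherry_tree(), 1, 4, 1.5), "extant")
})
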