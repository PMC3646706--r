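# Small decorated trees built in code for the tests.

# Two species diverging at time T, constant demographics, constant
# reciprocal migration fraction m on [0, T].
two_pop_tree <- function(nu_a = 1, nu_b = 2, nu_anc = 1, m = 0.1, T = 2) {
  phy <- ape::read.tree(text = sprintf("(a:%g,b:%g);", T, T))
  st <- species_tree(phy)
  st <- set_population(st, 1, nu_a)
  st <- set_population(st, 2, nu_b)
  st <- set_population(st, 3, nu_anc)
  if (m > 0) st <- set_migration(st, 3, m, m, window = c(0, T))
  st
}

# ((b1,b2),a) with the root divergence decorated: migration between a and
# the b-clade, so emigrants are shared between b1 and b2 below their own
# divergence.
cherry_tree <- function(nu_a = 1, nu_b1 = 0.5, nu_b2 = 0.5, nu_b = 1,
                        nu_anc = 1, m = 0.2, t_split = 1, T = 2) {
  txt <- sprintf("((b1:%g,b2:%g):%g,a:%g);", t_split, t_split, T - t_split, T)
  st <- species_tree(ape::read.tree(text = txt))
  ids <- match(c("b1", "b2", "a"), st$phy$tip.label)
  st <- set_population(st, ids[1], nu_b1)
  st <- set_population(st, ids[2], nu_b2)
  st <- set_population(st, ids[3], nu_a)
  binode <- coalmig:::st_mrca(st, ids[1], ids[2])
  st <- set_population(st, binode, nu_b)
  st <- set_population(st, st$root, nu_anc)
  set_migration(st, st$root, m, m, window = c(0, T))
}

# random hazard over random piecewise-linear components, for property
# tests; numerators are kept strictly positive so the cumulative hazard is
# strictly increasing inside the window (the round-trip identity is only
# well posed there — on zero-hazard stretches the inverse returns the
# infimum time, by design)
random_hazard <- function() {
  rplf <- function(lo) {
    k <- sample(1:4, 1)
    piecewise_linear(sort(stats::runif(k, 0, 3)), stats::runif(k, lo, 3))
  }
  hazard(num1 = rplf(0.05), num2 = rplf(0.05), den = rplf(0.2),
         window = c(stats::runif(1, 0, 0.5), sample(c(Inf, stats::runif(1, 2, 4)), 1)))
}

root_height <- function(g) max(g$node.heights)
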