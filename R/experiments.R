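#' Generate one gradual-separation test case
#'
#' Convenience wrapper producing a fully decorated species tree under the
#' stochastic gradual-separation scenario: Yule topology and heights,
#' log-normal population histories shrinking backward in time, and
#' reciprocal linearly-declining migration at every divergence.
#'
#' @param n_species number of species.
#' @param M,S gradual-separation parameters (migration fraction at
#'   divergence; mean separation duration as a fraction of mean species
#'   lifetime).
#' @param lambda Yule birth rate.
#' @param tip_mean,sd_log,expansion population-assignment parameters, see
#'   [assign_populations()].
#' @return A decorated [species_tree()].
#' @export
gradual_separation_scenario <- function(n_species = 5, M = 0.1, S = 0.1,
                                        lambda = 0.8, tip_mean = 0.85,
                                        sd_log = 0.4, expansion = 0.7) {
  st <- simulate_yule(n_species, lambda)
  st <- assign_populations(st, tip_mean = tip_mean, sd_log = sd_log,
                           expansion = expansion)
  assign_gradual_separation(st, M, S, lambda)
}

#' Migration and inconsistency statistics over an (M, S) grid
#'
#' For every grid point, `reps` independent test cases are generated with
#' [gradual_separation_scenario()] (a fresh species tree per replicate)
#' and one gene tree is simulated in each; the mean number of migration
#' events, the mean number of inconsistent coalescences and the fraction
#' of gene trees with at least one migration are recorded with
#' Monte-Carlo standard errors.
#'
#' @param M,S numeric vectors of grid coordinates (crossed).
#' @param reps replicates per grid point.
#' @param n_species,n_individuals,lambda,tip_mean scenario parameters.
#' @return A data frame of class `"grid_result"` with one row per grid
#'   point: `M`, `S`, `reps`, `mean_migrations`, `se_migrations`,
#'   `mean_inconsistent`, `se_inconsistent`, `frac_ge1`.
#' @export
run_grid <- function(M, S, reps = 100, n_species = 5, n_individuals = 10,
                     lambda = 0.8, tip_mean = 0.85) {
  stopifnot(reps >= 1)
  grid <- expand.grid(M = M, S = S)
  out <- lapply(seq_len(nrow(grid)), function(gi) {
    mm <- grid$M[gi]; ss <- grid$S[gi]
    migs <- inc <- numeric(reps)
    for (r in seq_len(reps)) {
      st <- gradual_separation_scenario(n_species, mm, ss, lambda, tip_mean)
      g <- simulate_gene_tree(st, n_individuals)
      migs[r] <- count_migrations(g)
      inc[r] <- count_inconsistent_coalescences(g, st)
    }
    data.frame(M = mm, S = ss, reps = reps,
               mean_migrations = mean(migs),
               se_migrations = stats::sd(migs) / sqrt(reps),
               mean_inconsistent = mean(inc),
               se_inconsistent = stats::sd(inc) / sqrt(reps),
               frac_ge1 = mean(migs >= 1))
  })
  res <- do.call(rbind, out)
  class(res) <- c("grid_result", class(res))
  res
}

#' Fit the saturating-hazard curve to grid means
#'
#' The expected migration (or inconsistent-coalescence) count over the
#' (M, S) grid is well described by a saturating function of the hazard
#' \eqn{h = M S}: \deqn{\mathrm{count}(M, S) \approx a\,h^c / (h^c + b).}
#' Least squares is fitted with Levenberg-Marquardt; a nested fit with
#' `c` fixed at 1 is returned alongside for comparison.
#'
#' @param grid a [run_grid()] result (or any data frame with `M`, `S` and
#'   the response column).
#' @param response column to fit, default `"mean_migrations"`.
#' @return List with `par` (named `a`, `b`, `c`), `residual_norm`,
#'   `residual_norm_c1` (the `c = 1` fit), and the two
#'   [minpack.lm::nls.lm()] fit objects.  Note that when the grid shows
#'   no saturation, `a` and `b` are only identified through their ratio.
#' @export
fit_hazard_curve <- function(grid, response = "mean_migrations") {
  h <- grid$M * grid$S
  y <- grid[[response]]
  keep <- h > 0
  if (sum(keep) < 6L) stop("degenerate grid: need >= 6 points with positive hazard")
  h <- h[keep]; y <- y[keep]
  resid3 <- function(p) y - p[1] * h^p[3] / (h^p[3] + p[2])
  resid2 <- function(p) y - p[1] * h / (h + p[2])
  start <- c(a = max(y) * 2, b = stats::median(h))
  fit <- minpack.lm::nls.lm(par = c(start, c = 1), fn = resid3,
                            lower = c(1e-8, 1e-8, 0.05),
                            upper = c(1e6, 1e6, 20),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  fit1 <- minpack.lm::nls.lm(par = start, fn = resid2,
                             lower = c(1e-8, 1e-8), upper = c(1e6, 1e6),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
  list(par = fit$par,
       residual_norm = sqrt(sum(resid3(fit$par)^2)),
       residual_norm_c1 = sqrt(sum(resid2(fit1$par)^2)),
       fit = fit, fit_c1 = fit1)
}

tree_clades <- function(phy) {
  # clade (tip-label set) below each edge, keyed by a canonical string
  n <- length(phy$tip.label)
  sets <- vector("list", n + phy$Nnode)
  sets[seq_len(n)] <- as.list(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  keys <- vapply(sets, function(s) paste(sort(s), collapse = "|"), "")
  len <- numeric(n + phy$Nnode)
  len[phy$edge[, 2L]] <- phy$edge.length
  stats::setNames(len[phy$edge[, 2L]], keys[phy$edge[, 2L]])
}

#' Rooted branch score between two trees
#'
#' Clade-matched branch-length distance for rooted trees on the same leaf
#' set: over the union of clades subtended by edges of either tree, the
#' squared differences of the subtending branch lengths are summed (a
#' clade absent from one tree contributes its full length squared) and
#' the square root is taken.  The score is zero exactly when topologies
#' and branch lengths coincide.  With `normalized = TRUE` the score is
#' divided by the number of clade terms.
#'
#' @param t1,t2 `phylo`, [species_tree()] or gene-tree objects with
#'   identical leaf sets.
#' @param normalized divide by the number of clade terms?
#' @return Nonnegative score.
#' @export
rooted_branch_score <- function(t1, t2, normalized = FALSE) {
  p1 <- if (inherits(t1, "species_tree")) as.phylo.species_tree(t1) else t1
  p2 <- if (inherits(t2, "species_tree")) as.phylo.species_tree(t2) else t2
  if (!setequal(p1$tip.label, p2$tip.label)) stop("trees must share a leaf set")
  b1 <- tree_clades(p1); b2 <- tree_clades(p2)
  keys <- union(names(b1), names(b2))
  v1 <- ifelse(keys %in% names(b1), b1[keys], 0)
  v2 <- ifelse(keys %in% names(b2), b2[keys], 0)
  sc <- sqrt(sum((v1 - v2)^2))
  if (normalized) sc / length(keys) else sc
}

pair_mrca_heights <- function(st) {
  n <- st$n_tips
  labs <- st_tip_labels(st)
  out <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    key <- paste(sort(c(labs[i], labs[j])), collapse = "|")
    out[[key]] <- st$heights[st_mrca(st, i, j)]
  }
  unlist(out)
}

#' Species-pair divergence bounds from gene trees
#'
#' For each species pair, the most recent coalescence joining lineages of
#' the two species across a set of gene trees: an upper bound on the
#' pair's divergence time that plays the role of a perfect-data
#' ("infinite sites") divergence estimate.
#'
#' @param gene_trees list of gene trees simulated within `st`.
#' @param st the species tree the gene trees were simulated in.
#' @return Named numeric vector, names `"spA|spB"`.
#' @export
pair_divergence_bounds <- function(gene_trees, st) {
  labs <- st_tip_labels(st)
  n <- st$n_tips
  best <- stats::setNames(rep(Inf, n * (n - 1L) / 2L),
                          unlist(lapply(seq_len(n - 1L), function(i)
                            vapply((i + 1L):n, function(j)
                              paste(sort(c(labs[i], labs[j])), collapse = "|"),
                              ""))))
  for (g in gene_trees) {
    h <- gene_tree_heights(g)
    spidx <- gene_tree_species_idx(g, st)
    ntip <- length(g$tip.label)
    po <- ape::reorder.phylo(g, "postorder")
    sets <- vector("list", ntip + g$Nnode)
    sets[seq_len(ntip)] <- as.list(spidx)
    for (k in seq_len(nrow(po$edge))) {
      p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
      old <- sets[[p]]
      if (!is.null(old) && length(sets[[ch]])) {
        for (i in old) for (j in sets[[ch]]) if (i != j) {
          key <- paste(sort(c(labs[i], labs[j])), collapse = "|")
          if (h[p] < best[key]) best[key] <- h[p]
        }
      }
      sets[[p]] <- union(old, sets[[ch]])
    }
  }
  best
}

#' Classify a tree sample against the weak and strong species trees
#'
#' Given a sample of species-tree estimates (or any rooted trees on the
#' species leaf set), computes the mean [rooted_branch_score()] to the
#' weak and to the strong reference tree, flags whether the sample is
#' closer to the weak end, and reports the mean pair location: for each
#' species pair the estimated divergence time \eqn{\hat t} is placed at
#' \eqn{(\hat t - t_s)/(t_w - t_s)} between the strong (\eqn{t_s}) and
#' weak (\eqn{t_w}) divergence of that pair, averaged over pairs and
#' trees (pairs with \eqn{t_w = t_s} are skipped).
#'
#' @param trees list of `phylo`/[species_tree()] objects, or a single one.
#' @param weak,strong the reference trees from [weak_tree()] and
#'   [strong_tree()].
#' @return List with `mean_score_weak`, `mean_score_strong`,
#'   `closer_to_weak`, `mean_pair_location`.
#' @export
weak_strong_classification <- function(trees, weak, strong) {
  if (!is.list(trees) || inherits(trees, "phylo") ||
      inherits(trees, "species_tree")) trees <- list(trees)
  stopifnot(length(trees) >= 1L)
  dw <- vapply(trees, rooted_branch_score, 0, t2 = weak)
  ds <- vapply(trees, rooted_branch_score, 0, t2 = strong)
  hw <- pair_mrca_heights(weak)
  hs <- pair_mrca_heights(strong)
  locs <- unlist(lapply(trees, function(tr) {
    stt <- if (inherits(tr, "species_tree")) tr else species_tree(tr)
    ht <- pair_mrca_heights(stt)
    keep <- hw[names(ht)] - hs[names(ht)] > 1e-12
    (ht[keep] - hs[names(ht)][keep]) / (hw[names(ht)][keep] - hs[names(ht)][keep])
  }))
  list(mean_score_weak = mean(dw), mean_score_strong = mean(ds),
       closer_to_weak = mean(dw) < mean(ds),
       mean_pair_location = if (length(locs)) mean(locs) else NA_real_)
}

#' Pairwise sequence identity under the no-migration reference scenario
#'
#' Simulates the fully specified no-migration setup used for sequence
#' summaries: `n_trees` Yule species trees, constant per-branch
#' population sizes drawn uniformly within `pop_spread` of `pop_mean`,
#' `n_ind` individuals per species, and `n_loci` independent gene trees
#' per species tree, each evolved into a Jukes-Cantor alignment of
#' `seq_length` sites under a strict clock.  Returns the mean fraction of
#' identical sites for same-species and for cross-species taxon pairs,
#' averaged over pairs, loci and trees.
#'
#' @param n_trees number of replicate species trees.
#' @param n_species,lambda Yule settings.
#' @param pop_mean,pop_spread constant-population settings.
#' @param n_ind individuals sampled per species.
#' @param n_loci loci (independent gene trees) per species tree.
#' @param seq_length sites per locus.
#' @param rate substitution rate per site per time unit.
#' @return Named vector with `within` and `between` mean identities (in
#'   \[0, 1\]).
#' @export
identity_experiment <- function(n_trees = 100, n_species = 5, lambda = 0.4,
                                pop_mean = 5 / 8, pop_spread = 0.2,
                                n_ind = 6, n_loci = 4, seq_length = 1600,
                                rate = 0.005) {
  wsum <- bsum <- 0; nw <- nb <- 0L
  for (r in seq_len(n_trees)) {
    st <- simulate_yule(n_species, lambda)
    st <- assign_constant_populations(st, pop_mean, pop_spread)
    for (loc in seq_len(n_loci)) {
      g <- simulate_gene_tree(st, n_ind)
      a <- simulate_jc(g, seq_length, rate)
      pp <- partition_pairs(rownames(a), g$tip.species[rownames(a)])
      id <- identity_matrix(a)
      wsum <- wsum + sum(id[pp$within]); nw <- nw + nrow(pp$within)
      bsum <- bsum + sum(id[pp$between]); nb <- nb + nrow(pp$between)
    }
  }
  c(within = wsum / nw, between = bsum / nb)
}

#' Fraction of gene trees carrying at least one migration
#'
#' Replicated gradual-separation simulations at a single (M, S) point
#' (fresh species tree per replicate), returning the incidence of
#' migration together with the mean event count.
#'
#' @inheritParams run_grid
#' @param M,S scenario parameters (scalars).
#' @return List with `frac_ge1`, `mean_migrations`, `reps`.
#' @export
migration_incidence <- function(M, S, reps = 2000, n_species = 5,
                                n_individuals = 10, lambda = 0.8,
                                tip_mean = 0.85) {
  migs <- numeric(reps)
  for (r in seq_len(reps)) {
    st <- gradual_separation_scenario(n_species, M, S, lambda, tip_mean)
    migs[r] <- count_migrations(simulate_gene_tree(st, n_individuals))
  }
  list(frac_ge1 = mean(migs >= 1), mean_migrations = mean(migs), reps = reps)
}
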