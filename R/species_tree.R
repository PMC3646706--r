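#' Species tree with demographic and migration decoration
#'
#' Wraps a rooted, ultrametric `phylo` tree (tips at time 0, node heights
#' increasing toward the past) and attaches, per branch, a piecewise-linear
#' population function \eqn{\nu(t)} and, per divergence, an optional
#' migration decoration describing gene flow between the two daughter
#' clades.  Branches are identified by the node at their recent end, so
#' branch `i` spans `[height(i), height(parent(i)))`; the root branch is
#' the ancestral population, extended indefinitely into the past.
#'
#' @param phy an ultrametric rooted `phylo` object with branch lengths in
#'   model time units.
#' @return An object of class `"species_tree"`.
#' @seealso [simulate_yule()], [assign_populations()],
#'   [assign_gradual_separation()], [simulate_gene_tree()]
#' @export
species_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"), !is.null(phy$edge.length))
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  depth <- ape::node.depth.edgelength(phy)
  h <- max(depth) - depth
  if (max(abs(h[seq_len(n)])) > 1e-8 * max(h))
    stop("species tree must be ultrametric (all tips at time 0)")
  h[seq_len(n)] <- 0
  parent <- rep(NA_integer_, nn)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  children <- vector("list", nn)
  for (e in seq_len(nrow(phy$edge)))
    children[[phy$edge[e, 1L]]] <- c(children[[phy$edge[e, 1L]]], phy$edge[e, 2L])
  st <- list(phy = phy, n_tips = n, n_nodes = nn, root = n + 1L,
             heights = h, parent = parent, children = children,
             nu = vector("list", nn), mig = vector("list", nn))
  st$clade_tips <- st_clade_tips(st)
  class(st) <- "species_tree"
  st
}

# single-population "tree": one branch from the present to infinity
#' One-population model (degenerate species tree)
#'
#' A single panmictic population with population function `nu`, used for
#' plain (unstructured) coalescent simulation.
#' @param nu a [piecewise_linear()] population function, or a single
#'   number for a constant population.
#' @export
single_population <- function(nu) {
  if (is.numeric(nu)) nu <- plf_const(nu)
  st <- list(phy = NULL, n_tips = 1L, n_nodes = 1L, root = 1L,
             heights = 0, parent = NA_integer_,
             children = list(NULL), nu = list(nu), mig = list(NULL),
             clade_tips = list(1L), tip_labels = "s1")
  class(st) <- "species_tree"
  st
}

st_tip_labels <- function(st) {
  if (is.null(st$phy)) st$tip_labels else st$phy$tip.label
}

st_clade_tips <- function(st) {
  out <- vector("list", st$n_nodes)
  ord <- order(st$heights)        # children before parents
  for (v in ord) {
    out[[v]] <- if (v <= st$n_tips) v
    else sort(unlist(out[st$children[[v]]]))
  }
  out
}

st_mrca <- function(st, a, b) {
  # most recent common ancestor of two (branch) nodes
  anc_a <- integer(0); v <- a
  while (!is.na(v)) { anc_a <- c(anc_a, v); v <- st$parent[v] }
  v <- b
  while (!is.na(v)) { if (v %in% anc_a) return(v); v <- st$parent[v] }
  stop("nodes do not share an ancestor")
}

# branches extant at time t (alive on [height, parent height))
st_extant <- function(st, t) {
  up <- ifelse(is.na(st$parent), Inf, st$heights[st$parent])
  which(st$heights <= t & up > t)
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species tree:", x$n_tips, "species\n")
  if (!is.null(x$phy))
    cat("  root height:", format(max(x$heights)), "\n")
  ndec <- sum(!vapply(x$mig, is.null, logical(1L)))
  npop <- sum(!vapply(x$nu, is.null, logical(1L)))
  cat("  populated branches:", npop, "/", x$n_nodes,
      " migration-decorated divergences:", ndec, "\n")
  invisible(x)
}

#' @exportS3Method ape::as.phylo
#' @rawNamespace export(as.phylo.species_tree)
as.phylo.species_tree <- function(x, ...) {
  if (is.null(x$phy)) stop("a single population has no phylo representation")
  x$phy
}

#' Simulate a Yule species tree
#'
#' Pure-birth species tree conditioned on `n_species` extant tips: going
#' backward from the present, while `i` lineages remain the waiting time
#' to the next join is Exponential(`lambda * i`) and a uniformly random
#' pair is joined.  The expected root height is
#' \eqn{\sum_{i=2}^{n} 1/(\lambda i)}.
#'
#' @param n_species number of extant species (>= 2).
#' @param lambda birth rate per lineage per time unit.
#' @return An undecorated [species_tree()] (topology and heights only).
#' @export
simulate_yule <- function(n_species, lambda) {
  n <- as.integer(n_species)
  stopifnot(n >= 2, lambda > 0)
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  hts <- numeric(2L * n - 1L)
  active <- seq_len(n)
  t <- 0; ne <- 0L; newid <- n
  for (i in n:2) {
    t <- t + stats::rexp(1L, lambda * i)
    pick <- sample.int(length(active), 2L)
    newid <- newid + 1L
    hts[newid] <- t
    for (ch in active[pick]) {
      ne <- ne + 1L
      edge[ne, ] <- c(newid, ch)
      elen[ne] <- t - hts[ch]
    }
    active <- c(active[-pick], newid)
  }
  # relabel internal nodes so the root is n+1 (ape convention): creation
  # order was by increasing height, so reverse it
  remap <- seq_len(2L * n - 1L)
  remap[(n + 1L):(2L * n - 1L)] <- (2L * n - 1L):(n + 1L)
  edge[] <- remap[edge]
  h2 <- hts; h2[remap] <- hts
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = paste0("s", seq_len(n)), Nnode = n - 1L),
                   class = "phylo", order = "postorder")
  st <- species_tree(phy)
  st$heights <- h2  # exact heights, avoids rounding from edge sums
  st
}

#' Assign population-size functions to a species tree
#'
#' Builds a continuous, strictly positive piecewise-linear population
#' history on every branch.  Present-day (tip) values are drawn from a
#' log-normal distribution with real-space mean `tip_mean` and log-space
#' standard deviation `sd_log`; each branch declines linearly backward in
#' time so that its older-end value equals `expansion` times its
#' younger-end value (populations grow toward the present for
#' `expansion < 1`); at each divergence the ancestral branch starts from
#' the mean of its children's older-end values.  The root (ancestral)
#' population is constant.
#'
#' @param st a [species_tree()].
#' @param tip_mean real-space mean of present-day population sizes (in
#'   \eqn{\nu} units).
#' @param sd_log log-space standard deviation of the tip draw.
#' @param expansion ratio of a branch's older-end to younger-end value,
#'   in (0, 1].
#' @return The decorated species tree.
#' @export
assign_populations <- function(st, tip_mean = 0.85, sd_log = 0.4, expansion = 0.7) {
  stopifnot(inherits(st, "species_tree"), tip_mean > 0,
            expansion > 0, expansion <= 1, sd_log >= 0)
  old_end <- numeric(st$n_nodes)
  for (v in order(st$heights)) {   # children before parents
    young <- if (v <= st$n_tips)
      stats::rlnorm(1L, meanlog = log(tip_mean) - sd_log^2 / 2, sdlog = sd_log)
    else mean(old_end[st$children[[v]]])
    if (is.na(st$parent[v])) {     # root branch: constant ancestral population
      st$nu[[v]] <- plf_const(young, at = st$heights[v])
      old_end[v] <- young
    } else {
      lo <- st$heights[v]; hi <- st$heights[st$parent[v]]
      old_end[v] <- expansion * young
      st$nu[[v]] <- piecewise_linear(c(lo, hi), c(young, old_end[v]))
    }
  }
  st
}

#' Assign constant per-branch population sizes
#'
#' Each branch (including the root/ancestral branch) receives a constant
#' population size drawn uniformly within `+/- spread` of `mean`.
#'
#' @param st a [species_tree()].
#' @param mean central population size (\eqn{\nu} units).
#' @param spread relative half-width of the uniform draw (0.2 = +/-20%).
#' @return The decorated species tree.
#' @export
assign_constant_populations <- function(st, mean, spread = 0) {
  stopifnot(mean > 0, spread >= 0, spread < 1)
  for (v in seq_len(st$n_nodes))
    st$nu[[v]] <- plf_const(stats::runif(1L, mean * (1 - spread), mean * (1 + spread)),
                            at = st$heights[v])
  st
}

#' Decorate a species tree with the gradual-separation scenario
#'
#' Under gradual separation each divergence at height \eqn{t_d} is
#' followed (forward in time) by an interval of declining reciprocal gene
#' flow: the migration fraction between the two daughter clades starts at
#' `M` at the divergence and declines linearly to zero at the complete
#' separation time \eqn{t_s}, i.e. \eqn{m(t) = M (t - t_s)/(t_d - t_s)}
#' on \eqn{[t_s, t_d]} and zero elsewhere.  The interval length
#' \eqn{t_d - t_s} is drawn from a log-normal distribution with real-space
#' mean `S / (2 lambda)` (the expected branch length of a Yule tree times
#' `S`) and log-space standard deviation `sd_log`; `S` is therefore the
#' mean separation duration as a fraction of the mean species lifetime.
#'
#' Complete separation of a clade is constrained to happen no later
#' (going forward) than complete separation of any of its descendants:
#' processing divergences from the root down, a child's interval is
#' redrawn (up to `max_redraw` times, then truncated) until its
#' \eqn{t_s} does not exceed its parent's.  Separation intervals are
#' truncated at the present (\eqn{t_s \ge 0}).
#'
#' @param st a [species_tree()].
#' @param M migration fraction at the time of divergence (per time unit).
#' @param S mean separation duration as a fraction of mean species
#'   lifetime; `M = 0` or `S = 0` gives the strict multispecies
#'   coalescent (no migration).
#' @param lambda the Yule rate used to scale `S` into absolute time.
#' @param sd_log log-space standard deviation of the interval draw.
#' @param max_redraw redraw budget for the nesting constraint.
#' @return The decorated species tree.
#' @export
assign_gradual_separation <- function(st, M, S, lambda, sd_log = 0.25,
                                      max_redraw = 100L) {
  stopifnot(inherits(st, "species_tree"), M >= 0, S >= 0, lambda > 0)
  internal <- which(seq_len(st$n_nodes) > st$n_tips)
  if (is.null(st$phy)) return(st)
  st$mig[internal] <- list(NULL)
  if (M == 0 || S == 0) return(st)
  meanlog <- log(S / (2 * lambda)) - sd_log^2 / 2
  ts <- rep(NA_real_, st$n_nodes)
  for (v in internal[order(st$heights[internal], decreasing = TRUE)]) {
    td <- st$heights[v]
    cap <- if (is.na(st$parent[v])) Inf else ts[st$parent[v]]
    tsv <- NA_real_
    for (i in seq_len(max_redraw)) {
      L <- stats::rlnorm(1L, meanlog, sd_log)
      cand <- max(td - L, 0)
      if (cand <= cap) { tsv <- cand; break }
    }
    if (is.na(tsv)) tsv <- min(cap, td)   # truncate to the parent's t_s
    ts[v] <- tsv
    if (tsv < td) {
      m <- piecewise_linear(c(tsv, td), c(0, M))
      st$mig[[v]] <- list(ts = tsv, td = td, m12 = m, m21 = m)
    } else {
      st$mig[[v]] <- NULL                 # degenerate interval: no gene flow
      ts[v] <- td
    }
  }
  st
}

#' Manually decorate a divergence with migration functions
#'
#' Attaches gene-flow functions to the divergence at internal node `node`:
#' `m12` is the forward-time emigrant fraction from the first daughter
#' clade into the second, `m21` the reverse.  Both are zero outside
#' `window`.
#'
#' @param st a [species_tree()].
#' @param node internal node id (> number of tips).
#' @param m12,m21 [piecewise_linear()] migration fractions (per time
#'   unit); a single number is taken as a constant.
#' @param window numeric length-2 support `[t_s, t_d]`; defaults to the
#'   full branch interval below the divergence, capped at its height.
#' @return The decorated species tree.
#' @export
set_migration <- function(st, node, m12, m21 = m12, window = NULL) {
  stopifnot(inherits(st, "species_tree"), node > st$n_tips, node <= st$n_nodes)
  if (is.numeric(m12)) m12 <- plf_const(m12)
  if (is.numeric(m21)) m21 <- plf_const(m21)
  td <- st$heights[node]
  if (is.null(window)) window <- c(0, td)
  stopifnot(length(window) == 2L, window[1] <= window[2],
            window[2] <= td + 1e-6 * max(1, td))
  window[2] <- min(window[2], td)
  st$mig[[node]] <- list(ts = window[1], td = window[2], m12 = m12, m21 = m21)
  st
}

#' Set the population function of one branch
#' @param st a [species_tree()].
#' @param node branch id (node at the branch's recent end).
#' @param nu a [piecewise_linear()] or a constant.
#' @export
set_population <- function(st, node, nu) {
  stopifnot(inherits(st, "species_tree"), node >= 1, node <= st$n_nodes)
  if (is.numeric(nu)) nu <- plf_const(nu, at = st$heights[node])
  st$nu[[node]] <- nu
  st
}

# migration decoration covering ordered branch pair (from, to) at time t,
# or NULL.  Returns list(dec, v, side_from, side_to) with side indices 1/2
# referring to the decorated node's children.
st_pair_decoration <- function(st, from, to) {
  v <- st_mrca(st, from, to)
  if (v <= st$n_tips || is.null(st$mig[[v]])) return(NULL)
  ch <- st$children[[v]]
  side_of <- function(x) {
    if (x == ch[1L] || all(st$clade_tips[[x]] %in% st$clade_tips[[ch[1L]]])) 1L else 2L
  }
  list(dec = st$mig[[v]], v = v, side_from = side_of(from), side_to = side_of(to))
}

#' Backward migration rate between two extant branches
#'
#' The instantaneous rate, looking backward in time, at which a gene
#' lineage currently in branch `from` traces its ancestry to branch `to`
#' at time `t`.  The rate is resolved through the migration decoration at
#' the most recent common ancestor of the two branches: forward-time
#' emigrants leaving the side containing `to` (each branch contributing in
#' proportion to its population size) arrive on the side containing
#' `from` and are shared among its extant branches in proportion to their
#' population sizes, giving \deqn{f_{from \to to}(t) =
#' m_{to\text{-}side \to from\text{-}side}(t)\; \nu_{to}(t) /
#' \nu_{from\text{-}side,\,tot}(t).}
#' With a single branch on each side this reduces to the classical
#' two-population backward rate \eqn{m_{b \to a}(t)\,\nu_b(t)/\nu_a(t)}.
#'
#' @param st a decorated [species_tree()].
#' @param from,to branch ids, both extant at `t`.
#' @param t time before the present.
#' @return Per-lineage backward migration rate (possibly 0).
#' @export
backward_migration_rate <- function(st, from, to, t) {
  ext <- st_extant(st, t)
  if (!(from %in% ext) || !(to %in% ext))
    stop("both branches must be extant at time t")
  pd <- st_pair_decoration(st, from, to)
  if (is.null(pd)) return(0)
  dec <- pd$dec
  if (t < dec$ts || t > dec$td) return(0)
  # forward flow out of the to-side: m_{to_side -> from_side}
  m <- if (pd$side_to == 1L) dec$m12 else dec$m21
  ch <- st$children[[pd$v]]
  from_side_tips <- st$clade_tips[[ch[[pd$side_from]]]]
  side_branches <- ext[vapply(ext, function(x)
    all(st$clade_tips[[x]] %in% from_side_tips), logical(1L))]
  nu_tot <- sum(vapply(side_branches, function(x) plf_eval(st$nu[[x]], t), 0))
  plf_eval(m, t) * plf_eval(st$nu[[to]], t) / nu_tot
}

#' Weak and strong speciation trees
#'
#' Under gradual separation a divergence can be timed either at the start
#' of separation (the decorated divergence height \eqn{t_d}; the *weak*
#' tree) or at the completion of separation (\eqn{t_s}; the *strong*
#' tree).  `weak_tree()` returns the tree with its original heights;
#' `strong_tree()` moves every decorated divergence down to its
#' \eqn{t_s}.  Without migration the two coincide.
#'
#' @param st a decorated [species_tree()].
#' @return A [species_tree()] (topology preserved; `strong_tree` carries
#'   no decorations).
#' @export
weak_tree <- function(st) {
  stopifnot(inherits(st, "species_tree"))
  st
}

#' @rdname weak_tree
#' @export
strong_tree <- function(st) {
  stopifnot(inherits(st, "species_tree"), !is.null(st$phy))
  h <- st$heights
  for (v in (st$n_tips + 1L):st$n_nodes)
    if (!is.null(st$mig[[v]])) h[v] <- st$mig[[v]]$ts
  phy <- st$phy
  phy$edge.length <- h[phy$edge[, 1L]] - h[phy$edge[, 2L]]
  out <- species_tree_from_heights(phy, h, st)
  out
}

species_tree_from_heights <- function(phy, h, template) {
  st <- list(phy = phy, n_tips = template$n_tips, n_nodes = template$n_nodes,
             root = template$root, heights = h, parent = template$parent,
             children = template$children,
             nu = vector("list", template$n_nodes),
             mig = vector("list", template$n_nodes),
             clade_tips = template$clade_tips)
  class(st) <- "species_tree"
  st
}

# exhaustive nesting check: every decorated divergence separates no later
# (in height) than its decorated ancestors
check_nesting <- function(st) {
  for (v in which(!vapply(st$mig, is.null, logical(1L)))) {
    p <- st$parent[v]
    while (!is.na(p)) {
      if (!is.null(st$mig[[p]]) && st$mig[[v]]$ts > st$mig[[p]]$ts + 1e-12)
        return(FALSE)
      p <- st$parent[p]
    }
  }
  TRUE
}
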