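# Epoch tables: between two successive divergences the set of extant
# species branches is fixed, so per-branch coalescent hazards and
# per-ordered-pair backward migration hazards can be precomputed once and
# reused for every waiting-time draw inside the epoch.
epoch_tables <- function(st) {
  n <- st$n_tips
  internal <- if (st$n_nodes > n) (n + 1L):st$n_nodes else integer(0)
  divs <- internal[order(st$heights[internal])]
  bounds <- c(0, st$heights[divs], Inf)
  coal_h <- vector("list", st$n_nodes)
  for (b in seq_len(st$n_nodes)) {
    if (is.null(st$nu[[b]]))
      stop("configuration error: branch ", b, " has no population function")
    up <- if (is.na(st$parent[b])) Inf else st$heights[st$parent[b]]
    coal_h[[b]] <- hazard(den = st$nu[[b]], window = c(st$heights[b], up))
  }
  decorated <- which(!vapply(st$mig, is.null, logical(1L)))
  epochs <- vector("list", length(bounds) - 1L)
  for (e in seq_along(epochs)) {
    lo <- bounds[e]; hi <- bounds[e + 1L]
    ext <- st_extant(st, lo)
    pfrom <- integer(0); pto <- integer(0); ph <- list()
    for (v in decorated) {
      dec <- st$mig[[v]]
      if (dec$ts >= hi || dec$td <= lo) next
      ch <- st$children[[v]]
      in_clade <- function(x, c) all(st$clade_tips[[x]] %in% st$clade_tips[[c]])
      s1 <- ext[vapply(ext, in_clade, logical(1L), c = ch[1L])]
      s2 <- ext[vapply(ext, in_clade, logical(1L), c = ch[2L])]
      if (!length(s1) || !length(s2)) next
      win <- c(max(lo, dec$ts), min(hi, dec$td))
      nu1 <- plf_sum(st$nu[s1]); nu2 <- plf_sum(st$nu[s2])
      for (x in s1) for (y in s2) {    # backward jump x -> y: forward flow side2 -> side1
        pfrom <- c(pfrom, x); pto <- c(pto, y)
        ph <- c(ph, list(hazard(num1 = dec$m21, num2 = st$nu[[y]], den = nu1,
                                window = win)))
      }
      for (x in s2) for (y in s1) {
        pfrom <- c(pfrom, x); pto <- c(pto, y)
        ph <- c(ph, list(hazard(num1 = dec$m12, num2 = st$nu[[y]], den = nu2,
                                window = win)))
      }
    }
    epochs[[e]] <- list(lo = lo, hi = hi,
                        div_node = if (e <= length(divs)) divs[e] else NA_integer_,
                        branches = ext, pfrom = pfrom, pto = pto, ph = ph)
  }
  list(epochs = epochs, coal_h = coal_h)
}

#' Simulate a gene tree within a decorated species tree
#'
#' The structured-coalescent simulator at the heart of the package.
#' Starting from the sampled lineages at the present and moving backward
#' in time, one candidate waiting time is drawn for every possible event:
#' a coalescence per species with at least two resident lineages (hazard
#' \eqn{\binom{l}{2}/\nu(t)}) and a backward migration per ordered pair
#' of co-extant species (hazard \eqn{l \times} the per-lineage
#' [backward_migration_rate()]).  The earliest candidate is applied and
#' all times are redrawn from the new state.  A candidate falling beyond
#' the next species divergence is rejected: time advances to the
#' divergence, the two daughter species' lineage sets merge into the
#' ancestral branch, and the draw is repeated.  Above the root the
#' process is a one-population coalescent under the root branch's
#' (constant-extended) population function.  The simulation ends when a
#' single lineage remains.
#'
#' @param st a [species_tree()] with population functions on every branch
#'   (migration decorations optional).
#' @param samples per-species sample counts: a vector named by species
#'   tip label, an unnamed vector in tip-id order, or a single count
#'   recycled to all species.  Species with 0 samples still exist as
#'   migration destinations.
#' @return An object of classes `"gene_tree"` and `"phylo"`: a binary
#'   ultrametric genealogy whose tips are labelled
#'   `"<species>_<individual>"`, with components `node.heights`
#'   (times of all nodes), `tip.species`, and `migrations` (a data frame
#'   with one row per backward-time jump: `time`, `from`, `to` species
#'   branch ids and the gene-tree `node` below the branch the event sits
#'   on).
#' @export
simulate_gene_tree <- function(st, samples) {
  stopifnot(inherits(st, "species_tree"))
  labs <- st_tip_labels(st)
  n_sp <- st$n_tips
  if (length(samples) == 1L && n_sp > 1L) samples <- rep(samples, n_sp)
  if (!is.null(names(samples))) samples <- samples[labs]
  samples <- as.integer(samples)
  stopifnot(length(samples) == n_sp, all(samples >= 0), sum(samples) >= 2)
  tabs <- epoch_tables(st)

  N <- sum(samples)
  lin_sp <- rep.int(seq_len(n_sp), samples)      # species branch per lineage
  lin_id <- seq_len(N)                           # gene-tree node ids
  tip_species <- stats::setNames(labs[lin_sp],
                                 paste0(labs[lin_sp], "_",
                                        sequence(samples[samples > 0])))
  hts <- numeric(2L * N - 1L)
  edge <- matrix(0L, 2L * (N - 1L), 2L)
  elen <- numeric(2L * (N - 1L))
  mig_t <- mig_from <- mig_to <- mig_node <- numeric(0)
  ne <- 0L; n_int <- 0L
  t <- 0; e <- 1L

  while (length(lin_id) > 1L) {
    ep <- tabs$epochs[[e]]
    H <- ep$hi
    best <- Inf; best_kind <- 0L; best_a <- 0L; best_b <- 0L
    for (b in ep$branches) {
      l <- sum(lin_sp == b)
      if (l >= 2L) {
        tt <- solve_waiting_time(tabs$coal_h[[b]], t, stats::runif(1L),
                                 horizon = H, scale = l * (l - 1) / 2)
        if (tt < best) { best <- tt; best_kind <- 1L; best_a <- b }
      }
    }
    for (p in seq_along(ep$ph)) {
      l <- sum(lin_sp == ep$pfrom[p])
      if (l >= 1L) {
        tt <- solve_waiting_time(ep$ph[[p]], t, stats::runif(1L),
                                 horizon = H, scale = l)
        if (tt < best) {
          best <- tt; best_kind <- 2L
          best_a <- ep$pfrom[p]; best_b <- ep$pto[p]
        }
      }
    }
    if (!is.finite(best)) {
      # no event before the next divergence: advance and merge species
      if (!is.finite(H)) stop("internal error: no event possible above the root")
      v <- ep$div_node
      lin_sp[lin_sp %in% st$children[[v]]] <- v
      t <- H; e <- e + 1L
      next
    }
    t <- best
    if (best_kind == 1L) {                       # coalescence in branch best_a
      idx <- which(lin_sp == best_a)
      pick <- idx[sample.int(length(idx), 2L)]
      n_int <- n_int + 1L
      newid <- N + n_int
      hts[newid] <- t
      for (ii in pick) {
        ne <- ne + 1L
        edge[ne, ] <- c(newid, lin_id[ii])
        elen[ne] <- t - hts[lin_id[ii]]
      }
      lin_id[pick[1L]] <- newid
      lin_id <- lin_id[-pick[2L]]
      lin_sp <- lin_sp[-pick[2L]]
    } else {                                     # migration best_a -> best_b
      idx <- which(lin_sp == best_a)
      ii <- idx[sample.int(length(idx), 1L)]
      lin_sp[ii] <- best_b
      mig_t <- c(mig_t, t); mig_from <- c(mig_from, best_a)
      mig_to <- c(mig_to, best_b); mig_node <- c(mig_node, lin_id[ii])
    }
  }

  # relabel internal nodes to the ape convention (root = N + 1): creation
  # order was by increasing height, so reverse it
  remap <- seq_len(2L * N - 1L)
  remap[(N + 1L):(2L * N - 1L)] <- (2L * N - 1L):(N + 1L)
  edge[] <- remap[edge]
  h2 <- hts; h2[remap] <- hts
  mig_node <- remap[mig_node]
  g <- structure(list(edge = edge, edge.length = elen,
                      tip.label = names(tip_species), Nnode = N - 1L,
                      node.heights = h2, tip.species = tip_species,
                      migrations = data.frame(time = mig_t, from = mig_from,
                                              to = mig_to, node = mig_node)),
                 class = c("gene_tree", "phylo"), order = "postorder")
  g
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("gene tree:", length(x$tip.label), "tips,",
      nrow(x$migrations), "migration event(s), root height",
      format(max(x$node.heights)), "\n")
  invisible(x)
}

#' Number of migration events on a gene tree
#'
#' @param g a gene tree from [simulate_gene_tree()] (or
#'   [euler_simulate()]).
#' @return Total count of backward-time migration jumps over all branches.
#' @export
count_migrations <- function(g) {
  stopifnot(inherits(g, "gene_tree"))
  nrow(g$migrations)
}

gene_tree_heights <- function(g) {
  if (!is.null(g$node.heights)) return(g$node.heights)
  depth <- ape::node.depth.edgelength(g)
  h <- max(depth) - depth
  h[seq_along(g$tip.label)] <- 0
  h
}

gene_tree_species_idx <- function(g, st) {
  labs <- st_tip_labels(st)
  spn <- if (!is.null(g$tip.species)) unname(g$tip.species[g$tip.label])
  else sub("_[0-9]+$", "", g$tip.label)
  idx <- match(spn, labs)
  if (anyNA(idx)) stop("gene-tree tips do not map onto species-tree tips")
  idx
}

#' Count gene-tree coalescences inconsistent with the species tree
#'
#' A coalescence is *inconsistent* when it is more recent than the
#' species-tree divergence of the species involved: the node's time is
#' below the (weak) species-tree MRCA height of the set of species
#' sampled beneath it.  Such events are impossible under strict
#' divergence and are created by migrating lineages.  With
#' `per = "pair"` the count is instead the number of species pairs for
#' which at least one coalescence joins lineages of both species below
#' the pair's divergence.
#'
#' @param g a gene tree simulated within `st`.
#' @param st the (weak) species tree.
#' @param per count individual coalescence nodes (`"node"`, default) or
#'   affected species pairs (`"pair"`).
#' @return Nonnegative integer count.
#' @export
count_inconsistent_coalescences <- function(g, st, per = c("node", "pair")) {
  per <- match.arg(per)
  stopifnot(inherits(g, "phylo"), inherits(st, "species_tree"))
  n <- length(g$tip.label)
  h <- gene_tree_heights(g)
  spidx <- gene_tree_species_idx(g, st)
  # postorder over gene-tree internal nodes
  po <- ape::reorder.phylo(g, "postorder")
  rep_node <- integer(n + g$Nnode)       # species-tree MRCA of species below
  rep_node[seq_len(n)] <- spidx
  spset <- vector("list", n + g$Nnode)
  spset[seq_len(n)] <- as.list(spidx)
  eps <- 1e-12
  bad_nodes <- integer(0)
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    rep_node[p] <- if (rep_node[p] == 0L) rep_node[ch]
    else st_mrca(st, rep_node[p], rep_node[ch])
    spset[[p]] <- union(spset[[p]], spset[[ch]])
  }
  for (v in (n + 1L):(n + g$Nnode)) {
    m <- rep_node[v]
    if (m > st$n_tips && h[v] < st$heights[m] - eps)
      bad_nodes <- c(bad_nodes, v)
  }
  if (per == "node") return(length(bad_nodes))
  pairs <- character(0)
  for (v in bad_nodes) {
    sps <- spset[[v]]
    mh <- st$heights
    for (i in sps) for (j in sps) if (i < j) {
      if (h[v] < st$heights[st_mrca(st, i, j)] - eps)
        pairs <- c(pairs, paste(i, j))
    }
  }
  length(unique(pairs))
}
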