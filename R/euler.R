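#' Euler small-step simulation of the structured coalescent
#'
#' Independent discretized oracle for [simulate_gene_tree()]: time is cut
#' into steps of width `dt`, in each step every possible event (per-species
#' coalescence, per-ordered-pair backward migration) occurs with
#' probability `rate(t) * dt`, and at most one event can occur per step.
#' Species divergences are snapped onto the step grid, merging the two
#' daughter lineage sets exactly as the exact simulator does.  The output
#' contract is identical to [simulate_gene_tree()].
#'
#' The step width must satisfy `max total event probability per step <
#' 0.1`; exceeding it raises an error rather than silently biasing the
#' discretization.
#'
#' @param st a decorated [species_tree()].
#' @param samples per-species sample counts (see [simulate_gene_tree()]).
#' @param dt step width in model time units.
#' @return A `"gene_tree"` object.
#' @export
euler_simulate <- function(st, samples, dt = 1e-3) {
  stopifnot(inherits(st, "species_tree"), dt > 0)
  labs <- st_tip_labels(st)
  n_sp <- st$n_tips
  if (length(samples) == 1L && n_sp > 1L) samples <- rep(samples, n_sp)
  if (!is.null(names(samples))) samples <- samples[labs]
  samples <- as.integer(samples)
  stopifnot(length(samples) == n_sp, all(samples >= 0), sum(samples) >= 2)
  tabs <- epoch_tables(st)

  N <- sum(samples)
  lin_sp <- rep.int(seq_len(n_sp), samples)
  lin_id <- seq_len(N)
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
    if (is.finite(ep$hi) && t >= ep$hi - 1e-15) {
      v <- ep$div_node
      lin_sp[lin_sp %in% st$children[[v]]] <- v
      e <- e + 1L
      next
    }
    step <- if (is.finite(ep$hi)) min(dt, ep$hi - t) else dt
    # event probabilities for this step, rates evaluated at the step start
    kinds <- integer(0); aa <- integer(0); bb <- integer(0); pr <- numeric(0)
    for (b in ep$branches) {
      l <- sum(lin_sp == b)
      if (l >= 2L) {
        kinds <- c(kinds, 1L); aa <- c(aa, b); bb <- c(bb, 0L)
        pr <- c(pr, l * (l - 1) / 2 * hazard_rate(tabs$coal_h[[b]], t) * step)
      }
    }
    for (p in seq_along(ep$ph)) {
      l <- sum(lin_sp == ep$pfrom[p])
      if (l >= 1L) {
        kinds <- c(kinds, 2L); aa <- c(aa, ep$pfrom[p]); bb <- c(bb, ep$pto[p])
        pr <- c(pr, l * hazard_rate(ep$ph[[p]], t) * step)
      }
    }
    if (sum(pr) > 0.1) stop("dt too large: total event probability per step exceeds 0.1")
    u <- stats::runif(1L)
    hit <- which(u < cumsum(pr))
    t <- t + step
    if (length(hit)) {
      w <- hit[1L]
      if (kinds[w] == 1L) {
        idx <- which(lin_sp == aa[w])
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
      } else {
        idx <- which(lin_sp == aa[w])
        ii <- idx[sample.int(length(idx), 1L)]
        lin_sp[ii] <- bb[w]
        mig_t <- c(mig_t, t); mig_from <- c(mig_from, aa[w])
        mig_to <- c(mig_to, bb[w]); mig_node <- c(mig_node, lin_id[ii])
      }
    }
  }

  remap <- seq_len(2L * N - 1L)
  remap[(N + 1L):(2L * N - 1L)] <- (2L * N - 1L):(N + 1L)
  edge[] <- remap[edge]
  h2 <- hts; h2[remap] <- hts
  if (length(mig_node)) mig_node <- remap[mig_node]
  structure(list(edge = edge, edge.length = elen,
                 tip.label = names(tip_species), Nnode = N - 1L,
                 node.heights = h2, tip.species = tip_species,
                 migrations = data.frame(time = mig_t, from = mig_from,
                                         to = mig_to, node = mig_node)),
            class = c("gene_tree", "phylo"), order = "postorder")
}

#' Vectorized Euler root-height sampler for the constant-rate case
#'
#' Euler-discretized root heights for the two-population constant-rate
#' model of [ctmc_model()]: all `n` replicates are stepped through the
#' lineage-configuration chain simultaneously (probability `rate * dt`
#' per event per step, at most one event per step), before and after the
#' divergence, until every replicate has coalesced to a single lineage.
#' This is the same discretized process as [euler_simulate()], specialised
#' to constant rates so that large validation samples are cheap.
#'
#' @param model a [ctmc_model()].
#' @param n number of replicate root heights.
#' @param dt step width.
#' @param max_time absorb-by horizon (generous tail guard; an error is
#'   raised if any replicate is still uncoalesced).
#' @return Numeric vector of `n` root heights.
#' @export
euler_root_heights <- function(model, n, dt = 2e-3, max_time = NULL) {
  stopifnot(inherits(model, "ctmc_model"), n >= 1, dt > 0)
  Q <- model$Q
  ns <- nrow(Q)
  ktot <- model$states[, "i"] + model$states[, "j"]
  if (max(-diag(Q)) * dt > 0.1 ||
      max(ktot * (ktot - 1) / 2 / model$nu_anc) * dt > 0.1)
    stop("dt too large: total event probability per step exceeds 0.1")
  # per-state cumulative transition probabilities for one step
  P <- Q * dt; diag(P) <- 0
  cumP <- t(apply(P, 1L, cumsum))
  tot <- cumP[, ns]
  state <- rep.int(model$start, n)
  out <- rep(NA_real_, n)
  t <- 0
  nstep_T <- ceiling(model$T / dt)
  for (s in seq_len(nstep_T)) {
    alive <- which(ktot[state] > 1L)
    if (length(alive)) {
      u <- stats::runif(length(alive))
      st_a <- state[alive]
      moved <- u < tot[st_a]
      if (any(moved)) {
        mi <- alive[moved]
        newst <- vapply(seq_along(mi), function(z) {
          ss <- state[mi[z]]
          which(u[moved][z] < cumP[ss, ])[1L]
        }, 0L)
        state[mi] <- newst
      }
    }
    t <- t + dt
    done <- ktot[state] == 1L & is.na(out)
    out[done] <- t
  }
  # ancestral single population: plain coalescent chain on lineage counts
  k <- ktot[state]
  if (is.null(max_time)) max_time <- model$T + 60 * model$nu_anc
  while (any(k > 1L) && t < max_time) {
    t <- t + dt
    alive <- which(k > 1L)
    p <- k[alive] * (k[alive] - 1) / 2 / model$nu_anc * dt
    hit <- stats::runif(length(alive)) < p
    k[alive[hit]] <- k[alive[hit]] - 1L
    newly <- alive[hit][k[alive[hit]] == 1L]
    out[newly] <- t
  }
  if (any(k > 1L)) stop("max_time reached before all replicates coalesced")
  out
}
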