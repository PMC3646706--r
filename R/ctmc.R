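# Hypoexponential distribution: the law of a sum of independent
# exponentials with distinct rates; the ancestral-population TMRCA of k
# exchangeable lineages is hypoexponential with rates choose(j,2)/nu,
# j = k..2.
hypoexp_weights <- function(rates) {
  k <- length(rates)
  if (k == 1L) return(1)
  if (any(duplicated(rates))) stop("hypoexponential rates must be distinct")
  vapply(seq_len(k), function(i)
    prod(rates[-i] / (rates[-i] - rates[i])), 0)
}

dhypoexp <- function(x, rates) {
  w <- hypoexp_weights(rates)
  out <- numeric(length(x))
  ok <- x >= 0
  for (i in seq_along(rates))
    out[ok] <- out[ok] + w[i] * rates[i] * exp(-rates[i] * x[ok])
  out
}

phypoexp <- function(q, rates) {
  w <- hypoexp_weights(rates)
  out <- numeric(length(q))
  ok <- q >= 0
  for (i in seq_along(rates))
    out[ok] <- out[ok] + w[i] * (1 - exp(-rates[i] * q[ok]))
  out
}

#' Lineage-configuration CTMC for the two-population constant-rate case
#'
#' Builds the continuous-time Markov chain over lineage configurations
#' \eqn{(i, j)} (i lineages in population *a*, j in *b*, down to a single
#' absorbing ancestral lineage) for two populations of constant sizes
#' with constant reciprocal migration fractions, diverging `T` time units
#' in the past.  Coalescences occur at rate \eqn{\binom{i}{2}/\nu_a}
#' (resp. \eqn{\binom{j}{2}/\nu_b}); each lineage in *a* jumps backward
#' to *b* at rate \eqn{m_{b\to a} \nu_b/\nu_a} and vice versa.  The
#' generator is exponentiated to obtain configuration probabilities at
#' the divergence; lineages remaining there coalesce in the ancestral
#' population, whose time to the ultimate common ancestor is
#' hypoexponential with rates \eqn{\binom{k}{2}/\nu_{anc}}.
#'
#' Together these give the exact root-height distribution used to
#' validate the stochastic simulators.
#'
#' @param n_a,n_b sampled lineage counts in the two populations.
#' @param nu_a,nu_b,nu_anc constant population sizes (\eqn{\nu} units) of
#'   the two populations and their ancestor.
#' @param m_ab forward-time migration fraction from *a* to *b* (per time
#'   unit); `m_ba` likewise.
#' @param T divergence time (time units before present).
#' @return An object of class `"ctmc_model"` with the generator `Q`,
#'   state table, and model parameters.
#' @export
ctmc_model <- function(n_a, n_b, nu_a, nu_b, nu_anc, m_ab, m_ba = m_ab, T) {
  n <- n_a + n_b
  stopifnot(n >= 2, nu_a > 0, nu_b > 0, nu_anc > 0, m_ab >= 0, m_ba >= 0, T >= 0)
  states <- do.call(rbind, lapply(n:1, function(k)
    cbind(i = k:0, j = 0:k)))
  ns <- nrow(states)
  sid <- function(i, j) which(states[, "i"] == i & states[, "j"] == j)
  f_a <- m_ba * nu_b / nu_a     # backward per-lineage jump rate a -> b
  f_b <- m_ab * nu_a / nu_b
  Q <- matrix(0, ns, ns)
  for (s in seq_len(ns)) {
    i <- states[s, "i"]; j <- states[s, "j"]
    if (i + j == 1L) next                      # absorbing: single lineage
    if (i >= 2) Q[s, sid(i - 1L, j)] <- Q[s, sid(i - 1L, j)] + i * (i - 1) / 2 / nu_a
    if (j >= 2) Q[s, sid(i, j - 1L)] <- Q[s, sid(i, j - 1L)] + j * (j - 1) / 2 / nu_b
    if (i >= 1) Q[s, sid(i - 1L, j + 1L)] <- Q[s, sid(i - 1L, j + 1L)] + i * f_a
    if (j >= 1) Q[s, sid(i + 1L, j - 1L)] <- Q[s, sid(i + 1L, j - 1L)] + j * f_b
  }
  diag(Q) <- -rowSums(Q)
  structure(list(Q = Q, states = states, start = sid(n_a, n_b), n = n,
                 nu_a = nu_a, nu_b = nu_b, nu_anc = nu_anc,
                 m_ab = m_ab, m_ba = m_ba, T = T,
                 f_a = f_a, f_b = f_b),
            class = "ctmc_model")
}

ctmc_probs_at <- function(model, t) {
  p0 <- numeric(nrow(model$states)); p0[model$start] <- 1
  as.numeric(p0 %*% as.matrix(Matrix::expm(Matrix::Matrix(model$Q * t))))
}

anc_rates <- function(k, nu_anc) k:2 * (k:2 - 1) / 2 / nu_anc

#' Closed-form root-height distribution of the two-population model
#'
#' Density (`root_height_density`) and distribution function
#' (`root_height_cdf`) of the gene-tree root height under a
#' [ctmc_model()].  Before the divergence `T` the density of full
#' coalescence is obtained from the matrix exponential of the generator;
#' lineages remaining at `T` are folded into the ancestral
#' single-population coalescent, whose time to the common ancestor is
#' hypoexponential.
#'
#' @param model a [ctmc_model()].
#' @param grid times at which to evaluate.
#' @return `root_height_density`: density values on `grid`.
#'   `root_height_cdf`: a vectorized function of time, suitable for
#'   [ks_compare()].
#' @export
root_height_density <- function(model, grid) {
  st <- model$states
  two <- which(st[, "i"] + st[, "j"] == 2L)
  coal2 <- ifelse(st[two, "i"] == 2L, 1 / model$nu_a,
                  ifelse(st[two, "j"] == 2L, 1 / model$nu_b, 0))
  pT <- ctmc_probs_at(model, model$T)
  ktot <- st[, "i"] + st[, "j"]
  pk <- vapply(2:model$n, function(k) sum(pT[ktot == k]), 0)
  vapply(grid, function(t) {
    if (t < model$T) {
      p <- ctmc_probs_at(model, t)
      sum(p[two] * coal2)
    } else {
      s <- 0
      for (k in 2:model$n)
        if (pk[k - 1L] > 0)
          s <- s + pk[k - 1L] * dhypoexp(t - model$T, anc_rates(k, model$nu_anc))
      s
    }
  }, 0)
}

#' @rdname root_height_density
#' @export
root_height_cdf <- function(model) {
  st <- model$states
  ktot <- st[, "i"] + st[, "j"]
  pT <- ctmc_probs_at(model, model$T)
  pk <- vapply(2:model$n, function(k) sum(pT[ktot == k]), 0)
  pabsT <- sum(pT[ktot == 1L])
  force(model)
  function(q) vapply(q, function(t) {
    if (t < 0) return(0)
    if (t < model$T) {
      p <- ctmc_probs_at(model, t)
      sum(p[ktot == 1L])
    } else {
      s <- pabsT
      for (k in 2:model$n)
        if (pk[k - 1L] > 0)
          s <- s + pk[k - 1L] * phypoexp(t - model$T, anc_rates(k, model$nu_anc))
      s
    }
  }, 0)
}

#' One-sample Kolmogorov-Smirnov comparison against a reference CDF
#'
#' Thin wrapper around [stats::ks.test()] used throughout the validation
#' suite to compare empirical root-height samples with closed-form
#' distributions (and simulators with one another).
#'
#' @param sample numeric vector of empirical values (n >= 1).
#' @param cdf a vectorized distribution function.
#' @return List with `statistic` and `p.value`.
#' @export
ks_compare <- function(sample, cdf) {
  if (length(sample) == 0L) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(sample, cdf))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}
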