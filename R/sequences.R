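#' Simulate Jukes-Cantor sequences along a gene tree
#'
#' Evolves `length` independent nucleotide sites down the gene tree under
#' the Jukes-Cantor (JC69) model with a strict molecular clock: the root
#' state of each site is uniform on \{A, C, G, T\} and substitutions occur
#' at `rate` per site per time unit along every branch, so a branch of
#' time span \eqn{t} has expected substitutions \eqn{d = rate \times t}
#' and mismatch probability \eqn{(3/4)(1 - e^{-4d/3})}.  Simulation is
#' delegated to [phangorn::simSeq()].
#'
#' @param g a gene tree (`phylo`) with branch lengths in time units.
#' @param length number of sites (bp).
#' @param rate substitution rate per site per time unit.
#' @return A character matrix (class `"alignment_matrix"`) with one row
#'   per tip, columns the sites, entries in A/C/G/T.
#' @export
simulate_jc <- function(g, length, rate = 0.005) {
  stopifnot(inherits(g, "phylo"), length >= 1, rate > 0)
  sim <- phangorn::simSeq(g, l = length, rate = rate)
  m <- toupper(as.character(sim))
  rownames(m) <- names(sim)
  class(m) <- c("alignment_matrix", class(m))
  m
}

aln_matrix <- function(a) {
  stopifnot(is.matrix(a), !is.null(rownames(a)))
  a
}

#' Mean pairwise sequence identity
#'
#' Arithmetic mean over taxon pairs of the fraction of identical sites.
#'
#' @param a alignment matrix (rows = taxa, columns = sites).
#' @param pairs two-column matrix (or data frame) of taxon names; defaults
#'   to all unordered pairs.
#' @return Mean fraction of identical sites, in \[0, 1\].
#' @export
pairwise_identity <- function(a, pairs = NULL) {
  a <- aln_matrix(a)
  if (is.null(pairs)) {
    cmb <- utils::combn(rownames(a), 2L)
    pairs <- cbind(cmb[1L, ], cmb[2L, ])
  }
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L, nrow(pairs) >= 1L)
  if (!all(pairs %in% rownames(a))) stop("unknown taxon in pairs")
  id <- identity_matrix(a)
  mean(id[pairs])
}

# full taxon-by-taxon matrix of pairwise identical-site fractions
identity_matrix <- function(a) {
  a <- aln_matrix(a)
  n <- nrow(a); L <- ncol(a)
  S <- matrix(0, n, n, dimnames = list(rownames(a), rownames(a)))
  for (base in unique(as.vector(a))) {
    ind <- a == base
    S <- S + tcrossprod(ind + 0)
  }
  S / L
}

#' Sequence-level summary statistics
#'
#' Standard summaries of a simulated alignment: `segregating_sites()`
#' counts sites with two or more observed states; `haplotype_count()`
#' counts distinct sequences; `nucleotide_diversity()` is the mean
#' per-site difference over taxon pairs — overall, and, when a species
#' partition is supplied, split into within- and between-species pairs.
#'
#' @param a alignment matrix (rows = taxa, columns = sites).
#' @param partition optional character vector of species labels, named by
#'   taxon or in row order.
#' @return `segregating_sites` and `haplotype_count`: an integer.
#'   `nucleotide_diversity`: a named vector with `overall` and, given a
#'   partition, `within` and `between` components.
#' @export
segregating_sites <- function(a) {
  a <- aln_matrix(a)
  sum(apply(a, 2L, function(col) length(unique(col)) > 1L))
}

#' @rdname segregating_sites
#' @export
haplotype_count <- function(a) {
  a <- aln_matrix(a)
  length(unique(apply(a, 1L, paste0, collapse = "")))
}

#' @rdname segregating_sites
#' @export
nucleotide_diversity <- function(a, partition = NULL) {
  a <- aln_matrix(a)
  if (nrow(a) < 2L) stop("need at least two sequences")
  diff <- 1 - identity_matrix(a)
  ut <- upper.tri(diff)
  out <- c(overall = mean(diff[ut]))
  if (!is.null(partition)) {
    if (!is.null(names(partition))) partition <- partition[rownames(a)]
    stopifnot(length(partition) == nrow(a))
    same <- outer(partition, partition, `==`)
    out <- c(out, within = mean(diff[ut & same]),
             between = mean(diff[ut & !same]))
  }
  out
}

# all same-species and cross-species pair indices for an alignment whose
# taxa carry a species partition
partition_pairs <- function(taxa, partition) {
  cmb <- utils::combn(seq_along(taxa), 2L)
  same <- partition[cmb[1L, ]] == partition[cmb[2L, ]]
  list(within = cbind(taxa[cmb[1L, same]], taxa[cmb[2L, same]]),
       between = cbind(taxa[cmb[1L, !same]], taxa[cmb[2L, !same]]))
}
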