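#' Write a gene tree as newick, optionally with migration annotations
#'
#' In annotated mode each branch carrying migration events receives a
#' comment block `[&mig={time:from:to;...}]` after its branch length,
#' listing the backward-time jumps on that branch (species given as
#' species-tree branch ids, oldest event last).  Plain mode emits
#' standard newick via [ape::write.tree()] for downstream tools.
#'
#' @param g a gene tree.
#' @param file output path, or `NULL` to return the string.
#' @param annotations include migration comment blocks?
#' @return The newick string, invisibly when written to a file.
#' @export
write_gene_tree <- function(g, file = NULL, annotations = TRUE) {
  stopifnot(inherits(g, "phylo"))
  if (!annotations || is.null(g$migrations) || nrow(g$migrations) == 0L) {
    txt <- ape::write.tree(g)
  } else {
    n <- length(g$tip.label)
    h <- gene_tree_heights(g)
    kids <- vector("list", n + g$Nnode)
    for (k in seq_len(nrow(g$edge)))
      kids[[g$edge[k, 1L]]] <- c(kids[[g$edge[k, 1L]]], g$edge[k, 2L])
    ann <- function(v) {
      mg <- g$migrations[g$migrations$node == v, , drop = FALSE]
      if (nrow(mg) == 0L) return("")
      mg <- mg[order(mg$time), , drop = FALSE]
      paste0("[&mig={", paste(sprintf("%.10g:%d:%d", mg$time, mg$from, mg$to),
                              collapse = ";"), "}]")
    }
    parent <- integer(n + g$Nnode)
    parent[g$edge[, 2L]] <- g$edge[, 1L]
    bl <- function(v) sprintf(":%.10g", h[parent[v]] - h[v])
    rec <- function(v) {
      if (v <= n) return(paste0(g$tip.label[v], bl(v), ann(v)))
      inner <- paste(vapply(kids[[v]], rec, ""), collapse = ",")
      root <- v == n + 1L
      paste0("(", inner, ")", if (!root) paste0(bl(v), ann(v)))
    }
    txt <- paste0(rec(n + 1L), ";")
  }
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Write gene-tree events as a tab-separated log
#'
#' One row per event (coalescences and migrations), ordered by time, with
#' columns `time`, `type`, `species`/`from`, `to`.
#'
#' @param g a gene tree.
#' @param file output path, or `NULL` to return the data frame.
#' @export
write_event_log <- function(g, file = NULL) {
  stopifnot(inherits(g, "gene_tree"))
  n <- length(g$tip.label)
  h <- gene_tree_heights(g)
  ev <- data.frame(time = h[(n + 1L):(2L * n - 1L)], type = "coalescence",
                   from = NA_integer_, to = NA_integer_)
  if (nrow(g$migrations) > 0L)
    ev <- rbind(ev, data.frame(time = g$migrations$time, type = "migration",
                               from = g$migrations$from, to = g$migrations$to))
  ev <- ev[order(ev$time), ]
  rownames(ev) <- NULL
  if (is.null(file)) return(ev)
  utils::write.table(ev, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ev)
}

plf_to_json <- function(f) if (is.null(f)) NULL else Map(c, f$x, f$y)
plf_from_json <- function(p) {
  if (is.null(p)) return(NULL)
  m <- do.call(rbind, lapply(p, as.numeric))
  piecewise_linear(m[, 1L], m[, 2L])
}

# stable branch identity across serialization: the sorted tip-label set
# of the clade below the branch
st_clade_key <- function(st, v) {
  labs <- st_tip_labels(st)
  paste(sort(labs[st$clade_tips[[v]]]), collapse = "|")
}

#' Read and write species-tree configurations as JSON
#'
#' Serializes a decorated species tree to a JSON configuration: the
#' topology as a newick string, per-branch population functions as arrays
#' of `[time, value]` breakpoint pairs, and per-divergence migration
#' decorations with their support window.  Branches are keyed by the
#' tip-label set of their clade so that the mapping survives the node
#' renumbering of newick parsers.  Times are in model units (interpreted
#' as Myr in the examples).
#'
#' @param st a decorated [species_tree()].
#' @param file path to write to / read from.
#' @return `read_species_tree_json` returns a [species_tree()];
#'   `write_species_tree_json` returns `file` invisibly.
#' @export
write_species_tree_json <- function(st, file) {
  stopifnot(inherits(st, "species_tree"), !is.null(st$phy))
  keys <- vapply(seq_len(st$n_nodes), st_clade_key, "", st = st)
  cfg <- list(
    newick = ape::write.tree(st$phy),
    populations = stats::setNames(lapply(st$nu, plf_to_json), keys),
    migrations = lapply(which(!vapply(st$mig, is.null, logical(1L))),
                        function(v) {
                          d <- st$mig[[v]]
                          list(clade = keys[v], window = c(d$ts, d$td),
                               m12 = plf_to_json(d$m12), m21 = plf_to_json(d$m21))
                        }))
  jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname write_species_tree_json
#' @export
read_species_tree_json <- function(file) {
  cfg <- jsonlite::read_json(file)
  st <- species_tree(ape::read.tree(text = cfg$newick))
  keys <- vapply(seq_len(st$n_nodes), st_clade_key, "", st = st)
  for (v in seq_len(st$n_nodes)) {
    f <- plf_from_json(cfg$populations[[keys[v]]])
    if (!is.null(f)) st$nu[[v]] <- f
  }
  for (d in cfg$migrations) {
    v <- match(d$clade, keys)
    if (is.na(v)) stop("migration decoration refers to an unknown clade")
    st <- set_migration(st, v,
                        m12 = plf_from_json(d$m12), m21 = plf_from_json(d$m21),
                        window = as.numeric(unlist(d$window)))
  }
  st
}
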