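# Distance-based tree building from a supermatrix, outgroup rooting, and
# taxon decoration with monophyly testing. Neighbor joining and tree
# manipulation come from ape; the distances are computed here, gap-aware,
# directly from the supermatrix.

#' Pairwise distances from a supermatrix
#'
#' For each genome pair, `p` is the mismatch fraction over columns where
#' neither row has a gap; the Poisson correction is `d = -ln(1 - p)` with
#' `p` capped at 0.95.
#'
#' @param sm A `supermatrix`.
#' @param model `"poisson"` or `"p_distance"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(sm, model = c("poisson", "p_distance")) {
  stopifnot(inherits(sm, "supermatrix"))
  model <- match.arg(model)
  mat <- sm$matrix
  n <- nrow(mat)
  if (n < 4) stop("at least 4 genomes required", call. = FALSE)
  ids <- rownames(mat)
  nongap <- mat != GAP
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- nongap[i, ] & nongap[j, ]
      ns <- sum(shared)
      if (ns == 0) {
        stop(sprintf("genomes %s and %s share no aligned columns",
                     ids[i], ids[j]), call. = FALSE)
      }
      p <- sum(mat[i, shared] != mat[j, shared]) / ns
      d <- if (model == "poisson") -log(1 - min(p, 0.95)) else p
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining with negative branch lengths clamped to zero.
#' Input order does not affect the topology.
#'
#' @param distances Symmetric numeric matrix (>= 4 taxa).
#' @return Unrooted `phylo` tree.
#' @export
build_nj_tree <- function(distances) {
  stopifnot(is.matrix(distances), nrow(distances) >= 3)
  if (max(abs(distances - t(distances))) > 1e-9) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  tr <- ape::nj(as.dist(distances))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Root a tree with an outgroup
#'
#' Requires the outgroup to be separable by a single edge of the unrooted
#' tree; the root is placed at the midpoint of that edge, so the outgroup is
#' monophyletic in the rooted tree.
#'
#' @param tree Unrooted `phylo`.
#' @param outgroup Character vector of outgroup tip labels.
#' @return Rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) {
    stop("outgroup tips absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
    error = function(e) {
      stop("outgroup not monophyletic on unrooted tree", call. = FALSE)
    })
  nt <- length(rooted$tip.label)
  root_node <- nt + 1L
  kids <- which(rooted$edge[, 1] == root_node)
  if (length(kids) == 2) {
    tot <- sum(rooted$edge.length[kids])
    rooted$edge.length[kids] <- tot / 2
  }
  rooted
}

#' Decorate a tree with taxon labels and test monophyly
#'
#' For every named taxon at the requested ranks, finds the MRCA of its
#' genomes in the tree and flags the taxon monophyletic when the MRCA's leaf
#' set equals the taxon's genome set. Taxa with no genomes in the tree are
#' skipped and listed.
#'
#' @param tree Rooted `phylo` whose tips are genome ids.
#' @param taxonomy data.frame with genome_id, taxonomy.
#' @param ranks Ranks to decorate (default phylum through genus).
#' @return Object of class `decorated_tree`: `tree`, `taxa` (data.frame:
#'   taxon, rank, node, n_taxon, n_clade, monophyletic), `skipped`.
#' @export
decorate_tree <- function(tree, taxonomy,
                          ranks = c("phylum", "class", "order", "family",
                                    "genus")) {
  in_tree <- taxonomy$genome_id %in% tree$tip.label
  rows <- list(); skipped <- character(0)
  for (rk in ranks) {
    tx <- taxon_at_rank(taxonomy$taxonomy, rk)
    for (name in unique(tx[nzchar(tx)])) {
      members <- taxonomy$genome_id[tx == name]
      here <- intersect(members, tree$tip.label)
      if (length(here) == 0) {
        skipped <- c(skipped, sprintf("%s (%s)", name, rk))
        next
      }
      if (length(here) == 1) {
        node <- match(here, tree$tip.label)
        clade <- here
      } else {
        node <- ape::getMRCA(tree, here)
        clade <- ape::extract.clade(tree, node)$tip.label
      }
      rows[[length(rows) + 1]] <- data.frame(
        taxon = name, rank = rk, node = node,
        n_taxon = length(here), n_clade = length(clade),
        monophyletic = setequal(clade, here),
        stringsAsFactors = FALSE)
    }
  }
  taxa <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(taxon = character(0), rank = character(0), node = integer(0),
               n_taxon = integer(0), n_clade = integer(0),
               monophyletic = logical(0))
  }
  rownames(taxa) <- NULL
  out <- list(tree = tree, taxa = taxa, skipped = skipped)
  class(out) <- "decorated_tree"
  out
}

#' @export
print.decorated_tree <- function(x, ...) {
  cat(sprintf("decorated tree: %d tips, %d labeled taxa (%d monophyletic)\n",
              length(x$tree$tip.label), nrow(x$taxa),
              sum(x$taxa$monophyletic)))
  invisible(x)
}
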