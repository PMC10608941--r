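# Relative evolutionary divergence (RED) and rank-interval modelling.
#
# RED normalizes node depth to [0,1] between the root (0) and the extant
# leaves (1): for a node n with parent RED P, branch length a to its parent
# and mean distance b from n to its descendant leaves,
#
#     RED(n) = P + (a / (a + b)) * (1 - P)
#
# with the continuity convention RED(n) = P when a + b = 0. Per-rank medians
# of RED over rank-labeled nodes, with a fixed interval half-width, turn a
# node's RED into a rank assignment; comparing assigned against labeled
# ranks yields reclassification proposals (the logic that demotes a
# phylum-labeled lineage sitting at class depth).

#' Compute RED values on a rooted tree
#'
#' One postorder sweep collects mean node-to-leaf distances, one preorder
#' sweep applies the recursion. Leaves get exactly 1, the root exactly 0,
#' and values are invariant under global scaling of branch lengths.
#'
#' @param tree Rooted `phylo` with non-negative branch lengths.
#' @return Object of class `red_table`: data.frame with node (ape
#'   numbering), label (tip label or node label), type, and red.
#' @export
compute_red <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo'", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths",
                                      call. = FALSE)
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0",
                                      call. = FALSE)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  b <- mean_leaf_depths(tree)
  red <- rep(NA_real_, nn)
  red[nt + 1L] <- 0
  cw <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (i in seq_len(nrow(cw$edge))) {
    p <- cw$edge[i, 1]; ch <- cw$edge[i, 2]
    a <- cw$edge.length[i]
    P <- red[p]
    red[ch] <- if (a + b[ch] == 0) P else P + (a / (a + b[ch])) * (1 - P)
  }
  red[seq_len(nt)] <- ifelse(is.na(red[seq_len(nt)]), 1, red[seq_len(nt)])
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label else
                rep("", tree$Nnode))
  out <- data.frame(node = seq_len(nn), label = labels,
                    type = rep(c("leaf", "internal"), c(nt, tree$Nnode)),
                    red = red, stringsAsFactors = FALSE)
  class(out) <- c("red_table", "data.frame")
  out
}

#' @export
print.red_table <- function(x, ...) {
  cat(sprintf("RED table: %d nodes (root 0, %d leaves at 1)\n",
              nrow(x), sum(x$type == "leaf")))
  print.data.frame(utils::head(x[x$type == "internal", ], 10))
  invisible(x)
}

#' Fit a per-rank RED interval model
#'
#' The model is the median RED of the labeled nodes of each rank, with a
#' common interval half-width. Ranks without labels are omitted; a
#' non-monotone median sequence triggers a warning but the model is still
#' returned.
#'
#' @param red A `red_table` from [compute_red()].
#' @param labeled_nodes data.frame with columns node and rank.
#' @param w Interval half-width (> 0).
#' @return Object of class `rank_model`: `medians` (named, in canonical
#'   rank order), `w`, `n_per_rank`.
#' @export
fit_rank_model <- function(red, labeled_nodes, w = 0.1) {
  stopifnot(inherits(red, "red_table"), w > 0)
  if (nrow(labeled_nodes) == 0) stop("empty label set", call. = FALSE)
  if (!all(labeled_nodes$node %in% red$node)) {
    stop("labeled node missing from RED table", call. = FALSE)
  }
  vals <- red$red[match(labeled_nodes$node, red$node)]
  med <- vapply(split(vals, labeled_nodes$rank), stats::median, numeric(1))
  n <- vapply(split(vals, labeled_nodes$rank), length, integer(1))
  ord <- order(match(names(med), RANKS7))
  med <- med[ord]; n <- n[ord]
  if (is.unsorted(med, strictly = TRUE)) {
    warning("rank medians are not strictly increasing from shallow to deep rank")
  }
  out <- list(medians = med, w = w, n_per_rank = n)
  class(out) <- "rank_model"
  out
}

#' @export
print.rank_model <- function(x, ...) {
  cat(sprintf("RED rank model (half-width %.3f):\n", x$w))
  for (r in names(x$medians)) {
    cat(sprintf("  %-8s median %.4f  [%.4f, %.4f]  (n=%d)\n", r,
                x$medians[[r]], x$medians[[r]] - x$w, x$medians[[r]] + x$w,
                x$n_per_rank[[r]]))
  }
  invisible(x)
}

#' Assign ranks to RED values
#'
#' Each value is tested against every rank's interval
#' `[median - w, median + w]`; among containing ranks the nearest median
#' wins, with ties resolved to the shallower rank. A value contained in no
#' interval is assigned the overall nearest median (flagged `in_interval =
#' FALSE`).
#'
#' @param node_red Numeric vector of RED values.
#' @param model A `rank_model`.
#' @return data.frame: red, assigned_rank, in_interval, plus one logical
#'   `in_<rank>` column per modeled rank.
#' @export
assign_rank <- function(node_red, model) {
  stopifnot(inherits(model, "rank_model"), length(model$medians) >= 1)
  med <- model$medians; w <- model$w
  res <- lapply(node_red, function(v) {
    dist <- abs(v - med)
    inside <- dist <= w
    pool <- if (any(inside)) which(inside) else seq_along(med)
    best <- pool[order(dist[pool], pool)][1]  # tie -> shallower rank
    c(list(red = v, assigned_rank = names(med)[best],
           in_interval = any(inside)),
      stats::setNames(as.list(inside), paste0("in_", names(med))))
  })
  out <- do.call(rbind, lapply(res, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
predict.rank_model <- function(object, newdata, ...) {
  assign_rank(newdata, object)
}

#' Propose reclassifications from labeled versus assigned ranks
#'
#' For every rank-labeled node, compares the label against the RED-based
#' assignment; mismatches carry a demotion (assigned rank deeper than
#' labeled) or promotion proposal.
#'
#' @param red A `red_table`.
#' @param labeled_nodes data.frame with node, rank, and optionally taxon.
#' @param model A `rank_model`.
#' @return data.frame sorted by taxon: taxon, labeled_rank, red,
#'   assigned_rank, in_interval, proposal (empty when consistent).
#' @export
evaluate_reclassification <- function(red, labeled_nodes, model) {
  stopifnot(inherits(red, "red_table"), inherits(model, "rank_model"))
  if (!all(labeled_nodes$node %in% red$node)) {
    stop("internal consistency error: labeled node without RED value",
         call. = FALSE)
  }
  vals <- red$red[match(labeled_nodes$node, red$node)]
  asg <- assign_rank(vals, model)
  taxon <- if ("taxon" %in% names(labeled_nodes)) labeled_nodes$taxon else {
    sprintf("node_%d", labeled_nodes$node)
  }
  li <- match(labeled_nodes$rank, RANKS7)
  ai <- match(asg$assigned_rank, RANKS7)
  proposal <- ifelse(li == ai, "",
                     ifelse(ai > li,
                            sprintf("demote to %s", asg$assigned_rank),
                            sprintf("promote to %s", asg$assigned_rank)))
  out <- data.frame(taxon = taxon, labeled_rank = labeled_nodes$rank,
                    node = labeled_nodes$node, red = vals,
                    assigned_rank = asg$assigned_rank,
                    in_interval = asg$in_interval,
                    proposal = proposal, stringsAsFactors = FALSE)
  out <- out[order(out$taxon), ]
  rownames(out) <- NULL
  out
}

#' Strict RED threshold flags for named lineages
#'
#' @param red_values Named numeric vector of lineage RED values.
#' @param threshold Threshold in (0,1).
#' @param direction `"above"` flags values strictly greater than the
#'   threshold; `"below"` strictly smaller.
#' @return Named logical vector.
#' @export
red_threshold_flags <- function(red_values, threshold,
                                direction = c("above", "below")) {
  stopifnot(threshold > 0, threshold < 1)
  direction <- match.arg(direction)
  if (direction == "above") red_values > threshold else red_values < threshold
}
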