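# GTDB-style taxonomy strings, per-rank representative selection, and
# balanced taxon down-sampling (3 + 0.2 * (n - 3), taxa of three or fewer
# genomes kept whole).

#' Parse a GTDB-style seven-rank taxonomy string
#'
#' Strings have seven semicolon-separated `prefix__name` fields with the
#' canonical prefixes d, p, c, o, f, g, s. Empty names are allowed, but no
#' rank may be named below an empty parent rank.
#'
#' @param s A taxonomy string.
#' @return Object of class `taxonomy`: named character vector of rank names
#'   (possibly empty strings).
#' @export
parse_taxonomy <- function(s) {
  if (!is.character(s) || length(s) != 1 || !nzchar(s)) {
    stop("taxonomy string must be a single non-empty string", call. = FALSE)
  }
  fields <- strsplit(s, ";", fixed = TRUE)[[1]]
  if (length(fields) != 7) {
    stop(sprintf("expected 7 rank fields, found %d", length(fields)),
         call. = FALSE)
  }
  want <- names(RANK_PREFIXES)
  names_out <- character(7)
  for (i in seq_len(7)) {
    f <- fields[i]
    if (!startsWith(f, paste0(want[i], "__"))) {
      stop(sprintf("field %d ('%s') must start with '%s__' (prefix order d,p,c,o,f,g,s)",
                   i, f, want[i]), call. = FALSE)
    }
    names_out[i] <- substring(f, 4)
  }
  empty_seen <- FALSE
  for (i in 2:7) {  # domain may be empty without constraining children
    if (!nzchar(names_out[i]) ) empty_seen <- TRUE
    else if (empty_seen) {
      stop(sprintf("rank '%s' is named below an empty parent rank",
                   RANKS7[i]), call. = FALSE)
    }
  }
  out <- stats::setNames(names_out, RANKS7)
  class(out) <- "taxonomy"
  out
}

#' Format a parsed taxonomy back to its string form
#'
#' @param x A `taxonomy` object.
#' @param ... Ignored.
#' @return The canonical string; `format(parse_taxonomy(s)) == s` for all
#'   valid `s`.
#' @export
format.taxonomy <- function(x, ...) {
  paste(paste0(names(RANK_PREFIXES), "__", unclass(x)), collapse = ";")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Name of a taxon at a given rank across many genomes
#'
#' @param taxonomies Character vector of taxonomy strings.
#' @param rank One of the seven ranks.
#' @return Character vector of names at that rank (empty string when
#'   unnamed).
#' @export
taxon_at_rank <- function(taxonomies, rank) {
  rank <- match.arg(rank, RANKS7)
  i <- match(rank, RANKS7)
  vapply(taxonomies, function(s) unclass(parse_taxonomy(s))[i], character(1),
         USE.NAMES = FALSE)
}

#' One representative genome per taxon at a rank
#'
#' For each distinct taxon name at the requested rank, keeps the
#' highest-quality genome (dereplication score: completeness minus five
#' times contamination; ties break lexicographically by id). Genomes with
#' an empty name at the rank form per-genome placeholder taxa and are all
#' kept.
#'
#' @param taxonomy data.frame with genome_id and taxonomy columns.
#' @param rank One of the seven ranks.
#' @param qualities data.frame with genome_id, weighted_completeness,
#'   contamination_pc.
#' @return data.frame: taxon, genome_id (the representative).
#' @export
rank_representatives <- function(taxonomy, rank, qualities) {
  rank <- match.arg(rank, RANKS7)
  taxon <- taxon_at_rank(taxonomy$taxonomy, rank)
  placeholder <- !nzchar(taxon)
  taxon[placeholder] <- paste0("<unnamed:", taxonomy$genome_id[placeholder], ">")
  q <- qualities[match(taxonomy$genome_id, qualities$genome_id), ]
  score <- derep_score(q$weighted_completeness, q$contamination_pc)
  keep <- vapply(split(seq_along(taxon), taxon), function(idx) {
    ord <- order(-score[idx], taxonomy$genome_id[idx])
    idx[ord[1]]
  }, integer(1))
  out <- data.frame(taxon = names(keep),
                    genome_id = taxonomy$genome_id[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$taxon), ]
}

#' Balanced down-sampling size for a taxon
#'
#' Taxa with three or fewer genomes are not reduced; larger taxa are reduced
#' to `3 + 0.2 * (n - 3)` genomes, rounded half-up.
#'
#' @param n Integer vector of genome counts (>= 0).
#' @return Integer vector of kept counts.
#' @export
downsample_size <- function(n) {
  if (any(n < 0)) stop("counts must be >= 0", call. = FALSE)
  as.integer(ifelse(n <= 3, n, pmin(n, round_half_up(3 + 0.2 * (n - 3)))))
}

#' Balanced down-sampling of over-represented taxa
#'
#' Groups genomes by their taxon at `rank` and keeps, per taxon, the number
#' of genomes given by [downsample_size()], chosen as the top-quality ones
#' (quality ties broken by a seeded uniform draw).
#'
#' @param taxonomy data.frame with genome_id and taxonomy columns.
#' @param rank Grouping rank.
#' @param qualities data.frame with genome_id, weighted_completeness,
#'   contamination_pc.
#' @param seed Integer seed for tie-breaking.
#' @return Character vector of kept genome ids.
#' @export
balanced_downsample <- function(taxonomy, rank, qualities, seed = 1L) {
  rank <- match.arg(rank, RANKS7)
  taxon <- taxon_at_rank(taxonomy$taxonomy, rank)
  placeholder <- !nzchar(taxon)
  taxon[placeholder] <- paste0("<unnamed:", taxonomy$genome_id[placeholder], ">")
  q <- qualities[match(taxonomy$genome_id, qualities$genome_id), ]
  score <- derep_score(q$weighted_completeness, q$contamination_pc)
  with_seed(seed, {
    jitter <- stats::runif(length(score))
    kept <- lapply(split(seq_along(taxon), taxon), function(idx) {
      k <- downsample_size(length(idx))
      ord <- order(-score[idx], jitter[idx])
      taxonomy$genome_id[idx[ord[seq_len(k)]]]
    })
    sort(unlist(kept, use.names = FALSE))
  })
}
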