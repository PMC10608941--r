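# Marker-gene selection and supermatrix construction: score-cutoff hit
# selection, fragmented-marker merging, presence-based marker/genome
# filtering, star alignment, gap trimming, concatenation with partition
# tracking, and the rpoB alignment-fraction guard.

GAP <- "-"

#' Select marker hits by the TC/NC-average cutoff
#'
#' A hit is accepted when its bit score reaches the average of the model's
#' trusted and noise cutoffs; among accepted hits for the same genome and
#' marker, the highest score wins (ties keep the first in input order).
#'
#' @param hits data.frame with columns genome_id, marker_id, score, tc, nc.
#' @return The accepted subset, one row per genome x marker.
#' @export
select_hits <- function(hits) {
  need <- c("genome_id", "marker_id", "score", "tc", "nc")
  if (!all(need %in% names(hits))) {
    stop("hits must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(hits$tc) || anyNA(hits$nc)) {
    stop("missing TC/NC cutoff values", call. = FALSE)
  }
  acc <- hits[hits$score >= (hits$tc + hits$nc) / 2, , drop = FALSE]
  if (nrow(acc) == 0) return(acc)
  key <- paste(acc$genome_id, acc$marker_id, sep = "\r")
  ord <- order(key, -acc$score)  # stable: preserves input order within ties
  acc <- acc[ord, , drop = FALSE]
  acc <- acc[!duplicated(paste(acc$genome_id, acc$marker_id, sep = "\r")), ,
             drop = FALSE]
  rownames(acc) <- NULL
  acc
}

#' Merge a fragmented marker from its part models
#'
#' Some markers are modeled in parts (e.g., a three-model rpoC set for
#' lineages with a split gene). Present parts are concatenated in declared
#' order and absent parts are gap-filled to their expected length, so the
#' merged marker has a fixed total length.
#'
#' @param parts Named character vector: sequences per part model, in
#'   declared order; `NA` for absent parts.
#' @param part_lengths Named integer vector of expected part lengths (used
#'   to gap-fill absences).
#' @return The merged sequence, or `NA_character_` when no part was found.
#' @export
merge_fragmented_marker <- function(parts, part_lengths) {
  stopifnot(!is.null(names(parts)), !is.null(names(part_lengths)))
  if (!all(names(parts) %in% names(part_lengths))) {
    stop("every part needs an expected length", call. = FALSE)
  }
  if (all(is.na(parts))) return(NA_character_)
  pieces <- vapply(names(parts), function(p) {
    if (is.na(parts[[p]])) {
      strrep(GAP, part_lengths[[p]])
    } else parts[[p]]
  }, character(1))
  paste(pieces, collapse = "")
}

#' Default fragment map (rpoC-style three-model marker)
#'
#' @return Named list: logical marker id -> ordered part model ids.
#' @export
default_fragment_map <- function() {
  list(rpoC = c("TIGR02387", "TIGR02388", "TIGR02386"))
}

#' Apply a fragment map to an accepted-hit presence table
#'
#' Replaces the part models of each logical marker with the merged marker in
#' a genome x marker sequence table.
#'
#' @param seq_table Named list marker_id -> named character vector
#'   (genome -> sequence).
#' @param fragment_map Named list from [default_fragment_map()] style
#'   configuration.
#' @param part_lengths Named integer vector of part lengths.
#' @return The sequence table with part markers replaced by merged markers.
#' @export
apply_fragment_map <- function(seq_table, fragment_map, part_lengths) {
  all_parts <- unlist(fragment_map)
  if (anyDuplicated(all_parts)) {
    stop("a part model is assigned to two logical markers", call. = FALSE)
  }
  for (lm in names(fragment_map)) {
    parts <- fragment_map[[lm]]
    found <- intersect(parts, names(seq_table))
    if (length(found) == 0) next
    genomes <- unique(unlist(lapply(seq_table[found], names)))
    merged <- vapply(genomes, function(g) {
      pv <- stats::setNames(vapply(parts, function(p) {
        s <- seq_table[[p]][g]
        if (is.null(s) || is.na(s)) NA_character_ else unname(s)
      }, character(1)), parts)
      merge_fragmented_marker(pv, part_lengths)
    }, character(1))
    merged <- merged[!is.na(merged)]
    seq_table[found] <- NULL
    seq_table[[lm]] <- merged
  }
  seq_table
}

#' Filter markers and genomes by mutual presence
#'
#' Iterates to a fixed point: drop markers present in fewer than
#' `min_genome_fraction` of the retained genomes, then genomes carrying
#' fewer than `min_marker_fraction` of the retained markers.
#'
#' @param presence Logical matrix, genomes x markers.
#' @param min_genome_fraction Minimum fraction of genomes a marker must
#'   cover.
#' @param min_marker_fraction Minimum fraction of markers a genome must
#'   carry.
#' @return List: `genomes`, `markers` (retained names).
#' @export
filter_matrix <- function(presence, min_genome_fraction = 0.9,
                          min_marker_fraction = 0.5) {
  stopifnot(is.matrix(presence), is.logical(presence))
  if (nrow(presence) == 0 || ncol(presence) == 0) {
    stop("presence matrix is empty", call. = FALSE)
  }
  g <- rownames(presence); m <- colnames(presence)
  repeat {
    sub <- presence[g, m, drop = FALSE]
    keep_m <- m[colMeans(sub) >= min_genome_fraction]
    sub <- presence[g, keep_m, drop = FALSE]
    keep_g <- if (length(keep_m)) g[rowMeans(sub) >= min_marker_fraction] else character(0)
    if (identical(keep_g, g) && identical(keep_m, m)) break
    g <- keep_g; m <- keep_m
    if (length(g) == 0 || length(m) == 0) {
      stop("empty selection: every genome or marker was filtered out",
           call. = FALSE)
    }
  }
  list(genomes = g, markers = m)
}

# Global Needleman-Wunsch alignment (match +1, mismatch -1, gap -2),
# returning the two gapped strings. Used only by the star aligner.
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(y == x[i], match, mismatch)
    prev <- S[i, ]
    cur <- numeric(m + 1)
    cur[1] <- gap * i
    for (j in seq_len(m)) {
      cur[j + 1] <- max(prev[j] + sub[j], prev[j + 1] + gap, cur[j] + gap)
    }
    S[i + 1, ] <- cur
  }
  ai <- character(0); bi <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(x[i] == y[j], match, mismatch)) {
      ai <- c(x[i], ai); bi <- c(y[j], bi); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ai <- c(x[i], ai); bi <- c(GAP, bi); i <- i - 1
    } else {
      ai <- c(GAP, ai); bi <- c(y[j], bi); j <- j - 1
    }
  }
  c(paste(ai, collapse = ""), paste(bi, collapse = ""))
}

#' Align the sequences of one marker
#'
#' Equal-length inputs pass through unchanged (the no-indel case). Otherwise
#' a star alignment is built: every sequence is globally aligned to the
#' longest one (match +1, mismatch -1, gap -2) and gaps opened in the center
#' are projected into all previously aligned sequences.
#'
#' @param seqs Named character vector (>= 2 sequences, none empty).
#' @return Named character vector of equal-length aligned sequences.
#' @export
align_marker <- function(seqs) {
  if (length(seqs) < 2) stop("at least 2 sequences required", call. = FALSE)
  if (any(nchar(seqs) == 0)) stop("empty sequence", call. = FALSE)
  if (length(unique(nchar(seqs))) == 1) return(seqs)
  center_i <- which.max(nchar(seqs))
  C <- seqs[[center_i]]
  n <- nchar(C)
  others <- setdiff(seq_along(seqs), center_i)
  pair_aln <- lapply(others, function(i) nw_align(C, seqs[[i]]))
  # per pairwise alignment: gaps opened in the center, counted per slot
  # (slot p = between center residues p and p+1; slot 0 = before residue 1)
  slot_gaps <- lapply(pair_aln, function(pa) {
    cc <- strsplit(pa[1], "", fixed = TRUE)[[1]]
    g <- integer(n + 1); p <- 0
    for (ch in cc) {
      if (ch == GAP) g[p + 1] <- g[p + 1] + 1 else p <- p + 1
    }
    g
  })
  gmax <- Reduce(pmax, slot_gaps)
  width <- n + sum(gmax)
  cpos <- cumsum(gmax[1:n]) + seq_len(n)  # merged column of center residue p
  rows <- character(length(seqs))
  ctr <- rep(GAP, width)
  ctr[cpos] <- strsplit(C, "", fixed = TRUE)[[1]]
  rows[center_i] <- paste(ctr, collapse = "")
  for (idx in seq_along(others)) {
    pa <- pair_aln[[idx]]
    cc <- strsplit(pa[1], "", fixed = TRUE)[[1]]
    ss <- strsplit(pa[2], "", fixed = TRUE)[[1]]
    out <- rep(GAP, width)
    p <- 0; used <- 0
    for (j in seq_along(cc)) {
      if (cc[j] == GAP) {
        used <- used + 1
        out[(if (p == 0) 0 else cpos[p]) + used] <- ss[j]
      } else {
        p <- p + 1; used <- 0
        out[cpos[p]] <- ss[j]
      }
    }
    rows[others[idx]] <- paste(out, collapse = "")
  }
  stats::setNames(rows, names(seqs))
}

#' Trim gap-rich alignment columns
#'
#' Removes columns whose gap fraction exceeds `max_gap_fraction` and returns
#' the kept-column index map for partition bookkeeping.
#'
#' @param aln Named character vector of equal-length sequences.
#' @param max_gap_fraction Maximum tolerated per-column gap fraction.
#' @return List: `alignment` (trimmed sequences), `kept_columns` (indices
#'   into the input columns).
#' @export
trim_alignment <- function(aln, max_gap_fraction = 0.5) {
  lens <- unique(nchar(aln))
  if (length(lens) != 1) stop("alignment is not rectangular", call. = FALSE)
  mat <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  gap_frac <- colMeans(mat == GAP)
  keep <- which(gap_frac <= max_gap_fraction)
  if (length(keep) == 0) stop("all columns removed by trimming", call. = FALSE)
  trimmed <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  list(alignment = stats::setNames(trimmed, names(aln)), kept_columns = keep)
}

#' Concatenate marker alignments into a supermatrix
#'
#' Markers are laid out in the declared order of `alignments`; genomes
#' missing a marker receive an all-gap block. The partition map records each
#' marker's half-open, 0-based column interval.
#'
#' @param alignments Named list: marker_id -> named character vector of
#'   aligned sequences.
#' @param genomes Genome universe (row order); defaults to the union of
#'   genomes over markers, sorted.
#' @return Object of class `supermatrix`: `matrix` (character matrix,
#'   genomes x columns), `partition` (data.frame marker, start, end),
#'   `missing` (logical genome x marker matrix).
#' @export
concatenate_markers <- function(alignments, genomes = NULL) {
  stopifnot(length(alignments) >= 1, !is.null(names(alignments)))
  for (m in names(alignments)) {
    if (anyDuplicated(names(alignments[[m]]))) {
      stop(sprintf("duplicate genome id within marker %s", m), call. = FALSE)
    }
    if (length(unique(nchar(alignments[[m]]))) != 1) {
      stop(sprintf("marker %s is not rectangular", m), call. = FALSE)
    }
  }
  if (is.null(genomes)) {
    genomes <- sort(unique(unlist(lapply(alignments, names))))
  }
  widths <- vapply(alignments, function(a) nchar(a[[1]]), numeric(1))
  ends <- cumsum(widths)
  starts <- c(0, utils::head(ends, -1))
  total <- sum(widths)
  mat <- matrix(GAP, nrow = length(genomes), ncol = total,
                dimnames = list(genomes, NULL))
  missing <- matrix(TRUE, nrow = length(genomes), ncol = length(alignments),
                    dimnames = list(genomes, names(alignments)))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    present <- intersect(genomes, names(a))
    if (length(present)) {
      block <- do.call(rbind, strsplit(a[present], "", fixed = TRUE))
      mat[present, (starts[i] + 1):ends[i]] <- block
      missing[present, i] <- FALSE
    }
  }
  out <- list(matrix = mat,
              partition = data.frame(marker = names(alignments),
                                     start = starts, end = ends,
                                     stringsAsFactors = FALSE),
              missing = missing)
  class(out) <- "supermatrix"
  out
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d genomes x %d columns, %d markers\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$partition)))
  invisible(x)
}

#' @export
dim.supermatrix <- function(x) dim(x$matrix)

#' Fraction of supermatrix columns derived from rpoB
#'
#' Trees built on alignments dominated by the single gene rpoB can show
#' clades unsupported by multi-gene data, so alignments with more than 20%
#' rpoB-derived columns are flagged.
#'
#' @param sm A `supermatrix`.
#' @param rpob_marker_ids Marker ids counted as rpoB.
#' @param max_fraction Warning threshold (strictly above flags).
#' @return List: `fraction`, `warn`.
#' @export
rpob_fraction_check <- function(sm, rpob_marker_ids, max_fraction = 0.20) {
  stopifnot(inherits(sm, "supermatrix"))
  unknown <- setdiff(rpob_marker_ids, sm$partition$marker)
  if (length(unknown)) {
    stop("unknown marker id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- sm$partition[sm$partition$marker %in% rpob_marker_ids, , drop = FALSE]
  frac <- sum(p$end - p$start) / ncol(sm$matrix)
  list(fraction = frac, warn = frac > max_fraction)
}

#' Write a supermatrix as FASTA plus a partition table
#'
#' @param sm A `supermatrix`.
#' @param fasta_path,partition_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_supermatrix <- function(sm, fasta_path, partition_path) {
  stopifnot(inherits(sm, "supermatrix"))
  seqs <- apply(sm$matrix, 1, paste, collapse = "")
  write_fasta(stats::setNames(seqs, rownames(sm$matrix)), fasta_path)
  write_tsv(sm$partition, partition_path)
  invisible(c(fasta_path, partition_path))
}
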