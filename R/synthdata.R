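# Synthetic genome collections with known ground truth.
#
# The simulator produces everything the downstream stages consume: a rooted,
# rank-labeled species tree, trivially-aligned amino-acid marker sequences
# evolved along it, nucleotide genomes with planted species clusters at
# controlled pairwise divergence, and degraded MAGs with injected
# incompleteness/contamination plus the truth tables that record all of it.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA_ALPHABET <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with validation.
#' Defaults describe the standard study conditions used throughout the
#' package's tests: 20 ingroup species (3 MAGs each) plus a 4-species
#' outgroup clade, 20 markers of 120 residues, 100 kb genomes, within-species
#' divergence well inside the 99% ANI boundary and between-species divergence
#' well outside the 90% boundary.
#'
#' @param n_taxa Number of ingroup species (tree leaves); at least 4.
#' @param n_outgroup Number of outgroup species (0 disables the outgroup
#'   clade; outgroup leaves are named `og*` and carry no rank labels).
#' @param n_markers Number of marker genes.
#' @param marker_len Marker length in residues (>= 10).
#' @param genome_len Genome length in bp (>= 50,000 so sketching works).
#' @param subst_rate_per_branch Expected substitutions per site per unit
#'   branch length for marker evolution.
#' @param rank_depths Named numeric, relative depths in (0,1) at which ranks
#'   are planted; must be strictly increasing from phylum towards genus.
#' @param genomes_per_species MAGs generated per ingroup species.
#' @param within_divergence Per-genome per-site divergence from its species
#'   reference (pairwise within-species divergence is about twice this).
#' @param between_divergence Per-species per-site divergence from the root
#'   genome (pairwise between-species divergence is about twice this).
#' @param frac_low_quality Fraction of MAGs drawn with low completeness.
#' @param completeness_range,low_completeness_range Uniform ranges for the
#'   retained fraction of a genome in ordinary and low-quality MAGs.
#' @param contamination_range,high_contamination_range Uniform ranges for the
#'   injected contaminant fraction in ordinary and heavily contaminated MAGs.
#' @param frac_contaminated Fraction of MAGs drawn with heavy contamination.
#' @param frac_public Fraction of MAGs labeled `public` (rest `novel`).
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 20L, n_outgroup = 4L, n_markers = 20L,
                       marker_len = 120L, genome_len = 100000L,
                       subst_rate_per_branch = 0.5,
                       rank_depths = c(phylum = 0.15, class = 0.35,
                                       order = 0.55, family = 0.75,
                                       genus = 0.9),
                       genomes_per_species = 3L,
                       within_divergence = 0.004,
                       between_divergence = 0.065,
                       frac_low_quality = 0.15,
                       completeness_range = c(0.7, 1),
                       low_completeness_range = c(0.3, 0.5),
                       contamination_range = c(0, 0.04),
                       high_contamination_range = c(0.12, 0.25),
                       frac_contaminated = 0.1,
                       frac_public = 0.5,
                       seed = 1L) {
  if (n_taxa < 4) stop("n_taxa must be >= 4", call. = FALSE)
  if (marker_len < 10) stop("marker_len must be >= 10", call. = FALSE)
  if (genome_len < 50000) {
    stop("genome_len must be >= 50,000 bp to support sketching", call. = FALSE)
  }
  if (subst_rate_per_branch < 0) stop("subst_rate_per_branch must be >= 0",
                                      call. = FALSE)
  if (is.null(names(rank_depths)) || any(!names(rank_depths) %in% RANKS7)) {
    stop("rank_depths must be named with taxonomic ranks", call. = FALSE)
  }
  ord <- match(names(rank_depths), RANKS7)
  if (is.unsorted(ord, strictly = TRUE)) {
    stop("rank_depths must be ordered from shallow to deep rank", call. = FALSE)
  }
  if (any(rank_depths <= 0) || any(rank_depths >= 1) ||
      is.unsorted(rank_depths, strictly = TRUE)) {
    stop("rank_depths must be strictly increasing within (0,1)", call. = FALSE)
  }
  cfg <- list(n_taxa = as.integer(n_taxa), n_outgroup = as.integer(n_outgroup),
              n_markers = as.integer(n_markers),
              marker_len = as.integer(marker_len),
              genome_len = as.integer(genome_len),
              subst_rate_per_branch = subst_rate_per_branch,
              rank_depths = rank_depths,
              genomes_per_species = as.integer(genomes_per_species),
              within_divergence = within_divergence,
              between_divergence = between_divergence,
              frac_low_quality = frac_low_quality,
              completeness_range = completeness_range,
              low_completeness_range = low_completeness_range,
              contamination_range = contamination_range,
              high_contamination_range = high_contamination_range,
              frac_contaminated = frac_contaminated,
              frac_public = frac_public,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  species: %d ingroup + %d outgroup; %d MAGs/species\n",
              x$n_taxa, x$n_outgroup, x$genomes_per_species))
  cat(sprintf("  markers: %d x %d residues; genomes: %d bp\n",
              x$n_markers, x$marker_len, x$genome_len))
  cat(sprintf("  rank depths: %s\n",
              paste(sprintf("%s=%.2f", names(x$rank_depths), x$rank_depths),
                    collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Mean distance from every node to its descendant leaves (0 at tips),
# computed in one postorder sweep.
mean_leaf_depths <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  nl <- c(rep(1, nt), rep(0, nn - nt))
  s <- numeric(nn)
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    nl[p] <- nl[p] + nl[ch]
    s[p] <- s[p] + s[ch] + nl[ch] * po$edge.length[i]
  }
  s / pmax(nl, 1)
}

# Relative depth in [0,1] used for rank planting: the package's RED measure
# (root 0, leaves 1, monotone along root-to-leaf paths).
relative_depths <- function(tree) {
  compute_red(tree)$red
}

#' Simulate a rank-labeled rooted species tree
#'
#' Generates a rooted binary tree with branch lengths drawn uniformly on
#' \[0.05, 1\] (the floor keeps every internal edge phylogenetically
#' resolvable). When the configuration requests an outgroup, a separate
#' outgroup clade is attached at the root on a lengthened stem. Every
#' ingroup internal node below the root is labeled with the rank whose
#' configured relative depth is nearest the node's own relative evolutionary
#' depth (RED), so planted ranks nest monotonically along every path.
#'
#' @param config A [sim_config()].
#' @return A `phylo` object with extra components: `rank_table`
#'   (data.frame: node, rank, rel_depth), `ingroup` and `outgroup`
#'   (tip label vectors).
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    ing <- ape::rtree(config$n_taxa, rooted = TRUE,
                      br = function(n) stats::runif(n, 0.05, 1))
    ing$tip.label <- sprintf("sp%03d", seq_len(config$n_taxa))
    if (config$n_outgroup > 0) {
      if (config$n_outgroup == 1L) {
        og_nwk <- "og001:0"
      } else {
        og <- ape::rtree(config$n_outgroup, rooted = TRUE,
                         br = function(n) stats::runif(n, 0.05, 1))
        og$tip.label <- sprintf("og%03d", seq_len(config$n_outgroup))
        og_nwk <- sub(";$", "", ape::write.tree(og))
      }
      stems <- stats::runif(2, 0.05, 1)
      nwk <- sprintf("(%s:%.8f,%s:%.8f);",
                     sub(";$", "", ape::write.tree(ing)), stems[1],
                     og_nwk, stems[2] + 1)
      tree <- ape::read.tree(text = nwk)
    } else {
      tree <- ing
    }
    tree <- ape::reorder.phylo(tree, "cladewise")
    nt <- length(tree$tip.label)
    rel <- relative_depths(tree)
    internal <- (nt + 1L):(nt + tree$Nnode)
    og_tips <- grep("^og", tree$tip.label)
    og_nodes <- if (length(og_tips)) {
      unique(unlist(lapply(og_tips, function(t) {
        ape::nodepath(tree, from = nt + 1L, to = t)
      })))
    } else integer(0)
    cand <- setdiff(internal, c(nt + 1L, og_nodes))
    rk <- vapply(cand, function(nd) {
      names(config$rank_depths)[which.min(abs(rel[nd] - config$rank_depths))]
    }, character(1))
    tree$rank_table <- data.frame(node = cand, rank = rk,
                                  rel_depth = rel[cand],
                                  stringsAsFactors = FALSE)
    lbl <- rep("", tree$Nnode)
    lbl[cand - nt] <- sprintf("%s_N%d", rk, cand)
    lbl[1] <- "root"
    tree$node.label <- lbl
    tree$ingroup <- grep("^sp", tree$tip.label, value = TRUE)
    tree$outgroup <- grep("^og", tree$tip.label, value = TRUE)
    tree
  })
}

#' Evolve marker sequences along a tree
#'
#' Simulates fixed-length amino-acid markers under per-site independent
#' substitution (a Jukes-Cantor-like model on 20 letters, no indels): the
#' probability of substitution on a branch of length `b` is
#' `1 - exp(-rate * b)`, and a substituted site takes one of the 19 other
#' residues uniformly. Because there are no indels the sequences of each
#' marker are trivially aligned.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param config A [sim_config()].
#' @return Named list (marker id -> named character vector of per-leaf
#'   sequences).
#' @export
evolve_markers <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tree$edge.length)) {
    stop("tree must have branch lengths", call. = FALSE)
  }
  nt <- length(tree$tip.label)
  cw <- ape::reorder.phylo(tree, "cladewise")
  L <- config$marker_len
  rate <- config$subst_rate_per_branch
  with_seed(derive_seed(config$seed, 2L), {
    out <- vector("list", config$n_markers)
    names(out) <- sprintf("M%02d", seq_len(config$n_markers))
    for (m in seq_len(config$n_markers)) {
      seqs <- vector("list", nt + cw$Nnode)
      seqs[[nt + 1L]] <- sample.int(20L, L, replace = TRUE)
      for (i in seq_len(nrow(cw$edge))) {
        p <- cw$edge[i, 1]; ch <- cw$edge[i, 2]
        s <- seqs[[p]]
        pr <- 1 - exp(-rate * cw$edge.length[i])
        hit <- which(stats::runif(L) < pr)
        if (length(hit)) {
          s[hit] <- ((s[hit] - 1L + sample.int(19L, length(hit),
                                               replace = TRUE)) %% 20L) + 1L
        }
        seqs[[ch]] <- s
      }
      tipseq <- vapply(seq_len(nt), function(t) {
        paste(AA_ALPHABET[seqs[[t]]], collapse = "")
      }, character(1))
      names(tipseq) <- cw$tip.label
      out[[m]] <- tipseq
    }
    out
  })
}

# -- nucleotide helpers -------------------------------------------------------

.dna_code <- local({
  v <- rep(NA_integer_, 256)
  v[as.integer(charToRaw("A")) + 1L] <- 0L
  v[as.integer(charToRaw("C")) + 1L] <- 1L
  v[as.integer(charToRaw("G")) + 1L] <- 2L
  v[as.integer(charToRaw("T")) + 1L] <- 3L
  v
})
.dna_raw <- charToRaw("ACGT")

random_dna <- function(len) {
  rawToChar(.dna_raw[sample.int(4L, len, replace = TRUE)])
}

#' Mutate a nucleotide sequence at an exact per-site fraction
#'
#' Substitutes exactly `round(fraction * nchar(x))` distinct positions with a
#' different base, so the true per-site divergence (and hence the true ANI)
#' of the pair is known exactly.
#'
#' @param x A DNA string.
#' @param fraction Fraction of sites to mutate, in \[0,1\].
#' @param seed Integer seed.
#' @return The mutated string.
#' @export
mutate_sequence <- function(x, fraction, seed) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- nchar(x)
  n_mut <- round(fraction * n)
  if (n_mut == 0) return(x)
  with_seed(seed, {
    r <- charToRaw(x)
    pos <- sample.int(n, n_mut)
    old <- .dna_code[as.integer(r[pos]) + 1L]
    new <- (old + sample.int(3L, n_mut, replace = TRUE)) %% 4L
    r[pos] <- .dna_raw[new + 1L]
    rawToChar(r)
  })
}

#' True average nucleotide identity of two equal-length sequences
#'
#' The alignment-free oracle used to calibrate the sketch-based ANI
#' estimator: per-site identity of two equal-length strings, in percent.
#'
#' @param a,b DNA strings of equal length.
#' @return Percent identity in \[0,100\].
#' @export
true_ani <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  if (length(ra) != length(rb)) stop("sequences must have equal length",
                                     call. = FALSE)
  100 * mean(ra == rb)
}

#' Synthesize genomes with planted species clusters
#'
#' Draws a random root genome, derives one reference genome per tree leaf
#' (species) by mutating the root at the configured between-species
#' divergence, and then derives member genomes per ingroup species at the
#' within-species divergence (outgroup species get a single exact copy of
#' their reference). With the default divergences, within-species pairs sit
#' above 99% true ANI and between-species pairs below 90%.
#'
#' @param tree A tree from [simulate_tree()].
#' @param config A [sim_config()].
#' @return List with `references` (per-species genome strings), `genomes`
#'   (per-MAG genome strings, pre-degradation), and `truth`
#'   (data.frame: genome_id, species).
#' @export
synthesize_genomes <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genome_len < 50000) {
    stop("genome_len too small to support sketching", call. = FALSE)
  }
  with_seed(derive_seed(config$seed, 3L), {
    root <- random_dna(config$genome_len)
    leaves <- tree$tip.label
    refs <- vapply(seq_along(leaves), function(i) {
      mutate_sequence(root, config$between_divergence,
                      derive_seed(config$seed, 100L + i))
    }, character(1))
    names(refs) <- leaves
    ids <- character(0); species <- character(0); genomes <- character(0)
    k <- 0L
    for (i in seq_along(leaves)) {
      sp <- leaves[i]
      n_g <- if (sp %in% tree$outgroup) 1L else config$genomes_per_species
      for (g in seq_len(n_g)) {
        k <- k + 1L
        id <- sprintf("%s_g%d", sp, g)
        gen <- if (sp %in% tree$outgroup) refs[[sp]] else {
          mutate_sequence(refs[[sp]], config$within_divergence,
                          derive_seed(config$seed, 1000L + k))
        }
        ids <- c(ids, id); species <- c(species, sp)
        genomes <- c(genomes, gen)
      }
    }
    names(genomes) <- ids
    list(references = refs, genomes = genomes,
         truth = data.frame(genome_id = ids, species = species,
                            stringsAsFactors = FALSE))
  })
}

# Split a genome string into contigs with lengths drawn uniformly on
# [1500, 50000] bp; a trailing remainder shorter than the floor is merged
# into the previous contig.
fragment_genome <- function(x, min_len = 1500, max_len = 50000) {
  L <- nchar(x)
  lens <- integer(0); tot <- 0
  while (tot < L) {
    l <- floor(stats::runif(1, min_len, max_len + 1))
    lens <- c(lens, min(l, L - tot))
    tot <- tot + lens[length(lens)]
  }
  if (length(lens) > 1 && lens[length(lens)] < min_len) {
    lens[length(lens) - 1] <- lens[length(lens) - 1] + lens[length(lens)]
    lens <- lens[-length(lens)]
  }
  ends <- cumsum(lens)
  starts <- c(1, utils::head(ends, -1) + 1)
  substring(x, starts, ends)
}

#' Degrade a genome into a fragmented, contaminated MAG
#'
#' Fragments the source genome into contigs (uniform lengths on
#' \[1500, 50000\] bp), retains a random subset amounting to
#' `completeness_frac` of the source length (within one contig boundary),
#' and appends contigs from a contaminant genome amounting to
#' `contamination_frac` of the source length. The returned truth report
#' records the injected fractions as percentages.
#'
#' @param genome Source genome string.
#' @param completeness_frac Fraction of source bp retained, in \[0,1\].
#' @param contaminant Contaminant genome string (may be `NULL` when
#'   `contamination_frac` is 0); must differ from the source.
#' @param contamination_frac Contaminant bp as a fraction of source length.
#' @param seed Integer seed.
#' @param id Genome id used to name contigs.
#' @return List with `contigs` (named character vector), `provenance`
#'   (data.frame: contig, origin, length) and `report` (true completeness
#'   and contamination percentages, injected and achieved).
#' @export
degrade_genome <- function(genome, completeness_frac, contaminant = NULL,
                           contamination_frac = 0, seed = 1L, id = "mag") {
  stopifnot(completeness_frac >= 0, completeness_frac <= 1,
            contamination_frac >= 0, contamination_frac <= 1)
  if (contamination_frac > 0) {
    if (is.null(contaminant)) stop("contaminant required", call. = FALSE)
    if (identical(genome, contaminant)) {
      stop("contaminant identical to source: contamination undetectable by construction",
           call. = FALSE)
    }
  }
  L <- nchar(genome)
  with_seed(seed, {
    take_frac <- function(seq, target) {
      if (target <= 0) return(character(0))
      ctg <- fragment_genome(seq)
      ctg <- ctg[sample.int(length(ctg))]
      keep <- which(cumsum(nchar(ctg)) >= target)[1]
      if (is.na(keep)) keep <- length(ctg)
      ctg[seq_len(keep)]
    }
    own <- take_frac(genome, round(completeness_frac * L))
    foreign <- if (contamination_frac > 0) {
      take_frac(contaminant, round(contamination_frac * L))
    } else character(0)
    contigs <- c(own, foreign)
    origin <- c(rep("self", length(own)), rep("contaminant", length(foreign)))
    if (length(contigs)) {
      names(contigs) <- sprintf("%s_c%04d", id, seq_along(contigs))
    }
    list(contigs = contigs,
         provenance = data.frame(contig = names(contigs) %||% character(0),
                                 origin = origin, length = nchar(contigs),
                                 stringsAsFactors = FALSE, row.names = NULL),
         report = list(completeness_pct = 100 * completeness_frac,
                       contamination_pct = 100 * contamination_frac,
                       achieved_completeness_pct = 100 * sum(nchar(own)) / L,
                       achieved_contamination_pct = 100 * sum(nchar(foreign)) / L))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive GTDB-style taxonomy strings from a rank-labeled tree
#'
#' Each leaf's seven-rank string is read off its planted ancestor labels:
#' rank `r` is named after the deepest ancestor planted at `r`; ranks
#' skipped on a path inherit a placeholder derived from the deepest
#' shallower-ranked ancestor, so no named rank ever sits below an empty
#' one. Outgroup leaves get a fixed outgroup lineage.
#'
#' @param tree A tree from [simulate_tree()].
#' @return data.frame with columns `species` and `taxonomy`.
#' @export
build_taxonomy <- function(tree) {
  stopifnot(!is.null(tree$rank_table))
  nt <- length(tree$tip.label)
  root <- nt + 1L
  rtab <- tree$rank_table
  pref <- c(phylum = "p", class = "c", order = "o", family = "f", genus = "g")
  mid_ranks <- names(pref)
  tax <- vapply(seq_len(nt), function(tip) {
    lf <- tree$tip.label[tip]
    if (lf %in% tree$outgroup) {
      return(sprintf("d__Bacteria;p__OGP;c__OGC;o__OGO;f__OGF;g__OGG;s__%s", lf))
    }
    path <- ape::nodepath(tree, from = root, to = tip)
    anc <- setdiff(path, tip)
    fields <- c("d__Bacteria")
    last_named <- root
    for (rk in mid_ranks) {
      here <- intersect(anc, rtab$node[rtab$rank == rk])
      if (length(here)) {
        nd <- here[which.max(match(here, path))]  # deepest labeled ancestor
        fields <- c(fields, sprintf("%s__%s%d", pref[[rk]], toupper(pref[[rk]]), nd))
        last_named <- nd
      } else {
        fields <- c(fields, sprintf("%s__%sx%d", pref[[rk]], pref[[rk]], last_named))
      }
    }
    fields <- c(fields, sprintf("s__%s", lf))
    paste(fields, collapse = ";")
  }, character(1))
  data.frame(species = tree$tip.label, taxonomy = tax, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic fixture
#'
#' Runs the whole generator: species tree, markers, genomes, per-MAG
#' degradation with injected quality truth, marker hit table, taxonomy
#' strings, and public/novel source labels. Outgroup genomes are emitted
#' undegraded (single contig, completeness 100, contamination 0).
#'
#' @param config A [sim_config()].
#' @return Object of class `red_fixture`: a list with components `config`,
#'   `tree`, `markers`, `references`, `mags` (list: per-genome contig sets),
#'   `quality` (QC report data.frame), `hits` (marker hit table),
#'   `taxonomy` (genome-level), `source_labels`, and `truth`.
#' @export
generate_fixture <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_tree(config)
  markers <- evolve_markers(tree, config)
  syn <- synthesize_genomes(tree, config)
  sp_tax <- build_taxonomy(tree)
  ids <- syn$truth$genome_id
  n <- length(ids)
  with_seed(derive_seed(config$seed, 4L), {
    is_og <- syn$truth$species %in% tree$outgroup
    low <- !is_og & stats::runif(n) < config$frac_low_quality
    heavy <- !is_og & stats::runif(n) < config$frac_contaminated
    comp <- ifelse(is_og, 1, ifelse(low,
      stats::runif(n, config$low_completeness_range[1], config$low_completeness_range[2]),
      stats::runif(n, config$completeness_range[1], config$completeness_range[2])))
    cont <- ifelse(is_og, 0, ifelse(heavy,
      stats::runif(n, config$high_contamination_range[1], config$high_contamination_range[2]),
      stats::runif(n, config$contamination_range[1], config$contamination_range[2])))
    source_lbl <- ifelse(is_og | stats::runif(n) < config$frac_public,
                         "public", "novel")
    mags <- vector("list", n); names(mags) <- ids
    prov <- vector("list", n)
    for (i in seq_len(n)) {
      if (is_og[i]) {
        ctg <- stats::setNames(syn$genomes[[ids[i]]], sprintf("%s_c0001", ids[i]))
        mags[[i]] <- ctg
        prov[[i]] <- data.frame(contig = names(ctg), origin = "self",
                                length = nchar(ctg), stringsAsFactors = FALSE)
      } else {
        other_sp <- sample(setdiff(tree$ingroup, syn$truth$species[i]), 1)
        dg <- degrade_genome(syn$genomes[[ids[i]]], comp[i],
                             contaminant = syn$references[[other_sp]],
                             contamination_frac = cont[i],
                             seed = derive_seed(config$seed, 2000L + i),
                             id = ids[i])
        mags[[i]] <- dg$contigs
        prov[[i]] <- dg$provenance
      }
    }
    # QC reports carry the injected truth on both estimators (estimator
    # noise is outside this generator's scope): strain heterogeneity is
    # drawn small, so paralog correction is exercised without flipping any
    # gate decision relative to truth.
    quality <- data.frame(
      genome_id = ids,
      checkm_completeness = 100 * comp,
      checkm_contamination = 100 * cont,
      strain_heterogeneity = round(stats::runif(n, 0, 15), 2),
      alt_completeness = 100 * comp,
      alt_contamination = 100 * cont,
      stringsAsFactors = FALSE)
    # Marker hit table: per marker a TC/NC pair; scores clear the (TC+NC)/2
    # cutoff except for a small fraction of planted misses.
    mk <- names(markers)
    tc <- round(stats::runif(length(mk), 80, 150), 1)
    nc <- round(tc - stats::runif(length(mk), 20, 40), 1)
    hit_rows <- expand.grid(genome_id = ids, marker_id = mk,
                            stringsAsFactors = FALSE)
    cut <- (tc + nc) / 2
    idx <- match(hit_rows$marker_id, mk)
    miss <- stats::runif(nrow(hit_rows)) < 0.05
    score <- ifelse(miss, nc[idx] - stats::runif(nrow(hit_rows), 1, 10),
                    cut[idx] + stats::runif(nrow(hit_rows), 5, 30))
    hits <- data.frame(genome_id = hit_rows$genome_id,
                       marker_id = hit_rows$marker_id,
                       score = round(score, 1), tc = tc[idx], nc = nc[idx],
                       stringsAsFactors = FALSE)
    taxonomy <- data.frame(
      genome_id = ids,
      taxonomy = sp_tax$taxonomy[match(syn$truth$species, sp_tax$species)],
      stringsAsFactors = FALSE)
    truth <- data.frame(genome_id = ids, species = syn$truth$species,
                        completeness_pct = 100 * comp,
                        contamination_pct = 100 * cont,
                        stringsAsFactors = FALSE)
    out <- list(config = config, tree = tree, markers = markers,
                references = syn$references, genomes = syn$genomes,
                mags = mags, provenance = prov, quality = quality,
                hits = hits, taxonomy = taxonomy,
                source_labels = data.frame(genome_id = ids,
                                           source = source_lbl,
                                           stringsAsFactors = FALSE),
                truth = truth)
    class(out) <- "red_fixture"
    out
  })
}

#' @export
print.red_fixture <- function(x, ...) {
  cat(sprintf("Synthetic fixture: %d MAGs over %d species (%d outgroup), %d markers\n",
              length(x$mags), length(x$tree$tip.label),
              length(x$tree$outgroup), length(x$markers)))
  invisible(x)
}

#' Write a fixture to disk
#'
#' Emits per-genome FASTA, per-marker FASTA, the Newick tree, taxonomy and
#' truth TSVs. Re-running with the same configuration overwrites every file
#' byte-identically.
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a character vector of written paths.
#' @export
emit_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "red_fixture"))
  dir.create(file.path(dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "markers"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory", call. = FALSE)
  paths <- character(0)
  for (id in names(fixture$mags)) {
    p <- file.path(dir, "genomes", paste0(id, ".fasta"))
    write_fasta(fixture$mags[[id]], p)
    paths <- c(paths, p)
  }
  for (m in names(fixture$markers)) {
    p <- file.path(dir, "markers", paste0(m, ".fasta"))
    write_fasta(fixture$markers[[m]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "tree.nwk")
  ape::write.tree(fixture$tree, file = p)
  paths <- c(paths, p)
  tabs <- list(taxonomy = fixture$taxonomy, quality = fixture$quality,
               hits = fixture$hits, source_labels = fixture$source_labels,
               truth_genomes = fixture$truth,
               truth_ranks = fixture$tree$rank_table)
  for (nm in names(tabs)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_tsv(tabs[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
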