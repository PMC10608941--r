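# MAG quality gating: paralog-corrected contamination, dual-estimator
# weighted completeness, MIMAG tiering, the pre-filter cascade, and basic
# assembly statistics. All percentages live on the 0-100 scale; boundary
# semantics follow the printed inequality directions strictly (completeness
# exactly 50 is not medium quality, contamination exactly 20 survives the
# pre-filter).

#' Paralog-corrected contamination
#'
#' Corrects a marker-based contamination estimate for the share of its
#' signal attributable to strain heterogeneity:
#' `contamination_pc = c - c * (h / 100)`.
#'
#' @param checkm_contamination Contamination percentage (>= 0).
#' @param strain_heterogeneity Strain heterogeneity percentage in \[0,100\].
#' @return Corrected contamination percentage.
#' @export
paralog_corrected_contamination <- function(checkm_contamination,
                                            strain_heterogeneity) {
  assert_scalar_pct(checkm_contamination, "checkm_contamination")
  assert_scalar_pct(strain_heterogeneity, "strain_heterogeneity", upper = 100)
  checkm_contamination - checkm_contamination * (strain_heterogeneity / 100)
}

#' Weighted completeness from two estimators
#'
#' Combines a marker-set completeness estimate with a second, reference-tree
#' based estimate as `0.8 * primary + 0.2 * secondary`.
#'
#' @param checkm_completeness Primary completeness percentage in \[0,100\].
#' @param alt_completeness Secondary completeness percentage in \[0,100\].
#' @return Weighted completeness percentage.
#' @export
weighted_completeness <- function(checkm_completeness, alt_completeness) {
  assert_scalar_pct(checkm_completeness, "checkm_completeness", upper = 100)
  assert_scalar_pct(alt_completeness, "alt_completeness", upper = 100)
  0.8 * checkm_completeness + 0.2 * alt_completeness
}

#' Dual-estimator contamination gate
#'
#' A genome passes only when both independent contamination estimates are
#' strictly below 10%, guarding against chimeric bins that a single
#' estimator misses.
#'
#' @param contamination_a,contamination_b Contamination percentages (>= 0).
#' @return Logical.
#' @export
dual_contamination_pass <- function(contamination_a, contamination_b) {
  assert_scalar_pct(contamination_a, "contamination_a")
  assert_scalar_pct(contamination_b, "contamination_b")
  contamination_a < 10 & contamination_b < 10
}

#' Pre-filter for raw bins
#'
#' Drops bins under 50,000 bp, with contamination above 20%, or with
#' completeness below 25% (removal inequalities strict, so the printed
#' boundaries are retained).
#'
#' @param total_bp Assembly size in bp.
#' @param contamination Contamination percentage.
#' @param completeness Completeness percentage.
#' @return Logical: keep the bin.
#' @export
prefilter_bin <- function(total_bp, contamination, completeness) {
  assert_scalar_pct(total_bp, "total_bp")
  assert_scalar_pct(contamination, "contamination")
  assert_scalar_pct(completeness, "completeness")
  total_bp >= 50000 & contamination <= 20 & completeness >= 25
}

#' MIMAG draft-quality tier
#'
#' High-quality drafts require completeness above 90% and contamination
#' below 5%; medium-quality above 50% and below 10%; everything else fails.
#'
#' @param weighted_completeness Completeness percentage.
#' @param contamination_pc Paralog-corrected contamination percentage.
#' @return Character vector of tiers: `"high"`, `"medium"`, or `"fail"`.
#' @export
mimag_tier <- function(weighted_completeness, contamination_pc) {
  assert_scalar_pct(weighted_completeness, "weighted_completeness")
  assert_scalar_pct(contamination_pc, "contamination_pc")
  ifelse(weighted_completeness > 90 & contamination_pc < 5, "high",
         ifelse(weighted_completeness > 50 & contamination_pc < 10,
                "medium", "fail"))
}

#' Basic assembly statistics
#'
#' N50 is the length of the contig at which the cumulative length of
#' descending-sorted contigs first reaches half the assembly size; L50 is
#' that contig's rank. The projected genome size extrapolates the assembly
#' to 100% completeness.
#'
#' @param contigs Character vector of contig sequences.
#' @param completeness Completeness percentage (> 0).
#' @return List of class `assembly_stats`: n_contigs, n50, l50, total_bp,
#'   gc_percent, projected_size.
#' @export
compute_assembly_stats <- function(contigs, completeness = 100) {
  if (length(contigs) < 1) stop("at least one contig required", call. = FALSE)
  if (completeness <= 0) {
    stop("completeness must be > 0 (projection undefined)", call. = FALSE)
  }
  lens <- sort(nchar(contigs), decreasing = TRUE)
  total <- sum(lens)
  l50 <- which(cumsum(lens) >= total / 2)[1]
  gc <- sum(vapply(contigs, function(s) {
    r <- charToRaw(s)
    sum(r == charToRaw("G") | r == charToRaw("C") |
          r == charToRaw("g") | r == charToRaw("c"))
  }, numeric(1)))
  out <- list(n_contigs = length(contigs), n50 = lens[l50], l50 = l50,
              total_bp = total, gc_percent = 100 * gc / total,
              projected_size = total / (completeness / 100))
  class(out) <- "assembly_stats"
  out
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("%d contigs, %d bp (N50 %d, L50 %d), GC %.1f%%, projected %.0f bp\n",
              x$n_contigs, x$total_bp, x$n50, x$l50, x$gc_percent,
              x$projected_size))
  invisible(x)
}

#' Quality verdicts for a table of QC reports
#'
#' Applies the full gate to a QC report table: paralog correction, weighted
#' completeness, the dual contamination rule, MIMAG tiering, and (when
#' assembly sizes are supplied) the pre-filter. A genome is kept when it
#' passes the pre-filter, passes the dual contamination rule, and reaches at
#' least the medium tier.
#'
#' @param reports data.frame with columns genome_id, checkm_completeness,
#'   checkm_contamination, strain_heterogeneity, alt_completeness,
#'   alt_contamination.
#' @param total_bp Optional named numeric of assembly sizes per genome; when
#'   absent the pre-filter's size clause is skipped.
#' @return The input with verdict columns appended: contamination_pc,
#'   weighted_completeness, dual_contamination_pass, mimag_tier,
#'   passed_prefilter, keep.
#' @export
quality_verdicts <- function(reports, total_bp = NULL) {
  need <- c("genome_id", "checkm_completeness", "checkm_contamination",
            "strain_heterogeneity", "alt_completeness", "alt_contamination")
  if (!all(need %in% names(reports))) {
    stop("reports must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- reports
  out$contamination_pc <- paralog_corrected_contamination(
    reports$checkm_contamination, reports$strain_heterogeneity)
  out$weighted_completeness <- weighted_completeness(
    reports$checkm_completeness, reports$alt_completeness)
  out$dual_contamination_pass <- dual_contamination_pass(
    reports$checkm_contamination, reports$alt_contamination)
  out$mimag_tier <- mimag_tier(out$weighted_completeness, out$contamination_pc)
  bp <- if (is.null(total_bp)) rep(50000, nrow(out)) else {
    as.numeric(total_bp[match(out$genome_id, names(total_bp))])
  }
  out$total_bp <- bp
  out$passed_prefilter <- prefilter_bin(bp, reports$checkm_contamination,
                                        reports$checkm_completeness)
  out$keep <- out$passed_prefilter & out$dual_contamination_pass &
    out$mimag_tier != "fail"
  out
}
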