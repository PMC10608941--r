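test_that("hit selection applies the TC/NC-average cutoff and best-hit rule", {
  h <- data.frame(genome_id = "g1", marker_id = "m1",
                  score = c(80, 70, 90), tc = 100, nc = 50)
  sel <- select_hits(h)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$score, 90)
  expect_equal(nrow(select_hits(h[2, ])), 0)  # 70 < cutoff 75
  expect_equal(select_hits(h[1, ])$score, 80)
  expect_error(select_hits(transform(h, tc = NA)), "cutoff")
  # idempotent and order-independent up to the tie rule
  set.seed(4)
  big <- data.frame(genome_id = sample(sprintf("g%d", 1:5), 60, TRUE),
                    marker_id = sample(sprintf("m%d", 1:4), 60, TRUE),
                    score = runif(60, 40, 120), tc = 100, nc = 50)
  s1 <- select_hits(big)
  expect_identical(select_hits(s1)[order(s1$genome_id, s1$marker_id), ],
                   s1[order(s1$genome_id, s1$marker_id), ])
  perm <- big[sample(nrow(big)), ]
  s2 <- select_hits(perm)
  k1 <- s1[order(s1$genome_id, s1$marker_id), c("genome_id", "marker_id", "score")]
  k2 <- s2[order(s2$genome_id, s2$marker_id), c("genome_id", "marker_id", "score")]
  rownames(k1) <- rownames(k2) <- NULL
  expect_identical(k1, k2)
})

test_that("fragmented markers merge in declared order with gap fill", {
  pl <- c(p1 = 100L, p2 = 150L)
  both <- merge_fragmented_marker(c(p1 = strrep("A", 100),
                                    p2 = strrep("C", 150)), pl)
  expect_equal(nchar(both), 250)
  first <- merge_fragmented_marker(c(p1 = strrep("A", 100),
                                     p2 = NA_character_), pl)
  expect_equal(nchar(first), 250)
  expect_identical(substring(first, 101, 250), strrep("-", 150))
  expect_true(is.na(merge_fragmented_marker(c(p1 = NA_character_,
                                              p2 = NA_character_), pl)))
  expect_error(
    apply_fragment_map(list(), list(a = c("x", "y"), b = c("y", "z")),
                       c(x = 1L, y = 1L, z = 1L)),
    "two logical markers")
})

test_that("presence filtering reaches the brute-force fixed point", {
  all_present <- matrix(TRUE, 4, 3,
                        dimnames = list(sprintf("g%d", 1:4),
                                        sprintf("m%d", 1:3)))
  fm <- filter_matrix(all_present)
  expect_setequal(fm$genomes, rownames(all_present))
  expect_setequal(fm$markers, colnames(all_present))
  rare <- all_present; rare[1:3, 1] <- FALSE  # marker in 25% of genomes
  expect_false("m1" %in% filter_matrix(rare, 0.9, 0.5)$markers)
  # random 10x5 matrices: compare with an independent exhaustive iteration
  brute <- function(p, fg, fm_) {
    g <- rownames(p); m <- colnames(p)
    for (it in 1:100) {
      m_new <- m[vapply(m, function(j) mean(p[g, j]) >= fg, logical(1))]
      g_new <- if (length(m_new) == 0) character(0) else
        g[vapply(g, function(i) mean(p[i, m_new]) >= fm_, logical(1))]
      if (identical(g_new, g) && identical(m_new, m)) break
      g <- g_new; m <- m_new
      if (!length(g) || !length(m)) return(NULL)
    }
    list(genomes = g, markers = m)
  }
  for (s in 1:8) {
    set.seed(s)
    p <- matrix(runif(50) < 0.75, 10, 5,
                dimnames = list(sprintf("g%d", 1:10), sprintf("m%d", 1:5)))
    ref <- brute(p, 0.6, 0.5)
    if (is.null(ref)) {
      expect_error(filter_matrix(p, 0.6, 0.5), "empty selection")
    } else {
      got <- filter_matrix(p, 0.6, 0.5)
      expect_setequal(got$genomes, ref$genomes)
      expect_setequal(got$markers, ref$markers)
    }
  }
})

test_that("star alignment is identity on equal lengths and exact on toy pairs", {
  eq <- c(a = "ACDEF", b = "ACDFF", c = "GCDEF")
  expect_identical(align_marker(eq), eq)
  # ACDE vs ACE: optimal global alignment inserts one gap, length 4
  pair <- align_marker(c(x = "ACDE", y = "ACE"))
  expect_equal(unique(nchar(pair)), 4)
  expect_identical(unname(pair["x"]), "ACDE")
  expect_identical(unname(pair["y"]), "AC-E")
  # direct check against an exhaustive DP score for the same pair
  expect_identical(redtax:::nw_align("ACDE", "ACE"), c("ACDE", "AC-E"))
  expect_error(align_marker(c(a = "ACDE")), "at least 2")
  expect_error(align_marker(c(a = "ACDE", b = "")), "empty")
})

test_that("trimming removes gap-heavy columns with a correct index map", {
  clean <- c(a = "ACDE", b = "ACDE")
  tr <- trim_alignment(clean)
  expect_identical(tr$alignment, clean)
  expect_identical(tr$kept_columns, 1:4)
  gappy <- c(a = "A-CD", b = "A-CD", c = "A-CD", d = "AEC-")
  tr2 <- trim_alignment(gappy, 0.5)  # column 2 has 3/4 gaps
  expect_identical(tr2$kept_columns, c(1L, 3L, 4L))
  # random alignments: kept set equals a per-column census
  set.seed(9)
  for (i in 1:5) {
    rows <- replicate(6, paste(sample(c("A", "C", "-"), 30, TRUE,
                                      prob = c(.4, .4, .2)), collapse = ""))
    names(rows) <- sprintf("s%d", 1:6)
    m <- do.call(rbind, strsplit(rows, ""))
    census <- which(colSums(m == "-") / 6 <= 0.5)
    expect_identical(trim_alignment(rows, 0.5)$kept_columns, census)
  }
  expect_error(trim_alignment(c(a = "--", b = "--")), "all columns")
})

test_that("concatenation tiles partitions and gap-fills absences", {
  a1 <- c(g1 = strrep("A", 10), g2 = strrep("C", 10))
  a2 <- c(g1 = strrep("D", 20))
  sm <- concatenate_markers(list(m1 = a1, m2 = a2))
  expect_equal(dim(sm), c(2L, 30L))
  expect_equal(sm$partition$start, c(0, 10))
  expect_equal(sm$partition$end, c(10, 30))
  expect_true(all(sm$matrix["g2", 11:30] == "-"))
  expect_true(sm$missing["g2", "m2"])
  # partition tiling invariant
  widths <- sm$partition$end - sm$partition$start
  expect_equal(sum(widths), ncol(sm$matrix))
  expect_true(all(sm$partition$start == c(0, cumsum(widths))[-3]))
  # declared order controls layout regardless of genome ordering
  sm2 <- concatenate_markers(list(m1 = a1[c(2, 1)], m2 = a2))
  expect_identical(sm$matrix, sm2$matrix)
  expect_error(concatenate_markers(list(m1 = c(g1 = "A", g1 = "C"))),
               "duplicate")
})

test_that("supermatrix over indel-free synthetic markers is exact", {
  cfg <- sim_config(n_taxa = 6, n_outgroup = 0, n_markers = 4,
                    marker_len = 50, seed = 10)
  tr <- simulate_tree(cfg)
  mk <- evolve_markers(tr, cfg)
  alns <- lapply(mk, function(m) trim_alignment(align_marker(m))$alignment)
  expect_identical(alns, lapply(mk, identity))  # align + trim is identity
  sm <- concatenate_markers(alns)
  expect_equal(ncol(sm$matrix), 4 * 50)
  expect_false(any(sm$missing))
})

test_that("rpoB fraction warning is strict at 20%", {
  mk <- function(w) stats::setNames(rep(strrep("A", w), 2), c("g1", "g2"))
  sm25 <- concatenate_markers(list(rpoB = mk(25), other = mk(75)))
  expect_true(rpob_fraction_check(sm25, "rpoB")$warn)
  sm10 <- concatenate_markers(list(rpoB = mk(10), other = mk(90)))
  expect_false(rpob_fraction_check(sm10, "rpoB")$warn)
  sm20 <- concatenate_markers(list(rpoB = mk(20), other = mk(80)))
  chk <- rpob_fraction_check(sm20, "rpoB")
  expect_equal(chk$fraction, 0.20)
  expect_false(chk$warn)
  expect_error(rpob_fraction_check(sm20, "nope"), "unknown marker")
})
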