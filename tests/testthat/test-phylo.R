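make_sm <- function(rows) {
  structure(list(matrix = do.call(rbind, strsplit(rows, "")),
                 partition = data.frame(marker = "m1", start = 0,
                                        end = nchar(rows[1])),
                 missing = matrix(FALSE, length(rows), 1,
                                  dimnames = list(names(rows), "m1"))),
            class = "supermatrix") -> sm
  rownames(sm$matrix) <- names(rows)
  sm
}

test_that("distances match per-pair censuses and the Poisson transform", {
  sm <- make_sm(c(a = "AAAA", b = "AAAA", c = "CCAA", d = "CCCC"))
  D <- distance_matrix(sm, "p_distance")
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.5)
  Dp <- distance_matrix(sm, "poisson")
  expect_equal(Dp["a", "c"], -log(0.5), tolerance = 1e-12)
  expect_identical(Dp, t(Dp))
  expect_true(all(diag(Dp) == 0))
  # gap-aware: shared columns only
  smg <- make_sm(c(a = "AA--", b = "AC--", c = "ACGT", d = "ACGA"))
  Dg <- distance_matrix(smg, "p_distance")
  expect_equal(Dg["a", "b"], 0.5)
  # random matrices against an independent recount
  set.seed(11)
  for (i in 1:4) {
    rows <- replicate(5, paste(sample(c("A", "C", "G", "-"), 100, TRUE),
                               collapse = ""))
    names(rows) <- sprintf("t%d", 1:5)
    sm2 <- make_sm(rows)
    D2 <- distance_matrix(sm2, "p_distance")
    m <- do.call(rbind, strsplit(rows, ""))
    for (p in list(c(1, 2), c(2, 5), c(3, 4))) {
      sh <- m[p[1], ] != "-" & m[p[2], ] != "-"
      expect_equal(D2[p[1], p[2]], sum(m[p[1], sh] != m[p[2], sh]) / sum(sh))
    }
  }
  # a pair with zero shared columns is an explicit error naming the pair
  bad <- make_sm(c(a = "AA--", b = "--CC", c = "ACGT", d = "ACGA"))
  expect_error(distance_matrix(bad), "a and b")
})

test_that("neighbor joining recovers additive trees and is order-stable", {
  true <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:1):1);")
  D <- ape::cophenetic.phylo(true)
  nj <- build_nj_tree(D)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), nj)), 0)
  # additive distances are reproduced exactly
  expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
               tolerance = 1e-12)
  # permuting taxa leaves the topology unchanged
  perm <- sample(rownames(D))
  nj2 <- build_nj_tree(D[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(nj, nj2)), 0)
  # 3 taxa: the single unrooted topology with exact pendant lengths
  D3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  nj3 <- build_nj_tree(D3)
  expect_equal(sort(ape::cophenetic.phylo(nj3)["a", c("b", "c")]),
               sort(c(b = 2, c = 3)))
  asym <- D; asym[1, 2] <- asym[1, 2] + 1
  expect_error(build_nj_tree(asym), "symmetric")
})

test_that("NJ on synthetic supermatrices recovers the generating topology", {
  # moderate substitution rate; 20 markers x 120 columns, 16 taxa
  rf0 <- vapply(1:20, function(s) {
    cfg <- sim_config(n_taxa = 16, n_outgroup = 0,
                      subst_rate_per_branch = 0.2, seed = s)
    tr <- simulate_tree(cfg)
    sm <- concatenate_markers(lapply(evolve_markers(tr, cfg), align_marker))
    nj <- build_nj_tree(distance_matrix(sm, "poisson"))
    ape::dist.topo(ape::unroot(tr), nj) == 0
  }, logical(1))
  expect_gte(mean(rf0), 0.95)
})

test_that("outgroup rooting splits ingroup from outgroup at an edge midpoint", {
  cfg <- sim_config(n_taxa = 10, n_outgroup = 3, seed = 15)
  tr <- simulate_tree(cfg)
  sm <- concatenate_markers(lapply(evolve_markers(tr, cfg), align_marker))
  nj <- build_nj_tree(distance_matrix(sm, "poisson"))
  rooted <- root_with_outgroup(nj, tr$outgroup)
  expect_true(ape::is.rooted(rooted))
  expect_true(ape::is.monophyletic(rooted, tr$outgroup))
  # rooting recovers the generating root's ingroup bipartition
  og_mrca <- ape::getMRCA(rooted, tr$outgroup)
  expect_setequal(ape::extract.clade(rooted, og_mrca)$tip.label, tr$outgroup)
  # single outgroup leaf: root on its pendant edge
  r1 <- root_with_outgroup(nj, tr$outgroup[1])
  nt <- length(r1$tip.label)
  kids <- r1$edge[r1$edge[, 1] == nt + 1L, 2]
  expect_true(match(tr$outgroup[1], r1$tip.label) %in% kids)
  # scattered "outgroup" rejected
  expect_error(root_with_outgroup(nj, c(tr$outgroup[1], tr$ingroup[1])),
               "not monophyletic")
  expect_error(root_with_outgroup(nj, "nonexistent_tip"), "absent")
})

test_that("taxon decoration flags exactly the non-monophyletic taxa", {
  cfg <- sim_config(n_taxa = 12, n_outgroup = 2, genomes_per_species = 1,
                    seed = 16)
  tr <- simulate_tree(cfg)
  tax <- build_taxonomy(tr)
  tax$genome_id <- tax$species
  dec <- decorate_tree(tr, tax[, c("genome_id", "taxonomy")])
  # planted taxa come from clades of the generating tree: all monophyletic
  expect_true(all(dec$taxa$monophyletic))
  # verdicts equal brute-force leaf-set comparison
  for (i in seq_len(nrow(dec$taxa))) {
    rk <- dec$taxa$rank[i]
    members <- tax$genome_id[taxon_at_rank(tax$taxonomy, rk) ==
                               dec$taxa$taxon[i]]
    clade <- if (dec$taxa$n_taxon[i] == 1) members else
      ape::extract.clade(tr, dec$taxa$node[i])$tip.label
    expect_identical(dec$taxa$monophyletic[i], setequal(clade, members))
  }
  # deliberately split one genus across the tree: exactly that taxon flagged
  split_tax <- tax
  gsplit <- taxon_at_rank(split_tax$taxonomy, "genus")[1]
  far_tip <- tr$outgroup[1]
  split_tax$taxonomy[split_tax$genome_id == far_tip] <-
    sub("g__[^;]*", paste0("g__", gsplit),
        split_tax$taxonomy[split_tax$genome_id == far_tip])
  dec2 <- decorate_tree(tr, split_tax[, c("genome_id", "taxonomy")])
  bad <- dec2$taxa$taxon[!dec2$taxa$monophyletic]
  expect_identical(bad, gsplit)
  # taxa absent from the tree are skipped and reported
  extra <- rbind(tax[, c("genome_id", "taxonomy")],
                 data.frame(genome_id = "ghost",
                            taxonomy = "d__B;p__Ghost;c__Gc;o__Go;f__Gf;g__Gg;s__ghost"))
  dec3 <- decorate_tree(tr, extra[extra$genome_id %in% tr$tip.label |
                                    extra$genome_id == "ghost", ])
  expect_true(any(grepl("Ghost", dec3$skipped)))
})
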