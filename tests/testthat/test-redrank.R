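test_that("RED recursion matches hand-computed and oracle values", {
  tr <- balanced4()
  red <- compute_red(tr)
  nt <- 4
  expect_equal(red$red[red$node == nt + 1], 0)          # root
  expect_equal(red$red[red$type == "leaf"], rep(1, 4))  # leaves
  # children of the root: P = 0, a = 1, b = 1 -> RED = 0.5
  kids <- tr$edge[tr$edge[, 1] == nt + 1, 2]
  expect_equal(red$red[red$node %in% kids], c(0.5, 0.5))
  # scale invariance
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 1234.5
  expect_lt(max(abs(compute_red(tr2)$red - red$red)), 1e-12)
  # zero-length edge convention: RED(n) = parent RED
  trz <- ape::read.tree(text = "((A:1,B:1):0,(C:1,D:1):2);")
  redz <- compute_red(trz)
  kidz <- trz$edge[trz$edge[, 1] == 5, 2]
  zero_child <- kidz[trz$edge.length[trz$edge[, 1] == 5] == 0]
  expect_equal(redz$red[redz$node == zero_child], 0)
  expect_error(compute_red(ape::unroot(ape::rtree(5))), "rooted")
})

test_that("RED invariants hold on 100 seeded random trees", {
  for (s in 1:100) {
    tr <- random_rooted_tree(sample(5:40, 1), seed = s)
    red <- compute_red(tr)
    nt <- length(tr$tip.label)
    expect_identical(red$red[red$node == nt + 1], 0)
    expect_identical(red$red[red$type == "leaf"], rep(1, nt))
    expect_true(all(red$red >= 0 & red$red <= 1))
    # monotone along every root-to-leaf path
    parent <- stats::setNames(tr$edge[, 1], tr$edge[, 2])
    for (ch in tr$edge[, 2]) {
      expect_gte(red$red[red$node == ch],
                 red$red[red$node == parent[[as.character(ch)]]])
    }
  }
})

test_that("RED equals the independent distance-matrix oracle on small trees", {
  grid <- c(0.1, 1, 10)
  for (n in 4:6) {
    topos <- phangorn::allTrees(n, rooted = TRUE)
    reps <- if (n == 4) 6L else if (n == 5) 2L else 1L
    for (ti in seq_along(topos)) {
      tr <- topos[[ti]]
      for (r in seq_len(reps)) {
        set.seed(1000 * n + 10 * ti + r)
        tr$edge.length <- sample(grid, nrow(tr$edge), replace = TRUE)
        got <- compute_red(tr)$red
        expect_lt(max(abs(got - red_oracle(tr))), 1e-12)
      }
    }
  }
})

test_that("rank models fit medians per rank and warn on inversions", {
  tr <- random_rooted_tree(30, seed = 21)
  red <- compute_red(tr)
  nodes <- red$node[red$type == "internal"][-1]
  lab <- data.frame(node = nodes[1:3], rank = "class")
  vals <- red$red[match(lab$node, red$node)]
  m <- fit_rank_model(red, lab, w = 0.1)
  expect_s3_class(m, "rank_model")
  expect_equal(unname(m$medians[["class"]]), stats::median(vals))
  single <- fit_rank_model(red, lab[1, ], w = 0.1)
  expect_equal(unname(single$medians[["class"]]), vals[1])
  expect_error(fit_rank_model(red, lab[0, ]), "empty")
  # planted ranks on a synthetic tree yield strictly increasing medians
  cfg <- sim_config(n_taxa = 150, n_outgroup = 0, seed = 22)
  trs <- simulate_tree(cfg)
  reds <- compute_red(trs)
  ms <- fit_rank_model(reds, trs$rank_table)
  expect_false(is.unsorted(ms$medians, strictly = TRUE))
  # inverted labels (phylum planted deeper than genus) trigger a warning
  inv <- data.frame(node = nodes[1:2], rank = c("genus", "phylum"))
  inv_red <- red$red[match(inv$node, red$node)]
  inv$rank <- if (inv_red[1] > inv_red[2]) c("phylum", "genus") else
    c("genus", "phylum")
  expect_warning(fit_rank_model(red, inv, w = 0.1), "not strictly increasing")
})

test_that("rank assignment reproduces the published interval decisions", {
  phylum_only <- structure(list(medians = c(phylum = 0.326), w = 0.1,
                                n_per_rank = c(phylum = 1L)),
                           class = "rank_model")
  # a lineage at RED 0.527 falls outside the phylum interval 0.326 +/- 0.1
  a <- assign_rank(0.527, phylum_only)
  expect_false(a$in_phylum)
  expect_false(a$in_interval)
  expect_true(assign_rank(0.326, phylum_only)$in_phylum)
  two <- structure(list(medians = c(class = 0.45, order = 0.70), w = 0.1,
                        n_per_rank = c(class = 1L, order = 1L)),
                   class = "rank_model")
  # RED 0.755 supports order placement
  expect_identical(assign_rank(0.755, two)$assigned_rank, "order")
  expect_identical(predict(two, 0.755)$assigned_rank, "order")
  # equidistant value resolves to the shallower rank
  expect_identical(assign_rank(0.575, two)$assigned_rank, "class")
})

test_that("threshold flags are strict in the stated direction", {
  expect_true(red_threshold_flags(0.6, 0.5, "above"))
  expect_false(red_threshold_flags(0.5, 0.5, "above"))
  expect_true(red_threshold_flags(0.62, 0.6, "above"))
  expect_identical(unname(red_threshold_flags(c(x = 0.755, y = 0.35), 0.5,
                                              "above")), c(TRUE, FALSE))
  expect_true(red_threshold_flags(0.35, 0.4, "below"))
})

test_that("reclassification reports exactly the planted inconsistencies", {
  cfg <- sim_config(n_taxa = 200, n_outgroup = 0,
                    rank_depths = c(phylum = 0.2, class = 0.4,
                                    order = 0.6, family = 0.8),
                    seed = 23)
  tr <- simulate_tree(cfg)
  red <- compute_red(tr)
  lab <- tr$rank_table
  model <- fit_rank_model(red, lab, w = 0.1)
  # consistent labels: every node assigned a rank == its label produces
  # an empty proposal for that node
  recl0 <- evaluate_reclassification(red, lab, model)
  agree <- recl0$assigned_rank == recl0$labeled_rank
  expect_true(all(recl0$proposal[agree] == ""))
  expect_identical(recl0$taxon, sort(recl0$taxon))
  # start from a fully consistent label set, then plant one phylum label on
  # a class-depth node: exactly one proposal, a demotion, at that node
  lab2 <- lab[lab$node %in% recl0$node[agree], ]
  cls <- which(lab2$rank == "class")
  pick <- cls[which.max(red$red[match(lab2$node[cls], red$node)])]
  lab2$rank[pick] <- "phylum"
  recl <- evaluate_reclassification(red, lab2, model)
  dem <- recl[nzchar(recl$proposal), ]
  expect_equal(nrow(dem), 1)
  expect_identical(dem$proposal, "demote to class")
  expect_identical(dem$node, lab2$node[pick])
  expect_error(
    evaluate_reclassification(red, data.frame(node = 99999, rank = "class"),
                              model), "consistency")
})
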