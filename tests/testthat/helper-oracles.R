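# Shared helpers: independent oracles and small fixtures built in code.

# Independent RED oracle: works from the full node-to-node distance matrix
# (ape::dist.nodes) rather than the package's postorder sweep.
red_oracle <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  dn <- ape::dist.nodes(tree)
  leaves_under <- function(node) {
    if (node <= nt) return(node)
    match(ape::extract.clade(tree, node)$tip.label, tree$tip.label)
  }
  red <- rep(NA_real_, nn)
  red[nt + 1L] <- 0
  cw <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(cw$edge))) {
    p <- cw$edge[i, 1]; ch <- cw$edge[i, 2]
    a <- cw$edge.length[i]
    b <- if (ch <= nt) 0 else mean(dn[ch, leaves_under(ch)])
    red[ch] <- if (a + b == 0) red[p] else red[p] + a / (a + b) * (1 - red[p])
  }
  red
}

# Adjusted Rand index between two partitions (label vectors).
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_i * sum_j / n2
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Small rooted tree with known RED values for hand checks.
balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# A random rooted tree with positive branch lengths.
random_rooted_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = TRUE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 2)
  tr
}

# Tiny DNA fixture: planted species clusters for derep tests.
planted_species_fixture <- function(n_species = 5, per_species = 4,
                                    seed = 3) {
  cfg <- sim_config(n_taxa = n_species, n_outgroup = 0,
                    genomes_per_species = per_species, seed = seed)
  tr <- simulate_tree(cfg)
  syn <- synthesize_genomes(tr, cfg)
  syn
}

# Random DNA string under a local seed.
with_seed_dna <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

rank_order <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")
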