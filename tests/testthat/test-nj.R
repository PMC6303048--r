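test_that("3-taxon NJ solves the star branch lengths exactly", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 3
  d[1, 3] <- d[3, 1] <- 4
  d[2, 3] <- d[3, 2] <- 5
  dm <- dist_from_matrix(d, c("A", "B", "C"))
  tree <- neighbor_joining(dm)
  expect_equal(sort(tree$tip.label), c("A", "B", "C"))
  # x_A = (3 + 4 - 5)/2 = 1, x_B = 2, x_C = 3
  bl <- stats::setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 2)
  expect_equal(bl[["C"]], 3)
})

test_that("the 4-taxon worked additive matrix recovers AB|CD with internal
           branch 1", {
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  dm <- dist_from_matrix(d)
  tree <- neighbor_joining(dm)
  # split AB|CD present
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  splits <- lapply(parts, function(p) sort(labs[p]))
  expect_true(list(c("A", "B")) %in% splits || list(c("C", "D")) %in% splits)
  # leaf branches A:1 B:2 C:3 D:4, internal 1 — check via path lengths
  expect_equal(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  tip_edge <- stats::setNames(
    tree$edge.length[match(seq_along(tree$tip.label), tree$edge[, 2])],
    tree$tip.label)
  expect_equal(tip_edge[c("A", "B", "C", "D")],
               c(A = 1, B = 2, C = 3, D = 4))
  internal <- tree$edge.length[tree$edge[, 2] > length(tree$tip.label)]
  expect_equal(sort(internal), 1)
})

test_that("NJ exactly recovers random additive trees up to 12 taxa", {
  withr::local_seed(61)
  for (k in c(5, 8, 12)) {
    for (rep in 1:5) {
      gen <- ape::unroot(ape::rtree(k, br = function(n) runif(n, 0.05, 1)))
      d <- ape::cophenetic.phylo(gen)
      dm <- dist_from_matrix(d)
      rec <- neighbor_joining(dm)
      # identical topology (RF distance 0) and identical path lengths
      expect_equal(ape::dist.topo(gen, rec), structure(0, names = "PH85"),
                   ignore_attr = TRUE)
      expect_equal(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)], d,
                   tolerance = 1e-9)
    }
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  withr::local_seed(62)
  for (rep in 1:5) {
    n <- 10
    gen <- ape::unroot(ape::rtree(n))
    d <- ape::cophenetic.phylo(gen)
    noise <- matrix(0, n, n)
    noise[upper.tri(noise)] <- stats::runif(choose(n, 2), 0, 0.02)
    d <- d + noise + t(noise)
    mine <- neighbor_joining(dist_from_matrix(d))
    ref <- ape::nj(stats::as.dist(d))
    expect_equal(ape::dist.topo(mine, ref), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
  }
})

test_that("ties are resolved deterministically and undefined entries error", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  dm <- dist_from_matrix(d, c("a", "b", "c", "d"))
  t1 <- neighbor_joining(dm)
  t2 <- neighbor_joining(dm)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))

  d[1, 2] <- d[2, 1] <- NA
  expect_error(neighbor_joining(dist_from_matrix(d, c("a", "b", "c", "d"))),
               "undefined")
})

test_that("negative branch estimates are clamped to zero and reported", {
  # violates the triangle inequality strongly enough to force a negative
  # NJ branch estimate
  d <- matrix(c(0, 0.1, 0.11, 0.5,
                0.1, 0, 0.01, 0.55,
                0.11, 0.01, 0, 0.01,
                0.5, 0.55, 0.01, 0), 4, 4)
  dm <- dist_from_matrix(d, c("a", "b", "c", "d"))
  expect_message(tree <- neighbor_joining(dm), "clamped")
  expect_true(all(tree$edge.length >= 0))
  expect_true(length(attr(tree, "clamped_raw")) > 0)
  expect_true(all(attr(tree, "clamped_raw") < 0))
})

test_that("newick output round-trips topology, lengths and supports", {
  withr::local_seed(63)
  aln <- related_alignment(8, 300)
  tree <- suppressWarnings(
    bootstrap_support(aln, bootstrap_config(replicates = 20, seed = 5),
                      dist_config(min_overlap = 10)))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  back <- read_newick(path)
  expect_equal(ape::dist.topo(tree, back), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  expect_equal(sort(tree$edge.length), sort(back$edge.length),
               tolerance = 1e-9)
  expect_setequal(back$node.label, tree$node.label)
})

test_that("resampling-invariant alignment gives 100% support everywhere", {
  # all sequences identical: every bootstrap replicate reproduces the same
  # distance matrix, and the deterministic tie-break reproduces the same
  # tree, so every bipartition appears in every replicate
  aln <- tibble::tibble(
    specimen_id = sprintf("t%d", 1:8),
    sequence = rep(strrep("ACGT", 100), 8)
  )
  tree <- bootstrap_support(aln, bootstrap_config(replicates = 25, seed = 3))
  expect_true(all(as.numeric(tree$node.label) == 100))
})

test_that("bootstrap with a single replicate yields only 0 or 100", {
  withr::local_seed(64)
  aln <- related_alignment(6, 400)
  tree <- bootstrap_support(aln, bootstrap_config(replicates = 1, seed = 9))
  expect_true(all(as.numeric(tree$node.label) %in% c(0, 100)))
})

test_that("two well-separated clades get >= 95% support at 200 replicates", {
  sim <- simulate_barcodes(sim_config(
    n_species = 2, specimens_per_species = 4, seq_length = 600,
    intra_depth = 0.005, inter_depth = 0.05, seed = 777))
  tree <- bootstrap_support(sim$alignment,
                            bootstrap_config(replicates = 200, seed = 12))
  clade1 <- sim$taxonomy$specimen_id[sim$taxonomy$species == "Species01"]
  node1 <- ape::getMRCA(tree, clade1)
  clade2 <- sim$taxonomy$specimen_id[sim$taxonomy$species == "Species02"]
  node2 <- ape::getMRCA(tree, clade2)
  support <- as.numeric(tree$node.label)
  ntip <- length(tree$tip.label)
  # the split appears as a proper clade on at least one side of the root
  vals <- c(
    if (length(ape::extract.clade(tree, node1)$tip.label) == length(clade1))
      support[node1 - ntip],
    if (length(ape::extract.clade(tree, node2)$tip.label) == length(clade2))
      support[node2 - ntip]
  )
  expect_true(length(vals) > 0)
  expect_gte(max(vals), 95)
})

test_that("bootstrap supports are reproducible from the master seed", {
  withr::local_seed(65)
  aln <- related_alignment(6, 300)
  t1 <- bootstrap_support(aln, bootstrap_config(replicates = 30, seed = 21))
  t2 <- bootstrap_support(aln, bootstrap_config(replicates = 30, seed = 21))
  expect_identical(t1$node.label, t2$node.label)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})
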