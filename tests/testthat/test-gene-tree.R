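test_that("Poisson distance has the documented closed form and domain", {
  expect_equal(poissonDistance(0), 0)
  expect_equal(poissonDistance(0.5), log(2))
  expect_equal(poissonDistance(0.99), -log(0.01), tolerance = 1e-12)
  expect_error(poissonDistance(1), "saturated")
  expect_error(poissonDistance(-0.1), ">= 0")
  # strictly increasing and convex on [0, 1)
  p <- seq(0, 0.95, by = 0.05)
  d <- poissonDistance(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(diff(d)) > 0))
})

test_that("neighbor joining recovers the generating four-taxon tree", {
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- 3; dm["A", "C"] <- 5; dm["A", "D"] <- 6
  dm["B", "C"] <- 6; dm["B", "D"] <- 7; dm["C", "D"] <- 7
  dm <- dm + t(dm)
  tr <- neighborJoining(dm)
  # split AB|CD with internal branch 1
  expect_true("C|D" %in% m6APhylo:::splitSet(tr))
  pd <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_lt(max(abs(pd - dm)), 1e-9)
  ab <- ape::getMRCA(tr, c("A", "B"))
  inner <- tr$edge.length[tr$edge[, 2] == ab]
  # the AB stem carries the unit internal branch (up to root placement)
  expect_equal(ape::cophenetic.phylo(tr)["A", "C"] -
                 ape::cophenetic.phylo(tr)["A", "B"], 2)
  # two taxa: a single edge of the input length
  d2 <- matrix(c(0, 5, 5, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighborJoining(d2)
  expect_equal(ape::cophenetic.phylo(t2)["A", "B"], 5)
  # invalid inputs
  bad <- dm; bad[1, 2] <- 99
  expect_error(neighborJoining(bad), "symmetric")
  neg <- dm; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(neighborJoining(neg), "symmetric|non-negative")
})

test_that("random additive matrices are reconstructed exactly", {
  recovered <- 0
  for (s in 1:100) {
    set.seed(s)
    n <- sample(4:10, 1)
    rt <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(rt)
    tr <- neighborJoining(d)
    pd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    topo <- setequal(m6APhylo:::splitSet(ape::unroot(rt)),
                     m6APhylo:::splitSet(tr))
    if (topo && max(abs(pd - d)) < 1e-9) recovered <- recovered + 1
  }
  expect_equal(recovered, 100)
})

test_that("our NJ agrees with the reference implementation on topology", {
  for (s in 1:10) {
    set.seed(100 + s)
    rt <- ape::rtree(8, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(rt)
    ours <- neighborJoining(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(phangorn::RF.dist(ape::unroot(ours), ref), 0)
  }
})

test_that("bootstrap supports are valid, deterministic and order-invariant", {
  panel <- twoTipPanel()
  # identical sequences: supports computed without error, in [0, 1]
  same <- Biostrings::AAStringSet(setNames(rep("MKLVHEAG", 4),
                                           paste0("t", 1:4)))
  bs0 <- bootstrapSupport(same, replicates = 20, seed = 3)
  expect_true(all(supports(bs0) >= 0 & supports(bs0) <= 1))
  # strong signal
  p4 <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
  p4$node.label <- paste0("n", 1:p4$Nnode)
  panel4 <- new("SpeciesPanel", tree = p4,
                supergroup = setNames(c("G1", "G1", "G2", "G2"),
                                      c("A", "B", "C", "D")))
  params <- evolParams(seqLength = 2000, subRate = 0.5)
  sim <- evolveSequences(simulateFamily(panel4, params, seed = 5),
                         params, seed = 6)
  aln <- proteinSequences(sim)
  names(aln) <- sub("\\|.*$", "", names(aln))
  bs <- bootstrapSupport(aln, replicates = 100, seed = 11)
  expect_gte(splitSupport(bs, c("C", "D")), 0.95)
  # determinism
  bs2 <- bootstrapSupport(aln, replicates = 100, seed = 11)
  expect_identical(supports(bs), supports(bs2))
  # tip input order does not change supports
  bs3 <- bootstrapSupport(aln[rev(seq_along(aln))], replicates = 100,
                          seed = 11)
  expect_identical(supports(bs)[sort(names(supports(bs)))],
                   supports(bs3)[sort(names(supports(bs3)))])
  expect_error(bootstrapSupport(aln, replicates = 0, seed = 1), ">= 1")
})

test_that("midpoint rooting halves the longest tip-to-tip path", {
  t2 <- ape::read.tree(text = "(A:1,B:3);")
  mr <- midpointRoot(t2)
  expect_equal(unname(ape::node.depth.edgelength(mr)[1:2]), c(2, 2))
  # random trees: the deepest tip sits at half the tree diameter
  for (s in 1:20) {
    set.seed(s)
    tr <- ape::rtree(sample(4:12, 1), br = function(k) runif(k, 0.1, 2))
    mr <- midpointRoot(ape::unroot(tr))
    depths <- ape::node.depth.edgelength(mr)[seq_along(mr$tip.label)]
    diam <- max(ape::cophenetic.phylo(tr))
    expect_equal(max(depths), diam / 2, tolerance = 1e-8)
  }
})
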