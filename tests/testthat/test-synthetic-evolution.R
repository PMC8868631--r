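test_that("species panels have the requested composition and structure", {
  counts <- c(Bacteria = 17L, Archaea = 6L, Discoba = 7L, Metamonada = 2L,
              SAR = 14L, Archaeplastida = 6L, Amorphea = 36L)
  p <- simulateSpeciesPanel(counts, seed = 7)
  tr <- speciesTree(p)
  expect_identical(length(tr$tip.label), 88L)
  expect_true(ape::is.rooted(tr))
  expect_true(all(tr$edge.length >= 0))
  # every supergroup is a clade
  for (g in names(counts)) {
    tips <- names(supergroups(p))[supergroups(p) == g]
    expect_identical(sum(supergroups(p) == g), unname(counts[g]))
    if (length(tips) > 1) {
      mrca <- ape::getMRCA(tr, tips)
      expect_setequal(ape::extract.clade(tr, mrca)$tip.label, tips)
    }
  }
  # minimal two-taxon panel
  p2 <- twoTipPanel()
  expect_identical(length(speciesTree(p2)$tip.label), 2L)
  # determinism
  expect_identical(
    ape::write.tree(speciesTree(simulateSpeciesPanel(counts, seed = 5))),
    ape::write.tree(speciesTree(simulateSpeciesPanel(counts, seed = 5))))
  expect_error(simulateSpeciesPanel(c(), seed = 1), "non-empty")
  expect_error(simulateSpeciesPanel(c(A = 0, B = 2), seed = 1), ">= 1")
})

test_that("with zero event rates the gene tree mirrors the species tree", {
  panel <- smallPanel()
  sim <- simulateFamily(panel, evolParams(), seed = 2)
  gt <- geneTree(sim)
  expect_identical(length(gt$tip.label), 16L)
  # exactly one copy per tip
  expect_setequal(unname(speciesMap(sim)),
                  speciesTree(panel)$tip.label)
  relab <- gt
  relab$tip.label <- sub("\\|.*$", "", relab$tip.label)
  expect_equal(
    phangorn::RF.dist(ape::unroot(relab),
                      ape::unroot(speciesTree(panel))), 0)
  expect_identical(sum(trueHistory(sim)$kind == "gain"), 1L)
})

test_that("overwhelming loss empties the family but records its history", {
  panel <- smallPanel()
  sim <- simulateFamily(panel, evolParams(loss = 50), seed = 4)
  expect_length(proteinSequences(sim), 0)
  expect_null(geneTree(sim))
  h <- trueHistory(sim)
  expect_identical(sum(h$kind == "gain"), 1L)
  expect_gt(sum(h$kind == "loss"), 0)
})

test_that("equal birth and death rates keep mean copy number near one", {
  panel <- smallPanel()
  params <- evolParams(dup = 0.1, loss = 0.1)
  tot <- 0
  reps <- 400
  for (s in seq_len(reps))
    tot <- tot + length(proteinSequences(
      simulateFamily(panel, params, seed = s))) / 16
  expect_lt(abs(tot / reps - 1), 0.1)
})

test_that("every simulated history has exactly one gain", {
  panel <- smallPanel()
  params <- evolParams(dup = 0.2, loss = 0.2, transfer = 0.1)
  for (s in 1:25)
    expect_identical(
      sum(trueHistory(simulateFamily(panel, params, seed = s))$kind ==
            "gain"), 1L)
})

test_that("sequence evolution conserves length, alphabet and motifs", {
  panel <- smallPanel()
  sim <- simulateFamily(panel, evolParams(), seed = 2)
  params <- evolParams(seqLength = 120, subRate = 0.4,
                       motifs = list(list(pattern = "DPPW", pos = 50)))
  ev <- evolveSequences(sim, params, seed = 9)
  seqs <- as.character(proteinSequences(ev))
  expect_true(all(nchar(seqs) == 120))
  expect_true(all(strsplit(paste(seqs, collapse = ""), "")[[1]] %in%
                    Biostrings::AA_STANDARD))
  expect_true(all(substr(seqs, 50, 53) == "DPPW"))
  # rate zero: all tips identical
  ev0 <- evolveSequences(sim, evolParams(seqLength = 80, subRate = 0),
                         seed = 9)
  expect_length(unique(as.character(proteinSequences(ev0))), 1)
  # motif outside the sequence errors
  expect_error(
    evolParams(seqLength = 40,
               motifs = list(list(pattern = "DPPW", pos = 39))),
    "range")
})

test_that("pairwise divergence follows the uniform-replacement closed form", {
  panel <- twoTipPanel()
  tpath <- sum(speciesTree(panel)$edge.length)
  params <- evolParams(seqLength = 400, subRate = 1)
  tot <- 0; reps <- 40
  for (s in seq_len(reps)) {
    f <- evolveSequences(simulateFamily(panel, params, seed = s),
                         params, seed = s + 5000)
    sq <- as.character(proteinSequences(f))
    a <- strsplit(sq[1], "")[[1]]; b <- strsplit(sq[2], "")[[1]]
    tot <- tot + mean(a != b)
  }
  expected <- (19 / 20) * (1 - exp(-(20 / 19) * tpath))
  expect_lt(abs(tot / reps - expected), 0.03)
})

test_that("structure pairs obey their rigid-motion/noise ground truth", {
  pr <- simulateStructurePair(50, rotation = c(0.4, 0.2, 1.1),
                              translation = c(3, -2, 7), noiseSd = 0,
                              seed = 5)
  expect_lt(rmsd(superpose(pr$a, pr$b)), 1e-9)
  # same seed reproduces the same coordinates
  pr2 <- simulateStructurePair(50, rotation = c(0.4, 0.2, 1.1),
                               translation = c(3, -2, 7), noiseSd = 0,
                               seed = 5)
  expect_identical(caCoords(pr$b), caCoords(pr2$b))
  # E[RMSD] ~ sqrt(3) sigma at noise sd 1
  tot <- 0; reps <- 30
  for (k in seq_len(reps))
    tot <- tot + rmsd(superpose(
      simulateStructurePair(500, c(0.3, 0.2, 0.1), c(1, 2, 3),
                            noiseSd = 1, seed = k)$a,
      simulateStructurePair(500, c(0.3, 0.2, 0.1), c(1, 2, 3),
                            noiseSd = 1, seed = k)$b,
      maxCycles = 0))
  expect_lt(abs(tot / reps - sqrt(3)), 0.06)
  expect_error(simulateStructurePair(2, seed = 1), "at least 3")
})
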