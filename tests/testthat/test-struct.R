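test_that("PDB parsing selects chains and resolves altlocs", {
  pr <- simulateStructurePair(5, seed = 9)
  f <- tempfile(fileext = ".pdb")
  writeCaTracePdb(pr$a, f)
  tr <- parseStructure(f, "A")
  expect_lt(max(abs(caCoords(tr) - caCoords(pr$a))), 1e-3)
  expect_identical(tr@resname, pr$a@resname)
  # crafted fixture with an altloc pair and a second chain
  txt <- paste(c(
    "ATOM      1  CA AALA A   1      0.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1      9.000   9.000   9.000  0.50  0.00           C",
    "ATOM      3  CA  GLY A   2      3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  SER A   3      7.600   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  LEU B   1      0.000   0.000   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
  suppressWarnings({
    t2 <- parseStructure(txt, "A")
    expect_identical(nrow(caCoords(t2)), 3L)
    expect_true(all(caCoords(t2)[1, ] == 0))   # first altloc kept
    expect_error(parseStructure(txt, "C"), "not present")
    expect_error(parseStructure(txt, "B"), "fewer than 3")
  })
})

test_that("superposition is exact under rigid motions, in both directions", {
  pr <- simulateStructurePair(120, rotation = c(pi / 2, 0.3, 1.2),
                              translation = c(5, 5, 5), noiseSd = 0,
                              seed = 3)
  sab <- superpose(pr$a, pr$b)
  expect_lt(rmsd(sab), 1e-9)
  expect_lt(abs(det(sab@rotation) - 1), 1e-9)
  expect_lt(max(abs(crossprod(sab@rotation) - diag(3))), 1e-9)
  # symmetry and invariance under extra rigid motions of either input
  pr2 <- simulateStructurePair(80, c(0.5, 0.1, 0.9), c(1, 2, 3),
                               noiseSd = 0.8, seed = 4)
  expect_equal(rmsd(superpose(pr2$a, pr2$b)),
               rmsd(superpose(pr2$b, pr2$a)), tolerance = 1e-9)
  moved <- transformTrace(pr2$b, superpose(pr2$a, pr2$b))
  expect_equal(rmsd(superpose(pr2$a, moved)),
               rmsd(superpose(pr2$a, pr2$b)), tolerance = 1e-6)
})

test_that("Kabsch matches an exhaustive rotation-grid oracle", {
  set.seed(2)
  A <- matrix(rnorm(12) * 5, 4, 3)
  B <- A
  B[4, ] <- B[4, ] + c(8, -5, 3)
  mk <- function(m, ch) new("CaTrace", chain = ch, resno = 1:4,
                            resname = rep("ALA", 4), coords = m)
  gridBest <- Inf
  Pc <- sweep(A, 2, colMeans(A)); Qc <- sweep(B, 2, colMeans(B))
  for (a in seq(0, 2 * pi, length.out = 60))
    for (b in seq(0, pi, length.out = 30))
      for (cc in seq(0, 2 * pi, length.out = 60)) {
        R <- m6APhylo:::eulerRotation(c(a, b, cc))
        r <- sqrt(mean(rowSums((Pc - Qc %*% t(R))^2)))
        if (r < gridBest) gridBest <- r
      }
  fit <- superpose(mk(A, "A"), mk(B, "B"), maxCycles = 0)
  # the closed-form optimum can only undercut the grid, within grid step
  expect_lte(rmsd(fit), gridBest + 1e-9)
  expect_lt(abs(rmsd(fit) - gridBest), 1e-3 + 2 * pi / 59 * 10)
  expect_lt(abs(rmsd(fit) - gridBest), 0.05)
  # rejection drops exactly the displaced pair
  rej <- superpose(mk(A, "A"), mk(B, "B"), maxCycles = 5,
                   rejectSigma = 1.0)
  expect_identical(rej@nPairs, 3L)
  expect_lt(rmsd(rej), 1e-9)
})

test_that("rejection cycles never increase the RMSD", {
  for (s in 1:10) {
    pr <- simulateStructurePair(60, c(0.2, 0.4, 0.6), c(2, 0, -1),
                                noiseSd = 1.5, seed = s)
    r0 <- rmsd(superpose(pr$a, pr$b, maxCycles = 0))
    prev <- r0
    for (mc in 1:4) {
      r <- rmsd(superpose(pr$a, pr$b, maxCycles = mc))
      expect_lte(r, prev + 1e-12)
      prev <- r
    }
  }
})

test_that("our superposition agrees with the reference implementation", {
  for (s in 1:5) {
    pr <- simulateStructurePair(90, c(0.3, 0.8, 0.2), c(4, -3, 1),
                                noiseSd = 1, seed = 40 + s)
    ours <- rmsd(superpose(pr$a, pr$b, maxCycles = 0))
    ref <- bio3d::rmsd(as.numeric(t(caCoords(pr$a))),
                       as.numeric(t(caCoords(pr$b))), fit = TRUE)
    expect_equal(ours, ref, tolerance = 1e-3)
  }
})

test_that("the RMSD matrix is symmetric and ordered by noise", {
  mkpair <- function(sd, seed) simulateStructurePair(
    200, c(0.1, 0.2, 0.3), c(1, 1, 1), noiseSd = sd, seed = seed)
  base <- mkpair(0, 7)$a
  traces <- list(ref = base,
                 low = mkpair(0.5, 7)$b,
                 mid = mkpair(1.5, 7)$b,
                 high = mkpair(3, 7)$b)
  m <- rmsdMatrix(traces, maxCycles = 0)
  expect_lt(max(abs(m - t(m))), 1e-9)
  expect_true(all(diag(m) == 0))
  expect_lt(m["ref", "low"], m["ref", "mid"])
  expect_lt(m["ref", "mid"], m["ref", "high"])
  # duplicate traces: all-zero matrix
  m0 <- rmsdMatrix(list(x = base, y = base))
  expect_lt(max(abs(m0)), 1e-9)
})
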