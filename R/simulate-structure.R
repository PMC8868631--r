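AA3 <- c(A="ALA", R="ARG", N="ASN", D="ASP", C="CYS", Q="GLN", E="GLU",
         G="GLY", H="HIS", I="ILE", L="LEU", K="LYS", M="MET", F="PHE",
         P="PRO", S="SER", T="THR", W="TRP", Y="TYR", V="VAL")
AA1 <- setNames(names(AA3), unname(AA3))

eulerRotation <- function(angles) {
  a <- angles[1]; b <- angles[2]; c <- angles[3]
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)),
               3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)),
               3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Simulate a pair of CA traces related by a known rigid motion
#'
#' Generates a toy C-alpha trace (a random self-avoiding-ish walk with
#' 3.8-Angstrom virtual bonds) and a second trace equal to a rigid
#' motion of the first plus isotropic Gaussian coordinate noise, so
#' superposition results can be checked against known ground truth
#' (with `noiseSd = 0` the optimal RMSD is exactly 0; with noise sd
#' sigma the expected pre-fit per-atom squared deviation is 3 sigma^2).
#'
#' @param nAtoms number of CA atoms (>= 3).
#' @param rotation three Euler angles (radians, z-y-x convention).
#' @param translation length-3 translation vector (Angstrom).
#' @param noiseSd isotropic coordinate noise sd (Angstrom, >= 0).
#' @param seed integer seed.
#' @return list of two [CaTrace-class] objects (`a`, `b`) with
#'   identical residue sequences.
#' @export
simulateStructurePair <- function(nAtoms, rotation = c(0, 0, 0),
                                  translation = c(0, 0, 0),
                                  noiseSd = 0, seed) {
  if (nAtoms < 3L) stop("superposition needs at least 3 atoms")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  withSeed(seed, {
    # random walk with fixed bond length and mild directional memory
    dirs <- matrix(rnorm(3L * nAtoms), ncol = 3L)
    coords <- matrix(0, nAtoms, 3L)
    v <- c(1, 0, 0)
    for (i in 2:nAtoms) {
      v <- v + 0.8 * dirs[i, ]
      v <- v / sqrt(sum(v^2))
      coords[i, ] <- coords[i - 1L, ] + 3.8 * v
    }
    resname <- unname(AA3[sample(names(AA3), nAtoms, replace = TRUE)])
    R <- eulerRotation(rotation)
    b <- coords %*% t(R) +
      matrix(translation, nAtoms, 3L, byrow = TRUE) +
      matrix(rnorm(3L * nAtoms, sd = noiseSd), nAtoms, 3L)
    list(a = new("CaTrace", chain = "A", resno = seq_len(nAtoms),
                 resname = resname, coords = coords),
         b = new("CaTrace", chain = "B", resno = seq_len(nAtoms),
                 resname = resname, coords = b))
  })
}

#' Write a CA trace as a minimal PDB coordinate file
#'
#' @param trace a [CaTrace-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeCaTracePdb <- function(trace, path) {
  lines <- vapply(seq_along(trace@resno), function(i) {
    sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, trace@resname[i], trace@chain, trace@resno[i],
            trace@coords[i, 1], trace@coords[i, 2], trace@coords[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
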