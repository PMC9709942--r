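#' Read a multi-model structural ensemble
#'
#' Reads a PDB file with multiple MODEL records and restricts it to a
#' residue range and atom set with consistent atom ordering across models.
#'
#' @param path PDB file.
#' @param residues residue numbers to keep.
#' @param atoms atom-name set; default heavy backbone `N, CA, C, O`
#'   (`c("N","CA","C")` is the common alternative convention).
#' @return Object of class `structure_ensemble`: list with `coords`
#'   (conformers x atoms x 3 array, Angstrom), `atom_table` (residue/atom
#'   identifiers), `n_models`.
#' @export
read_ensemble <- function(path, residues = 1:14,
                          atoms = c("N", "CA", "C", "O")) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, elety = atoms, resno = residues,
                            verbose = FALSE)
  if (length(sel$atom) == 0) stop("selection matched no atoms")
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  if (nrow(xyz) < 2)
    stop("an ensemble requires >= 2 models (file has ", nrow(xyz), ")")
  if (any(!is.finite(xyz))) {
    bad <- which(apply(xyz, 1, function(r) any(!is.finite(r))))
    stop("models with differing atom sets in the selection: model(s) ",
         paste(bad, collapse = ", "), " lack coordinates for selected atoms")
  }
  at <- pdb$atom[sel$atom, c("resno", "resid", "elety")]
  n_atoms <- nrow(at)
  coords <- aperm(array(t(xyz), dim = c(3, n_atoms, nrow(xyz))), c(3, 2, 1))
  structure(list(coords = coords, atom_table = at, n_models = nrow(xyz)),
            class = "structure_ensemble")
}

#' Build an ensemble from a list of coordinate matrices
#'
#' @param conformers list of N x 3 coordinate matrices (Angstrom), identical
#'   dimensions.
#' @param atom_table optional data frame `resno`, `resid`, `elety`.
#' @return A `structure_ensemble`.
#' @export
structure_ensemble <- function(conformers, atom_table = NULL) {
  stopifnot(length(conformers) >= 2)
  n <- nrow(conformers[[1]])
  if (!all(vapply(conformers, function(m) all(dim(m) == c(n, 3)), TRUE)))
    stop("all conformers must share the same atom set")
  coords <- aperm(simplify2array(conformers), c(3, 1, 2))
  if (is.null(atom_table))
    atom_table <- data.frame(resno = seq_len(n), resid = "ALA", elety = "CA")
  structure(list(coords = coords, atom_table = atom_table,
                 n_models = length(conformers)),
            class = "structure_ensemble")
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens a `structure_ensemble`.
#' @param path output PDB file.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "structure_ensemble"))
  at <- ens$atom_table
  n <- nrow(at)
  elesy <- substr(at$elety, 1, 1)
  atom <- data.frame(type = "ATOM", eleno = seq_len(n), elety = at$elety,
                     alt = NA, resid = at$resid, chain = "A",
                     resno = at$resno, insert = NA, x = 0, y = 0, z = 0,
                     o = 1, b = 0, segid = NA, elesy = elesy, charge = NA)
  xyz <- t(apply(ens$coords, 1, function(m) as.numeric(t(m))))
  pdb <- structure(list(atom = atom, xyz = bio3d::as.xyz(xyz)),
                   class = "pdb")
  bio3d::write.pdb(pdb, file = path, xyz = pdb$xyz)
  invisible(path)
}

superpose_onto <- function(mobile, fixed) {
  # optimal least-squares superposition (Kabsch) of one conformer onto a
  # reference; both N x 3
  fx <- as.numeric(t(fixed))
  mb <- as.numeric(t(mobile))
  idx <- seq_along(fx)
  out <- bio3d::fit.xyz(fixed = fx, mobile = mb,
                        fixed.inds = idx, mobile.inds = idx)
  matrix(out, ncol = 3, byrow = TRUE)
}

#' Ensemble precision: average backbone RMSD to the mean structure
#'
#' Iteratively superposes all conformers onto their mean coordinates with
#' optimal least-squares rotations until the mean converges, then reports
#' the average over conformers of the RMSD to the converged mean. Invariant
#' under rigid transformations of any conformer and under conformer order.
#'
#' @param ens a `structure_ensemble`.
#' @param tol convergence tolerance on the mean coordinates (Angstrom).
#' @param max_iter iteration cap.
#' @return List with `rmsd_mean` (average RMSD to mean, Angstrom),
#'   `per_conformer` RMSDs, `iterations`, and `rmsd_first` (same statistic
#'   with the first conformer as one-shot reference, reported for
#'   convention comparison).
#' @export
rmsd_to_mean <- function(ens, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(ens, "structure_ensemble"))
  conf <- lapply(seq_len(ens$n_models), function(i) ens$coords[i, , ])
  # initial alignment onto the first conformer
  ref <- conf[[1]]
  conf <- lapply(conf, superpose_onto, fixed = ref)
  mean_coords <- Reduce(`+`, conf) / length(conf)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    conf <- lapply(conf, superpose_onto, fixed = mean_coords)
    new_mean <- Reduce(`+`, conf) / length(conf)
    shift <- sqrt(max(rowSums((new_mean - mean_coords)^2)))
    mean_coords <- new_mean
    if (shift < tol) break
    if (iterations >= max_iter)
      stop("mean-structure superposition did not converge in ",
           max_iter, " iterations")
  }
  per <- vapply(conf, function(m)
    sqrt(mean(rowSums((m - mean_coords)^2))), numeric(1))
  conf1 <- lapply(seq_len(ens$n_models), function(i)
    superpose_onto(ens$coords[i, , ], fixed = ens$coords[1, , ]))
  mean1 <- Reduce(`+`, conf1) / length(conf1)
  per1 <- vapply(conf1, function(m)
    sqrt(mean(rowSums((m - mean1)^2))), numeric(1))
  list(rmsd_mean = mean(per), per_conformer = per, iterations = iterations,
       rmsd_first = mean(per1))
}
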