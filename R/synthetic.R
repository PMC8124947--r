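# Synthetic toy complexes, pose families, fitness scores and IC50 values.
# Everything the pipeline consumes can be generated here, seeded and
# self-contained, so every stage is testable without external structures
# or quantum calculations.  The generator emulates the study layout: a
# small active site of residues around a bound ligand, ~30 docked poses
# per ligand falling into a few well-separated orientation types, fitness
# scores monotone in the true interaction energy, and IC50 values
# log-linear in IE.

#' Specification for the synthetic generators
#'
#' Defaults mirror the study conditions where stated (30 poses per ligand
#' in 3 orientation types; a 5 Angstrom active-site shell) and otherwise
#' fix modest desk-scale values.  The inter-type displacement must exceed
#' `2 * (intra_jitter + 2)` Angstrom so that planted types can never
#' straddle the 2 Angstrom clustering radius.
#'
#' @param n_residues active-site residues
#' @param atoms_per_residue atoms in each toy residue
#' @param ligand_atoms atoms in the toy ligand
#' @param n_types planted orientation types
#' @param poses_per_type poses per type (3 x 10 = the study's 30)
#' @param intra_jitter per-coordinate Gaussian jitter within a type, A
#' @param inter_displacement rigid displacement between types, A
#' @param fitness_noise sd of additive noise on fitness scores
#' @param ic50_noise sd of log-scale noise in [make_ic50()]
#' @param total_charge target total formal charge of the complex
#' @param salt_bridge add a +1/-1 partial-charge pair (ligand/residue)?
#' @param seed mandatory RNG seed; every generator is deterministic
#'   under it
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_residues = 5, atoms_per_residue = 4,
                           ligand_atoms = 6, n_types = 3,
                           poses_per_type = 10, intra_jitter = 0.3,
                           inter_displacement = 8,
                           fitness_noise = 0, ic50_noise = 0,
                           total_charge = 0, salt_bridge = TRUE,
                           seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (inter_displacement <= 2 * (intra_jitter + 2.0))
    stop("inter_displacement must exceed 2 * (intra_jitter + 2.0) so ",
         "planted orientation types are unambiguous")
  structure(as.list(environment()), class = "synthetic_spec")
}

runif_pm <- function(n, lim) stats::runif(n, -lim, lim)

expand_grid_dirs <- function() {
  ## the 8 cube-diagonal unit vectors
  g <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  dimnames(g) <- NULL
  g / sqrt(3)
}

random_rotation <- function() {
  ## QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

place_atoms <- function(n, center, spread, existing = NULL,
                        min_intra = 1.0, min_cross = 2.8,
                        max_tries = 100) {
  ## min_intra: bonded-scale spacing inside the unit; min_cross:
  ## van-der-Waals-scale clearance from already placed units
  for (try in seq_len(max_tries)) {
    xyz <- sweep(matrix(runif_pm(3 * n, spread), ncol = 3), 2, center, "+")
    if (n > 1 && min(stats::dist(xyz)) < min_intra) next
    if (!is.null(existing) &&
        min_cross_dist(xyz, existing) < min_cross) next
    return(xyz)
  }
  NULL
}

#' Generate a toy protein-ligand complex
#'
#' The ligand sits at the origin; residues are placed on a shell around it
#' (centres 4-6.5 Angstrom out, so all fall inside the default 5 Angstrom
#' active-site selection by atom-atom distance).  Every atom receives a
#' partial charge, Lennard-Jones sigma and epsilon drawn from bounded
#' uniform ranges (|q| <= 0.5 e, sigma in [2.5, 3.5] A, epsilon in
#' [0.05, 0.3] kcal/mol); partial charges are mean-centred within each
#' unit, so units are individually net-neutral and long-range tails are
#' multipole-only — except for the default salt-bridge +1/-1 pair placed
#' on the closest ligand-site atom contact, which marks the bound
#' placement energetically.  Deterministic under the spec's seed.
#'
#' @param spec a [synthetic_spec()]
#' @return a [kem_complex()]; residue names are drawn from the standard
#'   set so charge templates apply (all chosen names are neutral, plus one
#'   ASP/LYS pair when `total_charge` bookkeeping needs exercising)
#' @export
make_complex <- function(spec) {
  set.seed(spec$seed)
  nres <- spec$n_residues
  apr <- spec$atoms_per_residue
  nlig <- spec$ligand_atoms
  lig_xyz <- place_atoms(nlig, c(0, 0, 0), spread = 1.6)
  if (is.null(lig_xyz))
    stop("could not place the ligand without overlap after 100 attempts")
  xyz <- lig_xyz
  res_xyz <- vector("list", nres)
  for (i in seq_len(nres)) {
    placed <- NULL
    for (att in seq_len(100)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      center <- u * stats::runif(1, 4.5, 6.5)
      placed <- place_atoms(apr, center, spread = 1.2, existing = xyz,
                            max_tries = 10)
      if (!is.null(placed)) break
    }
    if (is.null(placed))
      stop("could not place residue ", i,
           " without overlap after 100 attempts")
    res_xyz[[i]] <- placed
    xyz <- rbind(xyz, placed)
  }
  n_atoms <- nlig + nres * apr
  elements <- sample(c("C", "N", "O"), n_atoms, replace = TRUE)
  q <- runif_pm(n_atoms, 0.5)
  sig <- stats::runif(n_atoms, 2.5, 3.5)
  eps <- stats::runif(n_atoms, 0.05, 0.3)
  unit_of <- c(rep(0L, nlig), rep(seq_len(nres), each = apr))
  for (u in unique(unit_of)) {
    idx <- unit_of == u
    q[idx] <- q[idx] - mean(q[idx])   # net-neutral units
  }
  if (spec$salt_bridge) {
    ## +1/-1 pair on the closest ligand-site atom contact: gives the
    ## bound placement an unmistakable electrostatic signature
    lidx <- seq_len(nlig)
    ridx <- seq(nlig + 1, n_atoms)
    d2 <- outer(rowSums(xyz[lidx, , drop = FALSE]^2),
                rowSums(xyz[ridx, , drop = FALSE]^2), "+") -
      2 * tcrossprod(xyz[lidx, , drop = FALSE], xyz[ridx, , drop = FALSE])
    hit <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    q[lidx[hit[1]]] <- q[lidx[hit[1]]] + 1
    q[ridx[hit[2]]] <- q[ridx[hit[2]]] - 1
  }
  resnames <- sample(c("GLY", "ALA", "SER", "THR", "VAL", "LEU"), nres,
                     replace = TRUE)
  tc <- spec$total_charge
  if (tc != 0) {
    if (abs(tc) > nres) stop("total_charge exceeds residue count")
    resnames[sample(nres, abs(tc))] <- if (tc > 0) "LYS" else "ASP"
  }
  atoms <- data.frame(
    chain = "A",
    resno = c(rep(999L, nlig), rep(seq_len(nres), each = apr)),
    resname = c(rep("LIG", nlig), rep(resnames, each = apr)),
    name = c(paste0("L", seq_len(nlig)),
             paste0(rep("X", nres * apr), sequence(rep(apr, nres)))),
    element = elements,
    altloc = "", occupancy = 1,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = q, sigma = sig, epsilon = eps,
    role = c(rep("ligand", nlig), rep("protein-residue", nres * apr)),
    stringsAsFactors = FALSE)
  kem_complex(atoms, ligand = "A:999",
              provenance = paste0("make_complex(seed=", spec$seed, ")"))
}

#' Generate a family of docked poses with planted orientation types
#'
#' Type 1 is the reference (crystal-like) placement; each further type is
#' a rigid rotation plus a translation of `inter_displacement * (t - 1)`
#' Angstrom along a distinct axis.  Poses within a type add per-coordinate
#' Gaussian jitter of sd `intra_jitter`.  Fitness is monotone decreasing
#' in the pose's true classical interaction energy with the site (more
#' negative IE = higher fitness) plus optional Gaussian noise, so in the
#' noiseless limit the docking score and the energy agree on the planted
#' binding type.
#'
#' @param spec a [synthetic_spec()]
#' @param complex a [make_complex()] result providing the reference ligand
#'   placement and the site atoms
#' @return list with `poses` (list of [ligand_pose()]), `truth` (integer
#'   type labels named by pose id, numbered by the same best-fitness
#'   convention [cluster_pose_types()] uses), `binding_type` (the truth
#'   label of the bound/crystal-like family, 1 whenever it out-scores the
#'   decoys), and `reference` (the crystal-geometry [ligand_pose()])
#' @export
make_pose_set <- function(spec, complex) {
  set.seed(spec$seed + 1L)
  lig <- ligand_unit(complex)$atoms
  site_atoms <- complex$atoms[complex$atoms$role == "protein-residue", ,
                              drop = FALSE]
  ref_xyz <- as.matrix(lig[, c("x", "y", "z")])
  centroid <- colMeans(ref_xyz)
  site_xyz <- as.matrix(site_atoms[, c("x", "y", "z")])
  ## candidate displacement directions; each displaced type takes the one
  ## with most clearance from the site, so decoy placements never collide
  ## with the protein shell
  dirs <- rbind(diag(3), -diag(3),
                expand_grid_dirs())
  type_xyz <- vector("list", spec$n_types)
  for (t in seq_len(spec$n_types)) {
    if (t == 1) {
      type_xyz[[t]] <- ref_xyz
    } else {
      rot <- random_rotation()
      rotated <- sweep(sweep(ref_xyz, 2, centroid) %*% t(rot), 2,
                       centroid, "+")
      mag <- spec$inter_displacement * (t - 1)
      clear <- apply(dirs, 1, function(u)
        min_cross_dist(sweep(rotated, 2, u * mag, "+"), site_xyz))
      shift <- dirs[which.max(clear), ] * mag
      type_xyz[[t]] <- sweep(rotated, 2, shift, "+")
    }
  }
  poses <- list()
  fam <- integer(0)
  pid <- 0L
  for (t in seq_len(spec$n_types)) {
    for (p in seq_len(spec$poses_per_type)) {
      pid <- pid + 1L
      xyz <- type_xyz[[t]] +
        matrix(stats::rnorm(length(ref_xyz), 0, spec$intra_jitter),
               ncol = 3)
      a <- lig
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
      ie <- cross_interaction_energy(a, site_atoms)
      fitness <- 50 - ie + stats::rnorm(1, 0, spec$fitness_noise)
      poses[[pid]] <- ligand_pose(id = pid, atoms = a, fitness = fitness)
      fam[as.character(pid)] <- t
    }
  }
  ## label families with the same convention cluster_pose_types() uses:
  ## type index ordered by the family's best fitness (Type 1 = best)
  best <- tapply(vapply(poses, `[[`, numeric(1), "fitness"), fam, max)
  ord <- order(-best)
  truth <- stats::setNames(match(fam, ord), names(fam))
  reference <- ligand_pose(id = "crystal", atoms = lig)
  list(poses = poses, truth = truth,
       binding_type = match(1L, ord), reference = reference)
}

#' Brute-force classical cross-term energy between two atom sets
#'
#' The exact interaction energy under the pairwise potential: energy of
#' the union minus the energies of the parts.  Computed directly as the
#' sum over cross pairs; serves as the independent oracle for the KEM
#' reconstruction.
#'
#' @param a,b parameterised atom data.frames
#' @return kcal/mol
#' @export
cross_interaction_energy <- function(a, b) {
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 1e-12)) stop("coincident atoms in cross-term evaluation")
  qq <- outer(a$charge, b$charge)
  sig <- outer(a$sigma, b$sigma, "+") / 2
  eps <- sqrt(outer(a$epsilon, b$epsilon))
  sr6 <- (sig / r)^6
  sum(COULOMB_K * qq / r + 4 * eps * (sr6^2 - sr6))
}

#' Generate IC50 values log-linear in interaction energy
#'
#' `IC50 = exp(a + b * IE + eps)` nM with `b > 0`, so a more negative IE
#' yields a smaller (more potent) IC50; `eps ~ N(0, noise)`.  With
#' `noise = 0` the IC50 ranking reproduces the IE ranking exactly.
#'
#' @param true_ies numeric vector of interaction energies, kcal/mol
#' @param noise log-scale noise sd (>= 0)
#' @param seed RNG seed
#' @param a,b intercept and slope of the log-linear map
#' @return IC50 values in nM, same order as `true_ies`
#' @export
make_ic50 <- function(true_ies, noise = 0, seed, a = 5, b = 0.05) {
  if (noise < 0) stop("noise must be >= 0")
  if (b <= 0) stop("b must be > 0")
  set.seed(seed)
  exp(a + b * true_ies + stats::rnorm(length(true_ies), 0, noise))
}
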