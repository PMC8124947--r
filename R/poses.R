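# Docked-pose handling: in-place heavy-atom RMSD against the crystal
# geometry, grouping of poses into orientation types, and best-pose
# selection by docking fitness or by averaged interaction energy.

#' Construct a ligand pose
#'
#' @param id pose identifier
#' @param atoms data.frame with `element`, `name`, `x`, `y`, `z` (and
#'   optionally classical parameters); atom count and order must agree
#'   across the poses of one ligand
#' @param fitness docking fitness score (unitless, higher is better)
#' @param rank rank assigned by the docking program (optional)
#' @return object of class `ligand_pose`
#' @export
ligand_pose <- function(id, atoms, fitness = NA_real_, rank = NA_integer_) {
  if (nrow(atoms) == 0) stop("pose ", id, " has no atoms")
  structure(list(id = id, atoms = atoms, fitness = fitness,
                 rank = as.integer(rank)),
            class = "ligand_pose")
}

#' In-place heavy-atom RMSD between two poses
#'
#' Root mean square displacement over mapped heavy-atom pairs in a common
#' coordinate frame.  Deliberately *no* superposition or fitting: the
#' displacement from the crystallised ligand's localization in the binding
#' site is the quantity of interest, so a rigidly translated pose keeps
#' its full displacement.
#'
#' @param a,b [ligand_pose()] objects in the same frame
#' @param mapping two-column integer matrix/data.frame of atom indices
#'   (`a` index, `b` index) forming a bijection between heavy-atom
#'   subsets.  Default: positional identity over the heavy atoms of both
#'   poses (requires equal heavy-atom counts).
#' @return RMSD in Angstrom
#' @export
heavy_atom_rmsd <- function(a, b, mapping = NULL) {
  if (is.null(mapping)) {
    ha <- which(a$atoms$element != "H")
    hb <- which(b$atoms$element != "H")
    if (length(ha) != length(hb))
      stop("heavy-atom counts differ (", length(ha), " vs ", length(hb),
           "); supply an explicit mapping")
    mapping <- cbind(ha, hb)
  }
  mapping <- as.matrix(mapping)
  if (nrow(mapping) == 0) stop("empty atom mapping")
  if (anyDuplicated(mapping[, 1]) || anyDuplicated(mapping[, 2]))
    stop("mapping is not a bijection")
  if (any(a$atoms$element[mapping[, 1]] == "H") ||
      any(b$atoms$element[mapping[, 2]] == "H"))
    stop("hydrogens are not allowed in an RMSD mapping")
  pa <- as.matrix(a$atoms[mapping[, 1], c("x", "y", "z")])
  pb <- as.matrix(b$atoms[mapping[, 2], c("x", "y", "z")])
  sqrt(mean(rowSums((pa - pb)^2)))
}

#' Group poses into orientation types by greedy leader clustering
#'
#' Poses are processed in order of decreasing fitness.  Each pose joins
#' the first existing type whose representative lies within `threshold`
#' RMSD; otherwise it founds a new type.  Because processing is by
#' descending fitness, a type's founder is also its best-fitness member,
#' and type indices come out ordered by representative fitness (Type 1 =
#' best).  Deterministic given pose order and fitness values.
#'
#' @param poses list of [ligand_pose()] objects
#' @param threshold joining radius in Angstrom (default 2.0, aligned with
#'   the pose-correctness criterion)
#' @return object of class `pose_types`: list with `type` (named integer
#'   vector, pose id to 1-based type), `representative` (pose id per
#'   type), `rep_fitness`, `population`
#' @export
cluster_pose_types <- function(poses, threshold = 2.0) {
  if (length(poses) == 0) stop("no poses")
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  fit <- vapply(poses, `[[`, numeric(1), "fitness")
  ord <- order(-fit)
  ids <- vapply(poses, function(p) as.character(p$id), character(1))
  type <- stats::setNames(integer(length(poses)), ids)
  reps <- integer(0)   # indices into `poses` of type representatives
  for (i in ord) {
    assigned <- FALSE
    for (t in seq_along(reps)) {
      if (heavy_atom_rmsd(poses[[i]], poses[[reps[t]]]) <= threshold) {
        type[ids[i]] <- t
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      type[ids[i]] <- length(reps)
    }
  }
  structure(list(type = type,
                 representative = stats::setNames(ids[reps],
                                                  seq_along(reps)),
                 rep_fitness = stats::setNames(fit[reps], seq_along(reps)),
                 population = stats::setNames(
                   as.integer(table(factor(type, levels = seq_along(reps)))),
                   seq_along(reps))),
            class = "pose_types")
}

#' @export
print.pose_types <- function(x, ...) {
  cat("pose_types:", length(x$population), "orientation types over",
      length(x$type), "poses\n")
  for (t in seq_along(x$population))
    cat(sprintf("  Type %d: n=%d, representative %s (fitness %.2f)\n",
                t, x$population[[t]], x$representative[[t]],
                x$rep_fitness[[t]]))
  invisible(x)
}

#' Select the best orientation type
#'
#' By docking fitness (type whose representative scores highest) or by
#' averaged interaction energy (most negative).  Types with missing or
#' failed IE are skipped — a failed pose can never be selected.  Ties go
#' to the lowest type index, with a message.
#'
#' @param assignment a [cluster_pose_types()] result, or for
#'   `criterion = "avg_ie"` optionally just the number of types
#' @param criterion `"fitness"` or `"avg_ie"`
#' @param ie_by_type numeric vector of averaged IEs indexed by type
#'   (`NA` = missing/failed); required for `"avg_ie"`
#' @return selected type index (integer)
#' @export
select_best_pose <- function(assignment, criterion = c("fitness", "avg_ie"),
                             ie_by_type = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "fitness") {
    vals <- assignment$rep_fitness
    if (length(vals) == 0) stop("no eligible type")
    best <- which(vals == max(vals))
  } else {
    if (is.null(ie_by_type)) stop("ie_by_type required for avg_ie")
    vals <- as.numeric(ie_by_type)
    if (all(is.na(vals))) stop("no eligible type: all IEs missing")
    best <- which(vals == min(vals, na.rm = TRUE))
  }
  if (length(best) > 1)
    message("tie between types ", paste(best, collapse = ", "),
            "; selecting type ", min(best))
  as.integer(min(best))
}

#' Read ligand poses from a multi-model PDB file
#'
#' Each MODEL block is one pose; fitness scores are joined by pose id from
#' a data.frame (columns `pose_id`, `fitness`, optionally `rank`).
#'
#' @param path multi-model PDB file
#' @param scores optional scores data.frame
#' @return list of [ligand_pose()] objects
#' @export
read_poses_pdb <- function(path, scores = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  elem <- pdb$atom$elesy
  fix <- is.na(elem) | elem == ""
  elem[fix] <- substr(gsub("[^A-Za-z].*$", "", pdb$atom$elety[fix]), 1, 1)
  base <- data.frame(element = normalize_element(elem),
                     name = pdb$atom$elety, stringsAsFactors = FALSE)
  poses <- lapply(seq_len(nrow(xyz)), function(m) {
    a <- base
    m3 <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    a$x <- m3[, 1]; a$y <- m3[, 2]; a$z <- m3[, 3]
    ligand_pose(id = m, atoms = a)
  })
  join_scores(poses, scores)
}

#' Read ligand poses from a multi-record SDF (V2000) file
#'
#' Uses ChemmineR; each record is one pose.
#'
#' @inheritParams read_poses_pdb
#' @return list of [ligand_pose()] objects
#' @export
read_poses_sdf <- function(path, scores = NULL) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF requires the ChemmineR package")
  sdf <- ChemmineR::read.SDFset(path)
  poses <- lapply(seq_along(sdf), function(m) {
    ab <- ChemmineR::atomblock(sdf[[m]])
    el <- normalize_element(gsub("_.*$", "", rownames(ab)))
    ligand_pose(id = m, atoms = data.frame(
      element = el, name = rownames(ab),
      x = ab[, 1], y = ab[, 2], z = ab[, 3], stringsAsFactors = FALSE))
  })
  join_scores(poses, scores)
}

join_scores <- function(poses, scores) {
  if (is.null(scores)) return(poses)
  for (i in seq_along(poses)) {
    j <- match(poses[[i]]$id, scores$pose_id)
    if (!is.na(j)) {
      poses[[i]]$fitness <- scores$fitness[[j]]
      if (!is.null(scores$rank)) poses[[i]]$rank <- scores$rank[[j]]
    }
  }
  poses
}

#' Write ligand poses to a multi-model PDB file
#'
#' Inverse of [read_poses_pdb()] at PDB coordinate precision.
#'
#' @param poses list of [ligand_pose()] objects with identical atom tables
#' @param path output file
#' @return `path`, invisibly
#' @export
write_poses_pdb <- function(poses, path) {
  a <- poses[[1]]$atoms
  xyz <- do.call(rbind, lapply(poses, function(p)
    as.vector(t(as.matrix(p$atoms[, c("x", "y", "z")])))))
  n <- nrow(a)
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("HETATM", n),
                   resno = rep(1L, n), resid = rep("LIG", n),
                   eleno = seq_len(n), elety = a$name,
                   chain = rep("L", n), o = rep(1, n), b = rep(0, n),
                   elesy = toupper(a$element))
  invisible(path)
}
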