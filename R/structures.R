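# Structure containers and preparation: read/clean a protein-ligand complex
# and carve out the active-site shell around the bound ligand.

SOLVENT_RESNAMES <- c("HOH", "WAT", "DOD", "H2O", "SOL")
ION_RESNAMES <- c("NA", "K", "CL", "MG", "CA", "ZN", "MN", "FE", "CU",
                  "NI", "CO", "CD", "BR", "IOD", "SO4", "PO4")

#' Construct a protein-ligand complex structure
#'
#' A `kem_complex` holds one atom table for the whole complex plus a pointer
#' to the ligand unit.  A *unit* is one residue, the ligand, one solvent
#' molecule or one ion, identified by its `(chain, resno)` pair.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `name`
#'   (atom label), `element`, `altloc` (`""` when absent), `occupancy`,
#'   `x`, `y`, `z` (Angstrom) and optionally the classical-backend
#'   parameters `charge` (e), `sigma` (Angstrom), `epsilon` (kcal/mol) and a
#'   `role` column (`"protein-residue"`, `"ligand"`, `"solvent"`, `"ion"`).
#'   Missing parameter/role columns are filled with `NA` / inferred roles.
#' @param ligand unit key `"chain:resno"` naming the ligand unit, or `NULL`
#'   to auto-detect (the largest non-solvent, non-ion HETATM-role unit).
#' @param provenance character vector describing the source and
#'   preparation steps applied so far.
#'
#' @return An object of class `kem_complex`: a list with elements `atoms`,
#'   `ligand` (unit key or `NA`) and `provenance`.
#' @export
kem_complex <- function(atoms, ligand = NULL, provenance = character()) {
  req <- c("chain", "resno", "resname", "name", "element", "altloc",
           "occupancy", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  for (p in c("charge", "sigma", "epsilon"))
    if (is.null(atoms[[p]])) atoms[[p]] <- NA_real_
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  occ <- atoms$occupancy
  if (any(!is.na(occ) & (occ < 0 | occ > 1)))
    stop("occupancy outside [0, 1]")
  if (is.null(atoms$role)) atoms$role <- infer_roles(atoms)
  rownames(atoms) <- NULL
  dup <- duplicated(atoms[, c("chain", "resno", "name", "altloc")])
  if (any(dup))
    stop("duplicate atoms (same chain/resno/name/altloc): e.g. ",
         with(atoms[dup, ][1, ], paste(chain, resno, name, altloc)))
  if (is.null(ligand)) {
    lig_units <- unique(unit_key(atoms)[atoms$role == "ligand"])
    ligand <- if (length(lig_units) > 0) lig_units[[1]] else NA_character_
  }
  if (!is.na(ligand)) {
    sel <- unit_key(atoms) == ligand
    if (!any(sel)) stop("ligand unit not found: ", ligand)
    atoms$role[sel] <- "ligand"
    other <- atoms$role == "ligand" & !sel
    atoms$role[other] <- "protein-residue"
  }
  structure(list(atoms = atoms, ligand = ligand, provenance = provenance),
            class = "kem_complex")
}

unit_key <- function(atoms) paste(atoms$chain, atoms$resno, sep = ":")

infer_roles <- function(atoms) {
  rn <- toupper(atoms$resname)
  role <- rep("protein-residue", nrow(atoms))
  role[rn %in% SOLVENT_RESNAMES] <- "solvent"
  role[rn %in% ION_RESNAMES] <- "ion"
  role
}

#' @export
print.kem_complex <- function(x, ...) {
  u <- split(seq_len(nrow(x$atoms)), unit_key(x$atoms))
  cat("kem_complex:", nrow(x$atoms), "atoms in", length(u), "units;",
      "ligand =", x$ligand, "\n")
  cat("roles:", paste(names(table(x$atoms$role)),
                      table(x$atoms$role), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the units of a complex as residue objects
#'
#' @param s a [kem_complex()]
#' @param roles restrict to these roles (default: all)
#' @return Named list of `residue_unit` objects (key `"chain:resno"`), each
#'   a list with `chain`, `resno`, `resname`, `role` and an `atoms`
#'   data.frame.
#' @export
complex_units <- function(s, roles = NULL) {
  keys <- unit_key(s$atoms)
  idx <- split(seq_len(nrow(s$atoms)), factor(keys, levels = unique(keys)))
  units <- lapply(idx, function(i) {
    a <- s$atoms[i, , drop = FALSE]
    structure(list(chain = a$chain[[1]], resno = a$resno[[1]],
                   resname = a$resname[[1]], role = a$role[[1]],
                   atoms = a),
              class = "residue_unit")
  })
  if (!is.null(roles)) units <- Filter(function(u) u$role %in% roles, units)
  units
}

#' @rdname complex_units
#' @export
ligand_unit <- function(s) {
  if (is.na(s$ligand)) stop("complex has no ligand unit flagged")
  complex_units(s)[[s$ligand]]
}

#' Read a protein-ligand complex from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), honouring altloc and occupancy
#' columns.  Solvent is recognised by residue name (HOH/WAT/DOD, extendable
#' via `solvent`), monatomic ions by residue name whitelist.  The ligand is
#' the largest remaining HETATM unit unless named explicitly.
#'
#' @param path PDB file
#' @param ligand optional unit key `"chain:resno"` or residue name selecting
#'   the ligand unit
#' @param solvent extra residue names to treat as solvent
#' @return a [kem_complex()]
#' @export
read_pdb <- function(path, ligand = NULL, solvent = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[[i]]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))))
      stop("malformed ATOM/HETATM record at line ", i, " of ", path)
  }
  if (!any(rec)) stop("empty structure: no ATOM/HETATM records in ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  elem <- a$elesy
  fix <- is.na(elem) | elem == ""
  elem[fix] <- substr(gsub("[^A-Za-z].*$", "", a$elety[fix]), 1, 1)
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    resname = a$resid,
    name = a$elety,
    element = normalize_element(elem),
    altloc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
    occupancy = ifelse(is.na(a$o), 1, a$o),
    x = a$x, y = a$y, z = a$z,
    rectype = a$type,
    stringsAsFactors = FALSE)
  atoms$role <- infer_roles(atoms)
  atoms$role[atoms$resname %in% toupper(solvent)] <- "solvent"
  lig_key <- resolve_ligand_key(atoms, ligand)
  atoms$role[!is.na(lig_key) & unit_key(atoms) == lig_key] <- "ligand"
  atoms$rectype <- NULL
  kem_complex(atoms, ligand = lig_key,
              provenance = paste("read_pdb:", basename(path)))
}

normalize_element <- function(e) {
  e <- trimws(e)
  paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e))))
}

resolve_ligand_key <- function(atoms, ligand) {
  keys <- unit_key(atoms)
  if (!is.null(ligand)) {
    if (grepl(":", ligand)) {
      if (!any(keys == ligand)) stop("ligand unit not found: ", ligand)
      return(ligand)
    }
    hit <- unique(keys[atoms$resname == ligand])
    if (length(hit) == 0) stop("no unit with residue name ", ligand)
    return(hit[[1]])
  }
  het <- atoms$rectype == "HETATM" & atoms$role == "protein-residue"
  if (!any(het)) return(NA_character_)
  counts <- table(keys[het])
  names(counts)[which.max(counts)]
}

#' Write a complex structure to a PDB file
#'
#' Inverse of [read_pdb()] (coordinates to PDB's 3-decimal precision);
#' ligand/solvent/ion units are emitted as HETATM records.
#'
#' @param s a [kem_complex()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  type <- ifelse(a$role == "protein-residue", "ATOM", "HETATM")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = type, resno = a$resno, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = a$chain, o = a$occupancy,
                   b = rep(0, nrow(a)), elesy = toupper(a$element))
  invisible(path)
}

#' Keep only the major conformer at each alternate-location site
#'
#' For every `(chain, resno, atom name)` group with multiple altloc codes
#' the highest-occupancy copy is retained (ties: alphabetically first
#' altloc) and the altloc field is cleared.  Idempotent; atoms without
#' altlocs pass through unchanged.
#'
#' @param s a [kem_complex()]
#' @return a [kem_complex()] with one copy per atom site
#' @export
select_major_conformer <- function(s) {
  a <- s$atoms
  ord <- order(a$chain, a$resno, a$name, -a$occupancy, a$altloc)
  a <- a[ord, , drop = FALSE]
  keep <- !duplicated(a[, c("chain", "resno", "name")])
  n_drop <- sum(!keep)
  a <- a[keep, , drop = FALSE]
  a$altloc <- ""
  a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  rownames(a) <- NULL
  kem_complex(a, ligand = s$ligand,
              provenance = c(s$provenance,
                             paste0("select_major_conformer: removed ",
                                    n_drop, " alternate conformer atoms")))
}

#' Remove solvent and ion units
#'
#' @param s a [kem_complex()]
#' @return a [kem_complex()] without solvent/ion units; the count removed
#'   is appended to the provenance log.
#' @export
strip_solvent <- function(s) {
  drop <- s$atoms$role %in% c("solvent", "ion")
  n_units <- length(unique(unit_key(s$atoms)[drop]))
  a <- s$atoms[!drop, , drop = FALSE]
  if (nrow(a) == 0) stop("stripping solvent left no atoms")
  rownames(a) <- NULL
  kem_complex(a, ligand = s$ligand,
              provenance = c(s$provenance,
                             paste0("strip_solvent: removed ", n_units,
                                    " solvent/ion units")))
}

#' Select the active-site residues within a sphere
#'
#' Returns every protein residue having at least one atom within `radius`
#' (closed boundary, minimum atom-atom distance) of any atom of the center
#' unit.  The ligand, solvent and ions are never part of the returned set.
#'
#' @param s a [kem_complex()]
#' @param center unit key `"chain:resno"`, or `"ligand"` for the flagged
#'   ligand unit
#' @param radius sphere radius in Angstrom (> 0)
#' @return named list of `residue_unit` objects (see [complex_units()])
#' @export
select_active_site <- function(s, center = "ligand", radius = 5.0) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  units <- complex_units(s)
  ckey <- if (identical(center, "ligand")) s$ligand else center
  if (is.na(ckey) || !ckey %in% names(units))
    stop("unknown center unit: ", center)
  cxyz <- as.matrix(units[[ckey]]$atoms[, c("x", "y", "z")])
  hits <- Filter(function(u) {
    if (u$role != "protein-residue") return(FALSE)
    key <- paste(u$chain, u$resno, sep = ":")
    if (key == ckey) return(FALSE)
    min_cross_dist(as.matrix(u$atoms[, c("x", "y", "z")]), cxyz) <= radius
  }, units)
  hits
}

min_cross_dist <- function(a, b) {
  ## smallest pairwise distance between two coordinate matrices
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}
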