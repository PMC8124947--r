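# Kernel fragmentation: cut the active-site complex into single-residue
# kernels plus the ligand kernel, cap severed bonds with hydrogens, and
# attach formal charge / spin multiplicity to each kernel.

KERNEL_ATOM_COLS <- c("element", "name", "x", "y", "z",
                      "charge", "sigma", "epsilon")

#' Construct a kernel
#'
#' A kernel is the unit of energy calculation: the atoms of one residue (or
#' the ligand) plus any hydrogen caps added where covalent bonds were
#' severed by the fragmentation.
#'
#' @param label unique text id
#' @param atoms data.frame of the original atoms (columns `element`,
#'   `name`, `x`, `y`, `z`, optionally `charge`, `sigma`, `epsilon`)
#' @param origin `"ligand"` or the source residue key/name
#' @param caps data.frame of added cap hydrogens (same columns), default
#'   none
#' @param formal_charge integer formal charge in e (`NA` until assigned)
#' @param multiplicity positive integer spin multiplicity
#' @return object of class `kem_kernel`
#' @export
kernel <- function(label, atoms, origin, caps = NULL,
                   formal_charge = NA_integer_, multiplicity = 1L) {
  if (nrow(atoms) == 0) stop("kernel ", label, " has zero atoms")
  for (p in c("charge", "sigma", "epsilon"))
    if (is.null(atoms[[p]])) atoms[[p]] <- NA_real_
  atoms <- atoms[, KERNEL_ATOM_COLS]
  rownames(atoms) <- NULL
  if (is.null(caps)) caps <- atoms[0, , drop = FALSE]
  if (nrow(caps) > 0 && any(caps$element != "H"))
    stop("caps must be hydrogens")
  if (!is.na(multiplicity) && multiplicity < 1)
    stop("multiplicity must be >= 1")
  structure(list(label = label, atoms = atoms, caps = caps,
                 origin = origin, formal_charge = formal_charge,
                 multiplicity = as.integer(multiplicity)),
            class = "kem_kernel")
}

#' @export
print.kem_kernel <- function(x, ...) {
  cat("kernel", x$label, "(", x$origin, "):", nrow(x$atoms), "atoms +",
      nrow(x$caps), "caps; charge", x$formal_charge,
      "mult", x$multiplicity, "\n")
  invisible(x)
}

#' All atoms of a kernel, caps included
#'
#' @param k a [kernel()]
#' @return data.frame of original atoms followed by cap hydrogens
#' @export
kernel_atoms <- function(k) rbind(k$atoms, k$caps)

#' Fragment an active site into kernels
#'
#' One kernel per residue plus the ligand kernel, ligand first.  Every
#' input atom lands in exactly one kernel (the partition property); the
#' function verifies this and aborts otherwise.  Caps are not added here —
#' see [cap_kernel()] and [backbone_severed_bonds()].
#'
#' @param site named list of `residue_unit` objects (from
#'   [select_active_site()] or [complex_units()])
#' @param ligand the ligand `residue_unit` (from [ligand_unit()])
#' @return list of [kernel()] objects; element 1 has origin `"ligand"`
#' @export
fragment_complex <- function(site, ligand) {
  if (length(site) == 0) stop("active site is empty")
  if (is.null(ligand)) stop("ligand unit is required")
  units <- c(list(ligand = ligand), site)
  n_in <- sum(vapply(units, function(u) nrow(u$atoms), integer(1)))
  kerns <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[[i]]
    if (nrow(u$atoms) == 0)
      stop("residue with zero atoms: ", u$resname, " ", u$resno)
    lab <- if (i == 1) "ligand" else paste(u$chain, u$resno, u$resname,
                                           sep = ":")
    org <- if (i == 1) "ligand" else lab
    kerns[[i]] <- kernel(lab, u$atoms, origin = org)
  }
  labs <- vapply(kerns, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("duplicate kernel labels")
  n_out <- sum(vapply(kerns, function(k) nrow(k$atoms), integer(1)))
  if (n_out != n_in)
    stop("fragmentation lost or duplicated atoms (", n_in, " in, ",
         n_out, " out)")
  names(kerns) <- labs
  kerns
}

#' Default hydrogen cap bond lengths
#'
#' Standard covalent X-H distances keyed by the kernel-side element of the
#' severed bond.
#'
#' @return data.frame with columns `element` and `length` (Angstrom)
#' @export
default_cap_rules <- function() {
  data.frame(element = c("C", "N", "O", "S"),
             length = c(1.09, 1.01, 0.96, 1.34))
}

#' Cap severed bonds of a kernel with hydrogens
#'
#' For each severed bond with inside atom `a` and outside partner `b`, a
#' hydrogen is placed on the ray from `a` toward `b` at the rule's bond
#' length for `a`'s element, preserving the bond direction exactly.
#'
#' @param k a [kernel()]
#' @param severed_bonds list of bonds, each a list with `inside` (atom name
#'   in `k`), `outside_xyz` (length-3 numeric, position of the lost
#'   partner) and optionally `outside_name` for error messages
#' @param rules cap-length table as from [default_cap_rules()]
#' @param cap_params named list of classical parameters given to cap
#'   hydrogens (`charge`, `sigma`, `epsilon`)
#' @return the kernel with one cap H per severed bond appended
#' @export
cap_kernel <- function(k, severed_bonds, rules = default_cap_rules(),
                       cap_params = list(charge = 0, sigma = 2.5,
                                         epsilon = 0.03)) {
  if (length(severed_bonds) == 0) return(k)
  caps <- k$caps
  for (b in severed_bonds) {
    ia <- match(b$inside, k$atoms$name)
    if (is.na(ia))
      stop("severed bond endpoint ", b$inside, " not inside kernel ",
           k$label)
    bxyz <- as.numeric(b$outside_xyz)
    axyz <- as.numeric(k$atoms[ia, c("x", "y", "z")])
    inside_b <- any(abs(k$atoms$x - bxyz[1]) < 1e-6 &
                    abs(k$atoms$y - bxyz[2]) < 1e-6 &
                    abs(k$atoms$z - bxyz[3]) < 1e-6)
    if (inside_b)
      stop("severed bond has both endpoints inside kernel ", k$label)
    v <- bxyz - axyz
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("severed bond of zero length in kernel ", k$label)
    el <- k$atoms$element[[ia]]
    len <- rules$length[match(el, rules$element)]
    if (is.na(len))
      stop("no cap rule for element ", el, " (kernel ", k$label, ")")
    hxyz <- axyz + len * v / nv
    caps <- rbind(caps, data.frame(
      element = "H", name = paste0("HCP", nrow(caps) + 1),
      x = hxyz[1], y = hxyz[2], z = hxyz[3],
      charge = cap_params$charge, sigma = cap_params$sigma,
      epsilon = cap_params$epsilon))
  }
  rownames(caps) <- NULL
  k$caps <- caps
  k
}

#' Severed peptide bonds implied by a residue-per-kernel fragmentation
#'
#' The backbone is cut at the amide C-N bond between consecutive residues
#' of the same chain.  For each kernel this returns the severed-bond list
#' suitable for [cap_kernel()]: the acyl side is capped at its carbonyl C,
#' the amine side at its backbone N.
#'
#' @param site named list of `residue_unit` objects
#' @return named list (by kernel label) of severed-bond lists
#' @export
backbone_severed_bonds <- function(site) {
  out <- stats::setNames(vector("list", length(site)), names(site))
  info <- data.frame(
    key = names(site),
    chain = vapply(site, `[[`, character(1), "chain"),
    resno = vapply(site, function(u) as.integer(u$resno), integer(1)))
  get_atom <- function(u, nm) {
    i <- match(nm, u$atoms$name)
    if (is.na(i)) NULL else u$atoms[i, , drop = FALSE]
  }
  for (i in seq_len(nrow(info))) {
    j <- which(info$chain == info$chain[i] & info$resno == info$resno[i] + 1)
    if (length(j) != 1) next
    ui <- site[[i]]; uj <- site[[j]]
    ci <- get_atom(ui, "C"); nj <- get_atom(uj, "N")
    if (is.null(ci) || is.null(nj)) next
    lab_i <- names(site)[[i]]; lab_j <- names(site)[[j]]
    out[[lab_i]] <- c(out[[lab_i]], list(list(
      inside = "C", outside_xyz = as.numeric(nj[, c("x", "y", "z")]),
      outside_name = paste0(lab_j, ":N"))))
    out[[lab_j]] <- c(out[[lab_j]], list(list(
      inside = "N", outside_xyz = as.numeric(ci[, c("x", "y", "z")]),
      outside_name = paste0(lab_i, ":C"))))
  }
  out
}

#' Default residue formal-charge templates
#'
#' Physiological-pH conventions: ASP/GLU -1, LYS/ARG +1, HIS and all other
#' standard residues 0.
#'
#' @return named integer vector, residue name to formal charge
#' @export
default_charge_templates <- function() {
  res <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  ch <- stats::setNames(rep(0L, length(res)), res)
  ch[c("ASP", "GLU")] <- -1L
  ch[c("LYS", "ARG")] <- +1L
  ch
}

#' Assign formal charge and spin multiplicity to a kernel
#'
#' Charge comes from the residue-name template unless overridden; ligand
#' kernels default to 0 unless a `charge` override is supplied (e.g. -1 for
#' a carboxylate ligand).  Multiplicity defaults to 1 (closed shell).
#'
#' @param k a [kernel()]
#' @param templates named residue-to-charge map, see
#'   [default_charge_templates()]
#' @param charge explicit override (integer e), wins over the template
#' @param multiplicity explicit override (positive integer)
#' @return the kernel with `formal_charge` and `multiplicity` set
#' @export
assign_charge_multiplicity <- function(k, templates = default_charge_templates(),
                                       charge = NULL, multiplicity = NULL) {
  if (is.null(charge)) {
    if (identical(k$origin, "ligand")) {
      charge <- 0L
    } else {
      resname <- sub("^.*:", "", k$origin)
      charge <- unname(templates[resname])
      if (length(charge) != 1 || is.na(charge))
        stop("no charge template for residue ", resname,
             " and no override given (kernel ", k$label, ")")
    }
  }
  k$formal_charge <- as.integer(charge)
  k$multiplicity <- as.integer(if (is.null(multiplicity)) 1L else multiplicity)
  if (k$multiplicity < 1) stop("multiplicity must be >= 1")
  k
}
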