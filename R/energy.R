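# Kernel energy backends.  The built-in classical backend (point charges +
# Lennard-Jones, exactly pairwise-additive) exists so the KEM assembly can
# be validated against brute force; the external-QM interface writes
# Gaussian-dialect counterpoise jobs and parses their logs.

COULOMB_K <- 332.0636   # kcal A mol^-1 e^-2
HARTREE_KCAL <- 627.5095

#' Construct an energy record
#'
#' Houses the energies of a single kernel or a kernel pair.  `kind`
#' distinguishes backends that report total energies of the subject system
#' (classical backend; interaction energies are formed by differencing)
#' from those that report complexation/interaction energies directly
#' (counterpoise log parser).
#'
#' @param subject kernel label, or pair label `"a|b"`
#' @param e_raw raw energy, kcal/mol (`NA` when failed)
#' @param e_cp counterpoise-corrected energy, kcal/mol (pairs only)
#' @param kind `"total"` or `"interaction"`
#' @param status `"ok"` or `"failed"`
#' @return object of class `energy_record`
#' @export
energy_record <- function(subject, e_raw = NA_real_, e_cp = NA_real_,
                          kind = c("total", "interaction"),
                          status = c("ok", "failed")) {
  kind <- match.arg(kind)
  status <- match.arg(status)
  if (status == "failed") {
    e_raw <- NA_real_
    e_cp <- NA_real_
  } else if (!is.finite(e_raw)) {
    stop("ok record must carry a finite e_raw (subject ", subject, ")")
  }
  structure(list(subject = subject, e_raw = e_raw, e_cp = e_cp,
                 kind = kind, status = status),
            class = "energy_record")
}

#' @export
print.energy_record <- function(x, ...) {
  cat(sprintf("energy_record %s [%s/%s]: raw %s, cp %s kcal/mol\n",
              x$subject, x$kind, x$status,
              format(x$e_raw), format(x$e_cp)))
  invisible(x)
}

pair_label <- function(a, b) paste(sort(c(a, b)), collapse = "|")

check_params <- function(atoms, label) {
  bad <- !is.finite(atoms$charge) | !is.finite(atoms$sigma) |
    !is.finite(atoms$epsilon)
  if (any(bad))
    stop("missing classical parameters on atom(s) ",
         paste(atoms$name[bad], collapse = ", "), " of ", label)
}

#' Classical pairwise energy of an atom set
#'
#' Sum over distinct atom pairs of `332.0636 q_i q_j / r` plus
#' `4 eps [(sig/r)^12 - (sig/r)^6]` with Lorentz-Berthelot combination
#' (arithmetic-mean sigma, geometric-mean epsilon).  No cutoff, no
#' switching: the potential is exactly pairwise additive.
#'
#' @param atoms data.frame with `x`, `y`, `z`, `charge`, `sigma`, `epsilon`
#' @return energy in kcal/mol (0 for fewer than two atoms)
#' @keywords internal
classical_energy <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(0)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  up <- upper.tri(d2)
  r <- sqrt(pmax(d2[up], 0))
  if (any(r < 1e-12)) stop("coincident atoms (r = 0) in energy evaluation")
  q <- atoms$charge
  qq <- outer(q, q)[up]
  sig <- outer(atoms$sigma, atoms$sigma, "+")[up] / 2
  eps <- sqrt(outer(atoms$epsilon, atoms$epsilon))[up]
  sr6 <- (sig / r)^6
  sum(COULOMB_K * qq / r + 4 * eps * (sr6^2 - sr6))
}

#' Single-kernel energy, classical backend
#'
#' @param k a [kernel()]; every atom (caps included) must carry `charge`,
#'   `sigma` and `epsilon`
#' @return an [energy_record()] of kind `"total"`
#' @export
classical_single_energy <- function(k) {
  a <- kernel_atoms(k)
  check_params(a, k$label)
  energy_record(k$label, e_raw = classical_energy(a), kind = "total")
}

#' Double-kernel energy, classical backend
#'
#' Energy of the union atom set under the same potential.  A classical
#' model has no basis sets, so the counterpoise-corrected energy is
#' identical to the raw one (`e_cp == e_raw`): the CP/raw averaging
#' degenerates, which is exactly what makes the backend a clean test rig
#' for the averaging plumbing.
#'
#' @param ka,kb [kernel()] objects with disjoint atoms
#' @return an [energy_record()] of kind `"total"` with `e_cp == e_raw`
#' @export
classical_pair_energy <- function(ka, kb) {
  if (identical(ka$label, kb$label))
    stop("pair energy of a kernel with itself")
  a <- kernel_atoms(ka)
  b <- kernel_atoms(kb)
  check_params(a, ka$label)
  check_params(b, kb$label)
  if (min_cross_dist(as.matrix(a[, c("x", "y", "z")]),
                     as.matrix(b[, c("x", "y", "z")])) < 1e-6)
    stop("kernels ", ka$label, " and ", kb$label, " have overlapping atoms")
  e <- classical_energy(rbind(a, b))
  energy_record(pair_label(ka$label, kb$label), e_raw = e, e_cp = e,
                kind = "total")
}

#' Compute all energy records needed for a KEM assembly
#'
#' Runs the classical backend over every single kernel and over kernel
#' pairs — either ligand-residue pairs only (enough for the protein-ligand
#' interaction energy) or all unordered pairs (needed for the total
#' energy).
#'
#' @param kernels list of [kernel()] objects, ligand first (as returned by
#'   [fragment_complex()])
#' @param pairs `"ligand"` or `"all"`
#' @return list with named lists `singles` (by kernel label) and `pairs`
#'   (by `"a|b"` label)
#' @export
classical_energy_records <- function(kernels, pairs = c("ligand", "all")) {
  pairs <- match.arg(pairs)
  labs <- vapply(kernels, `[[`, character(1), "label")
  singles <- lapply(kernels, classical_single_energy)
  names(singles) <- labs
  prs <- list()
  n <- length(kernels)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (pairs == "ligand" && i != 1) next
      rec <- classical_pair_energy(kernels[[i]], kernels[[j]])
      prs[[rec$subject]] <- rec
    }
  }
  list(singles = singles, pairs = prs)
}

fmt_atom_line <- function(atoms, frag) {
  sprintf(" %s(Fragment=%d)  %14.8f %14.8f %14.8f",
          atoms$element, frag, atoms$x, atoms$y, atoms$z)
}

#' Write a two-fragment counterpoise job file
#'
#' Emits a Gaussian-dialect input: a route line with the level of theory
#' and a `Counterpoise=2` directive, a combined charge/multiplicity header
#' (total pair first, then per-fragment), and atom lines tagged with their
#' fragment index.  Cap hydrogens travel with their kernel's fragment.
#' Output is byte-stable for identical input.
#'
#' @param ka,kb [kernel()] objects with assigned charge and multiplicity
#' @param level level-of-theory string, e.g. `"MP2/6-311G(d,p)"`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_counterpoise_job <- function(ka, kb, level, path) {
  for (k in list(ka, kb))
    if (is.na(k$formal_charge) || is.na(k$multiplicity))
      stop("kernel ", k$label,
           " has unassigned charge/multiplicity; run",
           " assign_charge_multiplicity() first")
  qa <- ka$formal_charge; qb <- kb$formal_charge
  ma <- ka$multiplicity; mb <- kb$multiplicity
  lines <- c(
    sprintf("# %s Counterpoise=2", level),
    "",
    sprintf("counterpoise: %s | %s", ka$label, kb$label),
    "",
    sprintf("%d,%d %d,%d %d,%d", qa + qb, ma + mb - 1L, qa, ma, qb, mb),
    fmt_atom_line(kernel_atoms(ka), 1L),
    fmt_atom_line(kernel_atoms(kb), 2L),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Parse a counterpoise log into an energy record
#'
#' Recognises the `complexation energy = <value> (raw)` and `(corrected)`
#' summary lines (values in Hartree, converted to kcal/mol by 627.5095)
#' and requires a normal-termination marker.  Anything unparseable — a
#' truncated or aborted log — yields a record with status `"failed"`,
#' never an exception, so a failed pose propagates as a missing value.
#'
#' @param path log file
#' @return an [energy_record()] of kind `"interaction"`; `subject` is taken
#'   from a `counterpoise: a | b` echo line when present
#' @export
parse_counterpoise_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  subject <- NA_character_
  sub_ln <- grep("^\\s*counterpoise:", lines, value = TRUE)
  if (length(sub_ln) > 0) {
    parts <- trimws(strsplit(sub(".*counterpoise:", "", sub_ln[[1]]),
                             "\\|")[[1]])
    if (length(parts) == 2) subject <- pair_label(parts[1], parts[2])
  }
  grab <- function(tag) {
    ln <- grep(paste0("complexation energy\\s*=.*\\(", tag, "\\)"), lines,
               value = TRUE)
    if (length(ln) == 0) return(NA_real_)
    suppressWarnings(as.numeric(sub(
      ".*complexation energy\\s*=\\s*(-?[0-9.Ee+]+).*", "\\1", ln[[1]])))
  }
  raw_h <- grab("raw")
  cp_h <- grab("corrected")
  ok <- any(grepl("Normal termination", lines)) &&
    is.finite(raw_h) && is.finite(cp_h)
  if (!ok)
    return(energy_record(subject, kind = "interaction", status = "failed"))
  energy_record(subject, e_raw = raw_h * HARTREE_KCAL,
                e_cp = cp_h * HARTREE_KCAL, kind = "interaction")
}

#' Write a synthetic counterpoise log
#'
#' Emits a minimal log in the dialect [parse_counterpoise_log()] reads,
#' with planted raw/corrected complexation energies.  Exists so the
#' writer-to-parser path is testable without any quantum-chemistry
#' program; synthetic by construction.
#'
#' @param path output file
#' @param subject pair label echoed into the log (`"a|b"`)
#' @param raw_hartree,cp_hartree planted complexation energies, Hartree
#' @param terminated write the normal-termination marker? `FALSE` mimics
#'   an aborted job
#' @return `path`, invisibly
#' @export
write_synthetic_cp_log <- function(path, subject, raw_hartree, cp_hartree,
                                   terminated = TRUE) {
  parts <- strsplit(subject, "|", fixed = TRUE)[[1]]
  lines <- c(
    " Entering Gaussian System (synthetic log)",
    sprintf(" counterpoise: %s | %s", parts[1], parts[length(parts)]),
    " Counterpoise: doing DCBS calculation for fragment   1",
    sprintf(" Counterpoise: corrected energy = %16.9f", cp_hartree),
    sprintf(" complexation energy = %14.9f (raw)", raw_hartree),
    sprintf(" complexation energy = %14.9f (corrected)", cp_hartree))
  if (terminated)
    lines <- c(lines, " Normal termination of Gaussian 09")
  writeLines(lines, path)
  invisible(path)
}
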