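# Small builders shared across test files.  Everything is generated in
# code; no stored binary fixtures.

# a bare kernel from coordinates and classical parameters
toy_kernel <- function(label, xyz, q = 0, sigma = 3, epsilon = 0.1,
                       element = "C", origin = label) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  kernel(label,
         data.frame(element = rep(element, length.out = n),
                    name = paste0("A", seq_len(n)),
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    charge = rep(q, length.out = n),
                    sigma = rep(sigma, length.out = n),
                    epsilon = rep(epsilon, length.out = n)),
         origin = origin)
}

# an energy_record with given raw energy (classical "total" convention)
rec_total <- function(subject, e_raw, e_cp = NA_real_) {
  energy_record(subject, e_raw = e_raw, e_cp = e_cp, kind = "total")
}

# a pose from a coordinate matrix
toy_pose <- function(id, xyz, fitness = NA_real_, element = "C") {
  xyz <- matrix(xyz, ncol = 3)
  ligand_pose(id, data.frame(
    element = rep(element, length.out = nrow(xyz)),
    name = paste0("A", seq_len(nrow(xyz))),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]), fitness = fitness)
}

# one correctly column-aligned ATOM/HETATM record
pdb_line <- function(rec, serial, name, alt, resn, chain, resno,
                     x, y, z, occ = 1, el = "C") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name, alt, resn, chain, resno, x, y, z, occ, 0, el)
}

# minimal hand-written PDB text (one ATOM, one HETATM water)
minimal_pdb_lines <- function() {
  c(pdb_line("ATOM", 1, "CA", " ", "GLY", "A", 1, 0, 0, 0, el = "C"),
    pdb_line("HETATM", 2, "O", " ", "HOH", "A", 2, 3, 0, 0, el = "O"))
}
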