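test_that("fragmentation yields ligand-first kernels forming a partition", {
  cx <- make_complex(synthetic_spec(seed = 2))
  site <- complex_units(cx, roles = "protein-residue")
  kerns <- fragment_complex(site, ligand_unit(cx))
  expect_length(kerns, length(site) + 1)
  expect_equal(kerns[[1]]$origin, "ligand")
  # set-partition oracle: union of kernel atoms == input atoms, disjoint
  keys <- unlist(lapply(kerns, function(k)
    paste(k$origin, k$atoms$name)))
  expect_equal(anyDuplicated(keys), 0L)
  expect_equal(sum(vapply(kerns, function(k) nrow(k$atoms), integer(1))),
               nrow(cx$atoms))
  expect_error(fragment_complex(list(), ligand_unit(cx)), "empty")
  expect_error(fragment_complex(site, NULL), "ligand")
})

test_that("caps sit on the severed-bond ray at the rule length", {
  k <- toy_kernel("k", c(0, 0, 0), element = "C")
  capped <- cap_kernel(k, list(list(inside = "A1",
                                    outside_xyz = c(1.5, 0, 0))))
  expect_equal(nrow(capped$caps), 1)
  expect_equal(unlist(capped$caps[1, c("x", "y", "z")]),
               c(x = 1.09, y = 0, z = 0))
  # diagonal bond, N-H rule: cap at 1.01 * (1,1,1)/sqrt(3)
  kn <- toy_kernel("kn", c(0, 0, 0), element = "N")
  capped2 <- cap_kernel(kn, list(list(inside = "A1",
                                      outside_xyz = c(1, 1, 1))))
  expect_equal(unlist(capped2$caps[1, c("x", "y", "z")]),
               c(x = 1.01, y = 1.01, z = 1.01) / sqrt(3),
               tolerance = 1e-12)
  # direction is preserved exactly
  v_bond <- c(1, 1, 1) / sqrt(3)
  v_cap <- unlist(capped2$caps[1, c("x", "y", "z")])
  v_cap <- v_cap / sqrt(sum(v_cap^2))
  expect_lt(acos(min(1, sum(v_bond * v_cap))), 1e-9)
  # identity without severed bonds; one cap per bond
  expect_identical(cap_kernel(k, list()), k)
})

test_that("cap_kernel rejects bonds not crossing the kernel boundary", {
  k <- toy_kernel("k", rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_error(cap_kernel(k, list(list(inside = "A1",
                                       outside_xyz = c(1.5, 0, 0)))),
               "both endpoints")
  expect_error(cap_kernel(k, list(list(inside = "Z9",
                                       outside_xyz = c(9, 0, 0)))),
               "not inside")
})

test_that("backbone amide cuts produce two caps per severed bond", {
  mk_res <- function(resno, xoff) {
    structure(list(chain = "A", resno = resno, resname = "GLY",
                   role = "protein-residue",
                   atoms = data.frame(
                     element = c("N", "C"), name = c("N", "C"),
                     x = c(xoff, xoff + 1.2), y = 0, z = 0,
                     charge = 0, sigma = 3, epsilon = 0.1)),
              class = "residue_unit")
  }
  site <- list("A:1:GLY" = mk_res(1, 0), "A:2:GLY" = mk_res(2, 2.5))
  bonds <- backbone_severed_bonds(site)
  expect_length(bonds[["A:1:GLY"]], 1)
  expect_length(bonds[["A:2:GLY"]], 1)
  expect_equal(bonds[["A:1:GLY"]][[1]]$inside, "C")
  expect_equal(bonds[["A:2:GLY"]][[1]]$inside, "N")
  lig <- mk_res(99, 50)
  kerns <- fragment_complex(site, lig)
  k1 <- cap_kernel(kerns[["A:1:GLY"]], bonds[["A:1:GLY"]])
  expect_equal(nrow(k1$caps), 1)
  expect_equal(k1$caps$element, "H")
})

test_that("charge templates apply with override path and error on unknowns", {
  gly <- toy_kernel("A:1:GLY", c(0, 0, 0), origin = "A:1:GLY")
  expect_equal(assign_charge_multiplicity(gly)$formal_charge, 0L)
  expect_equal(assign_charge_multiplicity(gly)$multiplicity, 1L)
  asp <- toy_kernel("A:2:ASP", c(0, 0, 0), origin = "A:2:ASP")
  expect_equal(assign_charge_multiplicity(asp)$formal_charge, -1L)
  lys <- toy_kernel("A:3:LYS", c(0, 0, 0), origin = "A:3:LYS")
  expect_equal(assign_charge_multiplicity(lys)$formal_charge, 1L)
  # carboxylate-style ligand via explicit override
  lig <- toy_kernel("ligand", c(0, 0, 0), origin = "ligand")
  expect_equal(assign_charge_multiplicity(lig, charge = -1)$formal_charge,
               -1L)
  unk <- toy_kernel("A:4:XYZ", c(0, 0, 0), origin = "A:4:XYZ")
  expect_error(assign_charge_multiplicity(unk), "XYZ")
})

test_that("kernel formal charges sum to the configured total charge", {
  for (tc in c(0L, -2L, 1L)) {
    cx <- make_complex(synthetic_spec(seed = 31, total_charge = tc))
    kerns <- fragment_complex(complex_units(cx, roles = "protein-residue"),
                              ligand_unit(cx))
    kerns <- lapply(kerns, assign_charge_multiplicity)
    expect_equal(sum(vapply(kerns, `[[`, integer(1), "formal_charge")), tc)
  }
})

test_that("kernel sets survive a JSON round trip", {
  cx <- make_complex(synthetic_spec(seed = 13))
  kerns <- fragment_complex(complex_units(cx, roles = "protein-residue"),
                            ligand_unit(cx))
  kerns <- lapply(kerns, assign_charge_multiplicity)
  kerns[[2]] <- cap_kernel(kerns[[2]], list(list(
    inside = kerns[[2]]$atoms$name[1], outside_xyz = c(50, 50, 50))))
  f <- withr::local_tempfile(fileext = ".json")
  write_kernels_json(kerns, f)
  back <- read_kernels_json(f)
  expect_equal(names(back), names(kerns))
  for (nm in names(kerns)) {
    expect_equal(back[[nm]]$atoms, kerns[[nm]]$atoms)
    expect_equal(back[[nm]]$formal_charge, kerns[[nm]]$formal_charge)
  }
  expect_equal(back[[2]]$caps$x, kerns[[2]]$caps$x)
})
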