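test_that("in-place heavy-atom RMSD follows hand arithmetic", {
  p0 <- toy_pose(1, rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(heavy_atom_rmsd(p0, p0), 0)
  # rigid translation by (3,4,0): RMSD = 5 exactly (no superposition)
  shifted <- toy_pose(2, rbind(c(3, 4, 0), c(5, 4, 0)))
  expect_equal(heavy_atom_rmsd(p0, shifted), 5)
  # 2-atom toy with displacements 1 and 3: sqrt((1+9)/2)
  mixed <- toy_pose(3, rbind(c(1, 0, 0), c(5, 0, 0)))
  expect_equal(heavy_atom_rmsd(p0, mixed), sqrt(5), tolerance = 1e-12)
})

test_that("RMSD mappings must be heavy-atom bijections", {
  ph <- ligand_pose(1, data.frame(element = c("C", "H"),
                                  name = c("C1", "H1"),
                                  x = c(0, 1), y = 0, z = 0))
  pc <- toy_pose(2, rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(heavy_atom_rmsd(ph, pc, mapping = cbind(2, 1)), "hydrogen")
  expect_error(heavy_atom_rmsd(pc, pc, mapping = cbind(integer(0),
                                                       integer(0))),
               "empty")
  expect_error(heavy_atom_rmsd(pc, pc, mapping = rbind(c(1, 1), c(1, 2))),
               "bijection")
  # hydrogens are excluded from the default mapping
  expect_equal(heavy_atom_rmsd(ph, toy_pose(3, c(0, 0, 0))), 0)
})

test_that("RMSD is a metric on synthetic triples", {
  set.seed(99)
  for (i in 1:20) {
    a <- toy_pose(1, matrix(rnorm(15), ncol = 3))
    b <- toy_pose(2, matrix(rnorm(15), ncol = 3))
    c_ <- toy_pose(3, matrix(rnorm(15), ncol = 3))
    ab <- heavy_atom_rmsd(a, b)
    expect_equal(ab, heavy_atom_rmsd(b, a))
    expect_lte(heavy_atom_rmsd(a, c_), ab + heavy_atom_rmsd(b, c_) + 1e-12)
  }
  a <- toy_pose(1, matrix(rnorm(15), ncol = 3))
  expect_equal(heavy_atom_rmsd(a, a), 0)
})

test_that("leader clustering separates planted families and degenerate cases", {
  base <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0), ncol = 3, byrow = TRUE)
  # all identical -> one type holding everything
  same <- lapply(1:5, function(i) toy_pose(i, base, fitness = 10 - i))
  ct1 <- cluster_pose_types(same)
  expect_length(ct1$population, 1)
  expect_equal(unname(ct1$population[[1]]), 5)
  expect_equal(ct1$representative[["1"]], "1")  # best fitness
  # single pose founds its own type and represents it
  ct0 <- cluster_pose_types(same[1])
  expect_length(ct0$population, 1)
  expect_equal(ct0$representative[["1"]], "1")
  # two families 8 A apart, 0.5 A intra spread, threshold 2
  set.seed(1)
  fam1 <- lapply(1:6, function(i)
    toy_pose(i, base + matrix(rnorm(9, 0, 0.2), ncol = 3),
             fitness = 20 - i))
  fam2 <- lapply(7:12, function(i)
    toy_pose(i, base + 8 + matrix(rnorm(9, 0, 0.2), ncol = 3),
             fitness = 12 - i))
  ct2 <- cluster_pose_types(c(fam1, fam2), threshold = 2)
  expect_length(ct2$population, 2)
  expect_equal(unname(ct2$type[as.character(1:6)]), rep(1L, 6))
  expect_equal(unname(ct2$type[as.character(7:12)]), rep(2L, 6))
  # representative carries the max fitness within its type
  expect_equal(unname(ct2$rep_fitness), c(19, 5))
  # deterministic given pose order and fitness
  ct3 <- cluster_pose_types(c(fam1, fam2), threshold = 2)
  expect_identical(ct2$type, ct3$type)
})

test_that("best-pose selection honours criterion, skips failures, logs ties", {
  ps <- make_pose_set(synthetic_spec(seed = 8),
                      make_complex(synthetic_spec(seed = 8)))
  ct <- cluster_pose_types(ps$poses)
  expect_equal(select_best_pose(ct, "fitness"),
               unname(which.max(ct$rep_fitness)))
  # paper-style IE tables: most negative wins, Failed (NA) skipped
  expect_equal(select_best_pose(ct, "avg_ie",
                                ie_by_type = c(-98.39, -33.42)), 1L)
  expect_equal(select_best_pose(ct, "avg_ie",
                                ie_by_type = c(-398.53, -498.35, -362.61)),
               2L)
  expect_equal(select_best_pose(ct, "avg_ie",
                                ie_by_type = c(-418.00, -334.12, NA)), 1L)
  expect_error(select_best_pose(ct, "avg_ie",
                                ie_by_type = c(NA_real_, NA_real_)),
               "no eligible")
  expect_message(select_best_pose(ct, "avg_ie",
                                  ie_by_type = c(-5, -5, -1)), "tie")
  # adding a strictly worse type never changes the selection
  expect_equal(select_best_pose(ct, "avg_ie",
                                ie_by_type = c(-98.39, -33.42, -10)), 1L)
})

test_that("pose sets round-trip through multi-model PDB with scores joined", {
  spec <- synthetic_spec(seed = 17, n_types = 2, poses_per_type = 3)
  ps <- make_pose_set(spec, make_complex(spec))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_poses_pdb(ps$poses, f)
  scores <- data.frame(pose_id = seq_along(ps$poses),
                       fitness = vapply(ps$poses, `[[`, numeric(1),
                                        "fitness"),
                       rank = rank(-vapply(ps$poses, `[[`, numeric(1),
                                           "fitness")))
  back <- read_poses_pdb(f, scores = scores)
  expect_length(back, length(ps$poses))
  for (i in seq_along(back)) {
    expect_equal(as.matrix(back[[i]]$atoms[, c("x", "y", "z")]),
                 round(as.matrix(ps$poses[[i]]$atoms[, c("x", "y", "z")]),
                       3),
                 ignore_attr = TRUE)
    expect_equal(back[[i]]$fitness, ps$poses[[i]]$fitness)
  }
  # clustering the reread poses reproduces the planted families
  ct <- cluster_pose_types(back)
  expect_equal(unname(ct$type[names(ps$truth)]), unname(ps$truth))
})

test_that("SDF V2000 pose records are read with elements and coordinates", {
  skip_if_not_installed("ChemmineR")
  sdf_record <- function(xyz) {
    n <- nrow(xyz)
    c("pose", " generated", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, n - 1),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              xyz[, 1], xyz[, 2], xyz[, 3], c("C", "N", "O")[seq_len(n)]),
      sprintf("%3d%3d%3d  0  0  0  0", seq_len(n - 1), seq_len(n - 1) + 1,
              1),
      "M  END", "$$$$")
  }
  f <- withr::local_tempfile(fileext = ".sdf")
  xyz1 <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(0, 1.4, 0))
  writeLines(c(sdf_record(xyz1), sdf_record(xyz1 + 5)), f)
  poses <- read_poses_sdf(f)
  expect_length(poses, 2)
  expect_equal(poses[[1]]$atoms$element, c("C", "N", "O"))
  expect_equal(poses[[1]]$atoms$x, xyz1[, 1], tolerance = 1e-9)
  expect_equal(heavy_atom_rmsd(poses[[1]], poses[[2]]), sqrt(75),
               tolerance = 1e-9)
})
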