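toy_model <- function(...) toy_ternary_structure(...)

test_that("toy structures round-trip through PDB text unchanged", {
  m <- toy_model()
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, p)
  m2 <- read_structure(p)
  expect_equal(nrow(m2), nrow(m))
  expect_equal(m2$elety[order(m2$chain, m2$resno, m2$elety)],
               m$elety[order(m$chain, m$resno, m$elety)])
  ord <- order(m$chain, m$resno, m$elety)
  ord2 <- order(m2$chain, m2$resno, m2$elety)
  expect_equal(as.matrix(m2[ord2, c("x", "y", "z")]),
               as.matrix(m[ord, c("x", "y", "z")]),
               ignore_attr = TRUE, tolerance = 1e-3)
})

test_that("PDB reading resolves altlocs by occupancy and reports bad lines", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA  GLY A   2       2.000   0.000   0.000  1.00  0.00           C",
    "END"), p)
  m <- read_structure(p)
  expect_equal(nrow(m), 2)
  kept <- m[m$resno == 1, ]
  expect_equal(kept$alt, "A")
  expect_equal(kept$x, 0)

  # higher-occupancy B beats A
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.70  0.00           C",
    "END"), p)
  mB <- read_structure(p)
  expect_equal(mB$alt, "B")
  expect_equal(mB$x, 1)

  # occupancy tie -> alphabetically first altloc
  writeLines(c(
    "ATOM      1  CA BALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA AALA A   1       0.000   0.000   0.000  0.50  0.00           C",
    "END"), p)
  expect_equal(read_structure(p)$alt, "A")

  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000",
    "END"), p)
  expect_error(read_structure(p), "line 1")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.0x0   0.000   0.000  1.00  0.00           C",
    "END"), p)
  expect_error(read_structure(p), "line 1")
})

test_that("minimum distance finds the realizing pair", {
  A <- matrix(c(0, 0, 0, 10, 10, 10), 2, 3, byrow = TRUE)
  B <- matrix(c(3, 4, 0), 1, 3)
  md <- min_distance(A, B)
  expect_equal(md$distance, 5)
  expect_equal(unname(md$pair), c(1, 1))
  expect_equal(min_distance(A, A)$distance, 0)
  expect_error(min_distance(A[0, , drop = FALSE], B), "non-empty")
})

test_that("toy geometry is reproduced exactly by the contact operations", {
  m <- toy_model(ring_separation = 3.5, interplanar_angle = 0,
                 probe_distance = 3.5, hbond_distance = 2.9)
  ringA <- select_atoms(m, resid = "LGA", element = "C")
  ringB <- select_atoms(m, resid = "LGB")
  st <- ring_stacking(ringA, ringB)
  expect_equal(st$centroid_distance, 3.5, tolerance = 1e-9)
  expect_equal(st$angle_deg, 0, tolerance = 1e-6)
  expect_true(st$stacking)

  # perpendicular rings are not stacked
  m90 <- toy_model(interplanar_angle = 90)
  st90 <- ring_stacking(select_atoms(m90, resid = "LGA", element = "C"),
                        select_atoms(m90, resid = "LGB"))
  expect_equal(st90$angle_deg, 90, tolerance = 1e-6)
  expect_false(st90$stacking)

  # tilted geometry is folded to [0, 90]
  m150 <- toy_model(interplanar_angle = 150)
  expect_equal(ring_stacking(select_atoms(m150, resid = "LGA", element = "C"),
                             select_atoms(m150, resid = "LGB"))$angle_deg,
               30, tolerance = 1e-6)

  probe <- min_distance(select_atoms(m, elety = "F"),
                        select_atoms(m, resid = "TRP"))
  expect_equal(probe$distance, 3.5, tolerance = 1e-9)

  lig <- select_atoms(m, spec = "L:1:*")
  hb <- suppressWarnings(hbond_inventory(m, lig))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$resid, "ASN")
  expect_equal(hb$atom, "ND2")
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  # beyond the cutoff the pair disappears
  m4 <- toy_model(hbond_distance = 4.0)
  hb4 <- suppressWarnings(hbond_inventory(m4, select_atoms(m4, spec = "L:1:*")))
  expect_equal(nrow(hb4), 0)
})

test_that("hbond count is monotone non-decreasing in the cutoff", {
  m <- toy_model()
  lig <- select_atoms(m, spec = "L:1:*")
  counts <- vapply(c(2.5, 3.0, 3.5, 4.5, 6, 10), function(cc) {
    nrow(suppressWarnings(hbond_inventory(m, lig, cutoff = cc)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("ring plane fitting rejects collinear atoms", {
  line <- cbind(1:5, 0, 0)
  expect_error(ring_stacking(line, line), "collinear")
})

test_that("Kabsch superposition is exact under rigid motion and never reflects", {
  set.seed(11)
  A <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  for (i in 1:10) {
    th <- stats::runif(3, 0, 2 * pi)
    Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0),
                c(sin(th[1]), cos(th[1]), 0), c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[2]), -sin(th[2])),
                c(0, sin(th[2]), cos(th[2])))
    R <- Rz %*% Rx
    B <- A %*% t(R) + matrix(stats::rnorm(3), 10, 3, byrow = TRUE)
    fit <- kabsch_superpose(A, B)
    expect_equal(fit$rmsd, 0, tolerance = 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_equal(fit$transform(A), B, tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(kabsch_superpose(cbind(1:5, 0, 0), cbind(1:5, 0, 0)),
               "degenerate")
  expect_error(kabsch_superpose(A[1:4, ], A[1:5, ]), "equal length")
})

test_that("Kabsch beats random rigid alignments and matches bio3d", {
  set.seed(12)
  A <- matrix(stats::rnorm(24), 8, 3)
  B <- A + matrix(stats::rnorm(24, sd = 0.3), 8, 3)
  fit <- kabsch_superpose(A, B)
  rmsd_of <- function(R) {
    A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
    sqrt(mean(rowSums((A0 %*% t(R) - B0)^2)))
  }
  for (i in 1:25) {
    th <- stats::runif(1, 0, 2 * pi); ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
               c(-ax[2], ax[1], 0))
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    expect_gte(rmsd_of(R), fit$rmsd - 1e-12)
  }
  # independent cross-check against the bio3d implementation
  xyz_A <- as.vector(t(A)); xyz_B <- as.vector(t(B))
  ref <- bio3d::rmsd(xyz_A, xyz_B, fit = TRUE)  # rounded to 3 digits
  expect_equal(round(fit$rmsd, 3), ref, tolerance = 1e-6)
})

test_that("invariance of distances and RMSD under a common rigid motion", {
  set.seed(13)
  A <- matrix(stats::rnorm(15), 5, 3)
  B <- matrix(stats::rnorm(15), 5, 3)
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(3, -2, 7)
  move <- function(x) sweep(x %*% t(R), 2, shift, "+")
  expect_equal(min_distance(move(A), move(B))$distance,
               min_distance(A, B)$distance, tolerance = 1e-9)
  expect_equal(kabsch_superpose(move(A), move(B))$rmsd,
               kabsch_superpose(A, B)$rmsd, tolerance = 1e-9)
})

test_that("ligand pose RMSD measures displacement within a common frame", {
  frame <- matrix(stats::rnorm(30, sd = 5), 10, 3)
  lig_xyz <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 1), 4, 3,
                    byrow = TRUE)
  as_model <- function(xyz, names.) {
    out <- data.frame(chain = "L", resno = 1, insert = "", resid = "LIG",
                      elety = names., element = "C", alt = "",
                      occupancy = 1, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], stringsAsFactors = FALSE)
    class(out) <- c("structure_model", "data.frame")
    out
  }
  nm <- c("C1", "C2", "C3", "C4")
  ligA <- as_model(lig_xyz, nm)
  ligB <- as_model(lig_xyz, nm)
  expect_equal(ligand_pose_rmsd(ligA, ligB, frame, frame), 0,
               tolerance = 1e-12)
  # translate ligand A by 1 Angstrom inside identical frames
  ligA1 <- as_model(sweep(lig_xyz, 2, c(1, 0, 0), "+"), nm)
  expect_equal(ligand_pose_rmsd(ligA1, ligB, frame, frame), 1,
               tolerance = 1e-9)
  # atom-name mapping (fluorine substituent vs parent carbon)
  ligF <- as_model(lig_xyz, c("F", "C2", "C3", "C4"))
  expect_equal(ligand_pose_rmsd(ligF, ligB, frame, frame,
                                name_map = c(F = "C1")), 0,
               tolerance = 1e-12)
  expect_error(ligand_pose_rmsd(ligF, as_model(lig_xyz, c("X1", "X2", "X3", "X4")),
                                frame, frame), "corresponded")
})

test_that("chain RMSD pairing uses shared residues", {
  set.seed(14)
  ca <- matrix(stats::rnorm(60, sd = 8), 20, 3)
  th <- 0.4
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  cb <- ca %*% t(R) + matrix(c(10, 0, 0), 20, 3, byrow = TRUE)
  model <- data.frame(
    chain = rep(c("A", "B"), each = 20), resno = rep(1:20, 2),
    insert = "", resid = "ALA", elety = "CA", element = "C", alt = "",
    occupancy = 1, x = c(ca[, 1], cb[, 1]), y = c(ca[, 2], cb[, 2]),
    z = c(ca[, 3], cb[, 3]), stringsAsFactors = FALSE)
  class(model) <- c("structure_model", "data.frame")
  out <- chain_rmsd_matrix(model)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_atoms, 20)
  expect_equal(out$rmsd, 0, tolerance = 1e-9)
})
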