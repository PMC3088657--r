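test_that("kabsch recovers identity and exact rigid motions", {
  set.seed(1)
  a <- matrix(rnorm(30, sd = 4), ncol = 3)
  same <- kabsch(a, a)
  expect_equal(same$rmsd, 0, tolerance = 1e-9)
  expect_equal(same$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(same$transform$translation, c(0, 0, 0), tolerance = 1e-9)
  r <- random_rotation(); tr <- c(3, -7, 12)
  b <- sweep(a %*% t(r), 2, tr, "+")
  fit <- kabsch(a, b)
  expect_lt(fit$rmsd, 1e-9)
  expect_lt(max(abs(apply_transform(fit$transform, b) - a)), 1e-6)
})

test_that("kabsch rmsd matches the quaternion closed form on noisy pairs", {
  set.seed(42)
  for (k in 1:5) {
    a <- matrix(rnorm(30, sd = 3), ncol = 3)
    b <- sweep((a + matrix(rnorm(30, sd = 0.1), ncol = 3)) %*% t(random_rotation()),
               2, runif(3, -5, 5), "+")
    expect_equal(kabsch(a, b)$rmsd, horn_rmsd(a, b), tolerance = 1e-8)
  }
})

test_that("kabsch is symmetric, self-consistent and never reflects", {
  set.seed(3)
  a <- matrix(rnorm(24, sd = 3), ncol = 3)
  b <- matrix(rnorm(24, sd = 3), ncol = 3)
  f1 <- kabsch(a, b); f2 <- kabsch(b, a)
  expect_equal(f1$rmsd, f2$rmsd, tolerance = 1e-9)
  # recomputing the RMSD from the applied transform reproduces the report
  expect_equal(rmsd_xyz(a, apply_transform(f1$transform, b)), f1$rmsd,
               tolerance = 1e-9)
  # mirror image: optimal orthogonal fit would reflect; a proper rotation
  # must be returned, at the cost of a non-zero rmsd
  m <- a; m[, 1] <- -m[, 1]
  fm <- kabsch(a, m)
  expect_equal(det(fm$transform$rotation), 1, tolerance = 1e-9)
  expect_gt(fm$rmsd, 0.1)
  # inverse composition gives identity
  comp <- compose_transforms(invert_transform(f1$transform), f1$transform)
  expect_equal(comp$rotation, diag(3), tolerance = 1e-9)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("kabsch flags degenerate and collinear input", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "degenerate")
  line <- cbind(1:5, 0, 0)
  expect_warning(kabsch(line, line), "collinear")
})

test_that("self-alignment gives identity 1 and a substitution is counted", {
  cx <- make_pocket_complex(50, 3.5, "benzene", n_shell = 50)
  al <- align_protein_pair(cx$protein, cx$protein)
  expect_equal(al$identity, 1.0)
  expect_equal(nrow(al$pairs), 50)
  s <- strsplit(cx$protein$sequence, "")[[1]]
  s[10] <- if (s[10] == "A") "W" else "A"
  mut <- cx$protein
  mut$sequence <- paste(s, collapse = "")
  mut$atoms$resid <- bio3d::aa123(s)
  al2 <- align_protein_pair(cx$protein, mut)
  expect_equal(al2$identity, 49 / 50)
})

test_that("alignment score agrees with an independent affine-gap DP", {
  set.seed(9)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  # 100 positions, 40 identities by construction
  s1 <- sample(aa, 100, replace = TRUE)
  s2 <- s1
  flip <- sample(100, 60)
  for (p in flip) s2[p] <- sample(setdiff(aa, s1[p]), 1)
  ch1 <- make_chain(cbind(3 * (1:100), 0.5 * (1:100), 0), rep("C", 100),
                    paste(s1, collapse = ""))
  ch2 <- make_chain(cbind(3 * (1:100), 0.5 * (1:100), 0), rep("C", 100),
                    paste(s2, collapse = ""))
  al <- align_protein_pair(ch1, ch2)
  expect_equal(al$identity, 0.40, tolerance = 0.02)
  expect_equal(al$score,
               nw_score(paste(s1, collapse = ""), paste(s2, collapse = "")))
  expect_error(align_protein_pair(
    make_chain(cbind(1:10, 0, 0), rep("C", 10)), ch1), "too short")
})

test_that("name-matched ligands map by name, symmetric ones by best automorphism", {
  lig <- ligand_template("triol")
  m <- ligand_atom_map(lig, lig)
  expect_equal(attr(m, "source"), "name")
  expect_equal(m$idx_a, m$idx_b)
  # benzene in a rotated frame: 12 automorphisms, the chosen one refits
  # exactly onto the original
  bnz <- ligand_template("benzene")
  moved <- apply_transform(rigid_transform(random_rotation(), c(4, 5, 6)), bnz)
  moved$atoms$name <- paste0("X", 1:6)   # force the graph path
  m2 <- ligand_atom_map(bnz, moved)
  expect_equal(attr(m2, "source"), "graph")
  expect_length(ligtrans:::ligand_isomorphisms(bnz, bnz), 12)
  fit <- kabsch(atom_xyz(bnz$atoms)[m2$idx_a, ],
                atom_xyz(moved$atoms)[m2$idx_b, ])
  expect_lt(fit$rmsd, 1e-9)
})

test_that("constitutional isomers are rejected as different ligands", {
  expect_error(ligand_atom_map(ligand_template("ethanol"),
                               ligand_template("ether")),
               "not the same ligand")
})

test_that("protein- and ligand-based superposition undo a rigid motion", {
  cx <- make_pocket_complex(60, 3.5, "adenine", n_shell = 60)
  tf <- rigid_transform(random_rotation(), c(10, -4, 2))
  moved <- apply_transform(tf, cx)
  tp <- superpose_by_protein(cx, moved)
  expect_lt(attr(tp, "rmsd"), 1e-9)
  expect_lt(max(abs(apply_transform(tp, atom_xyz(moved$ligand$atoms)) -
                    atom_xyz(cx$ligand$atoms))), 1e-6)
  tl <- superpose_by_ligand(cx, moved)
  expect_lt(attr(tl, "rmsd"), 1e-9)
  expect_lt(max(abs(apply_transform(tl, atom_xyz(moved$protein$atoms)) -
                    atom_xyz(cx$protein$atoms))), 1e-6)
  # self-superposition is the identity
  ts <- superpose_by_protein(cx, cx)
  expect_equal(ts$rotation, diag(3), tolerance = 1e-9)
})

test_that("a rotated torsion gives the quaternion-oracle rmsd over automorphisms", {
  lig <- ligand_template("triol")
  bent <- lig
  # swing the terminal oxygen on atom 3 to a new position at the same
  # bond length: same graph, different conformer
  c3 <- atom_xyz(lig$atoms)[3, ]
  bent$atoms$x[6] <- c3[1] + 1.43; bent$atoms$y[6] <- c3[2]; bent$atoms$z[6] <- c3[3]
  bent$atoms$name <- paste0("X", 1:6)   # force the graph path on both sides
  cx_ref <- make_pocket_complex(70, 4.0, "triol", n_shell = 50)
  cx_mov <- cx_ref
  cx_mov$ligand <- bent
  tl <- superpose_by_ligand(cx_ref, cx_mov)
  expect_gt(attr(tl, "rmsd"), 0.05)
  maps <- ligtrans:::ligand_isomorphisms(cx_ref$ligand, bent)
  oracle <- min(vapply(maps, function(mp) {
    horn_rmsd(atom_xyz(cx_ref$ligand$atoms), atom_xyz(bent$atoms)[mp, ])
  }, numeric(1)))
  expect_equal(attr(tl, "rmsd"), oracle, tolerance = 1e-8)
})

test_that("a correspondence file drives superposition without sequences", {
  cx <- make_pocket_complex(80, 3.5, "benzene", n_shell = 40)
  tf <- rigid_transform(random_rotation(), c(1, 2, 3))
  moved <- apply_transform(tf, cx)
  f <- tempfile()
  writeLines(c("# ref mov", sprintf("A:%d A:%d", 1:40, 1:40)), f)
  corr <- read_correspondence(f)
  expect_equal(nrow(corr), 40)
  tp <- superpose_by_protein(cx, moved, correspondence = corr)
  expect_lt(attr(tp, "rmsd"), 1e-9)
})
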