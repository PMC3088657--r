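#' Small-molecule templates for synthetic fixtures
#'
#' A shipped library of rigid small molecules with explicit element-labelled
#' bond graphs: `alkane` (octane-like C8 chain), `benzene` (C6 ring),
#' `triol` (glycerol-like C3O3), `adenine` (fused 6-5 N-heterocycle, 10
#' atoms), `carboxylate` (acetate-like C2O2), `macrocycle` (20-atom ring
#' with two ring oxygens), plus `ethanol` and `ether` (same formula,
#' different graphs, for isomorphism tests).
#'
#' @param name template identifier.
#' @return a [ligand] centred at the origin.
#' @export
ligand_template <- function(name = c("alkane", "benzene", "triol", "adenine",
                                     "carboxylate", "macrocycle", "ethanol",
                                     "ether")) {
  name <- match.arg(name)
  ring_xyz <- function(n, r) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    cbind(r * cos(th), r * sin(th), 0)
  }
  chain_bonds <- function(n) tibble(from = seq_len(n - 1), to = 2:n)
  ring_bonds <- function(n) tibble(from = seq_len(n), to = c(2:n, 1))
  spec <- switch(name,
    alkane = {
      x <- 1.25 * (0:7); y <- 0.44 * rep_len(c(1, -1), 8)
      list(el = rep("C", 8), xyz = cbind(x, y, 0), bonds = chain_bonds(8),
           code = "ALK")
    },
    benzene = list(el = rep("C", 6), xyz = ring_xyz(6, 1.39),
                   bonds = ring_bonds(6), code = "BNZ"),
    triol = {
      cxyz <- rbind(c(0, 0, 0), c(1.25, 0.88, 0), c(2.5, 0, 0))
      oxyz <- cxyz + matrix(rep(c(0, -0.70, 1.25), each = 3), ncol = 3)
      list(el = c("C", "C", "C", "O", "O", "O"), xyz = rbind(cxyz, oxyz),
           bonds = tibble(from = c(1, 2, 1, 2, 3), to = c(2, 3, 4, 5, 6)),
           code = "TRL")
    },
    adenine = {
      # planar purine ring system at crystallographic geometry:
      # N9 C8 N7 C5 C4 N3 C2 N1 C6 + exocyclic amine N6
      xyz <- rbind(
        c(0.000, 0.000, 0), c(0.712, 1.178, 0), c(2.011, 0.958, 0),
        c(2.156, -0.403, 0), c(0.881, -0.938, 0), c(0.550, -2.240, 0),
        c(1.576, -3.060, 0), c(2.855, -2.709, 0), c(3.186, -1.400, 0),
        c(4.454, -1.069, 0))
      list(el = c("N", "C", "N", "C", "C", "N", "C", "N", "C", "N"),
           xyz = xyz,
           bonds = tibble(from = c(1, 2, 3, 4, 5, 5, 6, 7, 8, 9, 9),
                          to   = c(2, 3, 4, 5, 1, 6, 7, 8, 9, 4, 10)),
           code = "ADE")
    },
    carboxylate = list(
      el = c("C", "C", "O", "O"),
      xyz = rbind(c(0, 0, 0), c(1.53, 0, 0), c(2.15, 1.06, 0), c(2.15, -1.06, 0)),
      bonds = tibble(from = c(1, 2, 2), to = c(2, 3, 4)), code = "CBX"),
    macrocycle = {
      el <- rep("C", 20); el[c(1, 11)] <- "O"
      list(el = el, xyz = ring_xyz(20, 1.5 / (2 * sin(pi / 20))),
           bonds = ring_bonds(20), code = "MCY")
    },
    ethanol = list(
      el = c("C", "C", "O"),
      xyz = rbind(c(0, 0, 0), c(1.53, 0, 0), c(2.2, 1.2, 0)),
      bonds = chain_bonds(3), code = "ETH"),
    ether = list(
      el = c("C", "O", "C"),
      xyz = rbind(c(0, 0, 0), c(1.43, 0, 0), c(2.1, 1.2, 0)),
      bonds = chain_bonds(3), code = "DME")
  )
  xyz <- sweep(spec$xyz, 2, colMeans(spec$xyz))
  counts <- stats::ave(seq_along(spec$el), spec$el, FUN = seq_along)
  atoms <- tibble(
    eleno = seq_along(spec$el),
    name = paste0(spec$el, counts),
    element = spec$el,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    chain = "L", resno = 1L, insert = "", resid = spec$code,
    hetero = TRUE, occ = 1
  )
  ligand(spec$code, atoms, bonds = spec$bonds, source = "template")
}

# seeded proper rotation (QR of a random normal matrix) + translation
random_rigid_transform <- function(max_shift = 20) {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rigid_transform(q, stats::runif(3, -max_shift, max_shift))
}

random_sequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

#' Mutate a sequence to a target identity
#'
#' Substitutes a fixed number of positions (with letters different from the
#' originals) so that exact positional identity equals `identity` up to
#' rounding. Used to engineer protein pairs for the identity filters.
#'
#' @param sequence one-letter sequence.
#' @param identity target fraction of conserved positions.
#' @return mutated sequence string.
#' @export
mutate_sequence <- function(sequence, identity) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  s <- strsplit(sequence, "")[[1]]
  n_mut <- round((1 - identity) * length(s))
  pos <- sample(seq_along(s), n_mut)
  for (p in pos) s[p] <- sample(setdiff(aa, s[p]), 1)
  paste(s, collapse = "")
}

# rigid shell of C-alpha pseudo-residues at `tightness` Angstrom from the
# support of the given ligand atom cloud
make_shell_chain <- function(lig_xyz, tightness, n_shell, sequence,
                             chain_id = "A", source = "fixture") {
  dirs <- matrix(stats::rnorm(3 * n_shell), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  support <- apply(dirs %*% t(lig_xyz), 1, max)
  pos <- dirs * (support + tightness)
  atoms <- tibble(
    eleno = seq_len(n_shell),
    name = "CA",
    element = "C",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    chain = chain_id, resno = seq_len(n_shell), insert = "",
    resid = bio3d::aa123(strsplit(sequence, "")[[1]]),
    hetero = FALSE, occ = 1
  )
  protein_chain(chain_id, atoms, sequence, source = source)
}

#' Generate a synthetic pocket complex
#'
#' Builds a rigid "protein" shell of C-alpha pseudo-residues around a
#' template ligand: each shell atom sits `pocket_tightness` Angstrom outside
#' the ligand's support in a random direction, so tight pockets (around
#' 3.5 A) produce many contacts within the 5 A rule and loose shells
#' (8 A and beyond) produce none. Shell size and sequence are drawn from the
#' seed, so the fixture is fully reproducible. These shells are geometric
#' probes, not folded proteins; they exercise every distance-based and
#' statistical operation.
#'
#' @param seed integer seed.
#' @param pocket_tightness gap between ligand support and shell (Angstrom).
#' @param ligand_spec template name (see [ligand_template]).
#' @param n_shell number of shell pseudo-residues (default drawn from
#'   50-120).
#' @param sequence optional sequence override (length must equal `n_shell`).
#' @param source source label for provenance.
#' @return a [plc] record (contacts not required, so loose shells are
#'   representable).
#' @export
make_pocket_complex <- function(seed, pocket_tightness = 3.5,
                                ligand_spec = "benzene", n_shell = NULL,
                                sequence = NULL, source = NULL) {
  set.seed(as.integer(seed))
  lig <- ligand_template(ligand_spec)
  tf <- random_rigid_transform(max_shift = 0)   # random orientation at origin
  lig <- apply_transform(tf, lig)
  if (is.null(n_shell)) n_shell <- sample(50:120, 1)
  if (is.null(sequence)) sequence <- random_sequence(n_shell)
  if (nchar(sequence) != n_shell) stop("sequence length must equal n_shell")
  if (is.null(source)) source <- sprintf("fx%s_%d", ligand_spec, seed)
  lig$source <- source
  chain <- make_shell_chain(atom_xyz(lig$atoms), pocket_tightness, n_shell,
                            sequence, source = source)
  plc(chain, lig, source = source, require_contacts = FALSE)
}

#' Generate a ground-truth triplet with known ligand placement
#'
#' Builds one master complex carrying two ligands (a benzene-like common
#' ligand La and a triol-like transfer ligand Lb) inside one shell, then
#' emits the three triplet roles as rigidly transformed copies with known
#' transforms: P1:La, P1:Lb (same protein, different frames) and P2:La (a
#' copy acting as the second protein). The expected Lb placement in P2's
#' frame is exact by construction, so the model builder must reproduce it to
#' numerical precision.
#'
#' @param seed integer seed.
#' @param perturb_lb optional length-3 shift (Angstrom) applied to the
#'   expected Lb copy in the P2 frame before reporting, giving fixtures with
#'   a known non-zero RMSD.
#' @return list with `triplet` (a [candidate_triplet]), `expected_lb`
#'   (heavy-atom coordinate matrix of Lb in P2's frame), `reference` (a
#'   [plc] of P2 with Lb at the expected position) and the three transforms.
#' @export
make_ground_truth_triplet <- function(seed, perturb_lb = c(0, 0, 0)) {
  set.seed(as.integer(seed))
  la <- ligand_template("benzene")
  lb <- ligand_template("triol")
  lb$atoms$x <- lb$atoms$x + 7   # second site, 7 A from the first
  both <- rbind(atom_xyz(la$atoms), atom_xyz(lb$atoms))
  n_shell <- 90
  seq1 <- random_sequence(n_shell)
  master <- make_shell_chain(both, 3.5, n_shell, seq1, source = "master")
  t1 <- random_rigid_transform(); t2 <- random_rigid_transform()
  t3 <- random_rigid_transform()
  mk <- function(tf, lig, src) {
    ch <- apply_transform(tf, master); ch$source <- src
    lg <- apply_transform(tf, lig); lg$source <- src
    plc(ch, lg, source = src, require_contacts = FALSE)
  }
  c_p1_la <- mk(t1, la, "p1_la")
  c_p1_lb <- mk(t2, lb, "p1_lb")
  c_p2_la <- mk(t3, la, "p2_la")
  expected <- apply_transform(t3, atom_xyz(lb$atoms))
  expected <- sweep(expected, 2, perturb_lb, "+")
  lb_ref <- lb
  xyz <- expected
  lb_ref$atoms$x <- xyz[, 1]; lb_ref$atoms$y <- xyz[, 2]; lb_ref$atoms$z <- xyz[, 3]
  reference <- plc(c_p2_la$protein, lb_ref, source = "p2_lb_truth",
                   require_contacts = FALSE)
  list(
    triplet = candidate_triplet(c_p1_la, c_p2_la, c_p1_lb),
    expected_lb = expected,
    reference = reference,
    transforms = list(t1 = t1, t2 = t2, t3 = t3)
  )
}

#' Write the synthetic test corpus to a directory
#'
#' Emits a set of pocket complexes (PDB, one also as mmCIF) and one
#' enumerable triplet — a protein P1 solved with both La and Lb plus a
#' second, sequence-divergent protein P2 solved with La — together with a
#' JSON manifest. The triplet survives all candidate filters, so a pipeline
#' run over the directory yields at least one prediction.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_pockets number of stand-alone pocket complexes (default 4).
#' @return invisible list describing the written files.
#' @export
write_fixture_suite <- function(dir, seed = 1, n_pockets = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  templates <- c("alkane", "adenine", "carboxylate", "macrocycle")
  files <- character()
  for (k in seq_len(n_pockets)) {
    cx <- make_pocket_complex(seed * 100 + k, 3.5,
                              templates[(k - 1) %% length(templates) + 1])
    f <- file.path(dir, sprintf("pocket_%02d.pdb", k))
    write_structure(list(cx$protein), list(cx$ligand), f)
    files <- c(files, f)
  }
  # same pocket also as mmCIF for dialect round-trips
  cx1 <- make_pocket_complex(seed * 100 + 1, 3.5, templates[1])
  cif <- file.path(dir, "pocket_01.cif")
  write_structure(list(cx1$protein), list(cx1$ligand), cif, format = "mmcif")

  set.seed(as.integer(seed))
  la <- ligand_template("benzene")
  lb <- ligand_template("triol")
  lb$atoms$x <- lb$atoms$x + 7
  both <- rbind(atom_xyz(la$atoms), atom_xyz(lb$atoms))
  n_shell <- 90
  seq1 <- random_sequence(n_shell)
  p1 <- make_shell_chain(both, 3.5, n_shell, seq1, source = "trip_p1")
  seq2 <- mutate_sequence(seq1, 0.35)
  # P2's shell leaves the second site open so a transferred ligand can fit
  p2 <- make_shell_chain(both, 3.5, n_shell, seq2, source = "trip_p2")
  t1 <- random_rigid_transform(); t2 <- random_rigid_transform()
  trip_files <- c(
    trip_p1_la = file.path(dir, "trip_p1_la.pdb"),
    trip_p1_lb = file.path(dir, "trip_p1_lb.pdb"),
    trip_p2_la = file.path(dir, "trip_p2_la.pdb")
  )
  write_structure(list(apply_transform(t1, p1)), list(apply_transform(t1, la)),
                  trip_files[["trip_p1_la"]])
  write_structure(list(apply_transform(t2, p1)), list(apply_transform(t2, lb)),
                  trip_files[["trip_p1_lb"]])
  write_structure(list(p2), list(la), trip_files[["trip_p2_la"]])
  manifest <- list(seed = seed, pockets = basename(files),
                   mmcif = basename(cif), triplet = basename(unname(trip_files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
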