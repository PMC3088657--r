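# linear all-carbon chain ligand of arbitrary size, for atom-ratio boundaries
make_chain_ligand <- function(n, code = sprintf("C%02d", n)) {
  xyz <- cbind(1.25 * (seq_len(n) - 1), 0.44 * rep_len(c(1, -1), n), 0)
  atoms <- tibble::tibble(
    eleno = seq_len(n), name = paste0("C", seq_len(n)), element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    chain = "L", resno = 1L, insert = "", resid = code, hetero = TRUE, occ = 1
  )
  ligand(code, atoms, bonds = tibble::tibble(from = seq_len(n - 1), to = 2:n))
}

# a minimal contacting complex used when only bookkeeping matters
tiny_complex <- function(source, lig = ligand_template("benzene"),
                         sequence = NULL) {
  lig$source <- source
  if (is.null(sequence)) sequence <- paste(rep("A", 30), collapse = "")
  n <- nchar(sequence)
  set.seed(7)
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  support <- apply(dirs %*% t(cbind(lig$atoms$x, lig$atoms$y, lig$atoms$z)), 1, max)
  xyz <- dirs * (support + 4)
  ch <- make_chain(xyz, rep("C", n), sequence)
  ch$source <- source
  plc(ch, lig, source = source)
}

# corpus with ten enumerable candidates, five of which must clash severely:
# P1 (six structures: with La and with five transfer ligands, all sites on
# a ring), P2 with every site carved open, P3 open around La but lined with
# blocking atoms at the transfer sites so every transfer into it clashes
write_multi_triplet_corpus <- function(dir, seed = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  la <- ligand_template("benzene")
  lb_names <- c("triol", "alkane", "adenine", "carboxylate", "pentane")
  ang <- 2 * pi * (0:5) / 6
  offs <- cbind(8 * cos(ang), 8 * sin(ang), 0)   # row 1 is La's site
  la$atoms$x <- la$atoms$x + offs[1, 1]
  la$atoms$y <- la$atoms$y + offs[1, 2]
  lbs <- lapply(seq_along(lb_names), function(i) {
    lg <- if (lb_names[i] == "pentane") make_chain_ligand(5, "C05")
          else ligand_template(lb_names[i])
    lg$atoms$x <- lg$atoms$x + offs[i + 1, 1]
    lg$atoms$y <- lg$atoms$y + offs[i + 1, 2]
    lg$atoms$z <- lg$atoms$z + offs[i + 1, 3]
    lg
  })
  lb_cloud <- do.call(rbind, lapply(lbs, function(l) atom_xyz(l$atoms)))
  cloud <- rbind(atom_xyz(la$atoms), lb_cloud)
  n_shell <- 250
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seq1 <- paste(sample(aa, n_shell, replace = TRUE), collapse = "")
  p1 <- ligtrans:::make_shell_chain(cloud, 3.5, n_shell, seq1, source = "p1_la")
  wr <- function(chain, lig, stem) {
    chain$source <- stem; lig$source <- stem
    write_structure(list(chain), list(lig), file.path(dir, paste0(stem, ".pdb")))
  }
  wr(p1, la, "p1_la")
  for (i in seq_along(lbs)) {
    tf <- ligtrans:::random_rigid_transform()
    wr(apply_transform(tf, p1), apply_transform(tf, lbs[[i]]),
       sprintf("p1_lb%d", i))
  }
  seq2 <- mutate_sequence(seq1, 0.35)
  p2 <- ligtrans:::make_shell_chain(cloud, 3.5, n_shell, seq2, source = "p2_la")
  wr(p2, la, "p2_la")
  # P3: a normal pocket around La plus atoms hugging each transfer site at
  # well under half the vdW contact distance
  seq3 <- mutate_sequence(seq1, 0.40)
  open_part <- ligtrans:::make_shell_chain(atom_xyz(la$atoms), 3.5, 150,
                                           substr(seq3, 1, 150))
  block_part <- ligtrans:::make_shell_chain(lb_cloud, 0.8, 100,
                                            substr(seq3, 151, 250))
  atoms3 <- dplyr::bind_rows(open_part$atoms, block_part$atoms)
  atoms3$resno <- seq_len(nrow(atoms3))
  atoms3$eleno <- seq_len(nrow(atoms3))
  p3 <- protein_chain("A", atoms3, seq3, source = "p3_la")
  wr(p3, la, "p3_la")
  invisible(dir)
}
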