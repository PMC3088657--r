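test_that("network construction merges identical proteins and chemicals", {
  a <- tiny_complex("s1", ligand_template("benzene"),
                    sequence = strrep("AC", 15))
  b <- tiny_complex("s2", ligand_template("triol"),
                    sequence = strrep("DE", 15))
  cc <- tiny_complex("s3", ligand_template("alkane"),
                     sequence = strrep("FG", 15))
  net3 <- build_network(list(a, b, cc))
  expect_equal(nrow(net3$proteins), 3)
  expect_equal(nrow(net3$chemicals), 3)
  expect_equal(nrow(net3$edges), 3)
  # two structures of the same pair: one node each, two edges
  a2 <- tiny_complex("s4", ligand_template("benzene"),
                     sequence = strrep("AC", 15))
  net2 <- build_network(list(a, a2))
  expect_equal(nrow(net2$proteins), 1)
  expect_equal(nrow(net2$chemicals), 1)
  expect_equal(nrow(net2$edges), 2)
  # graph-identical ligands merge even with scrambled atom order and names
  scr <- ligand_template("benzene")
  perm <- c(3, 1, 4, 6, 2, 5)
  scr$atoms <- scr$atoms[perm, ]
  inv <- integer(6); inv[perm] <- 1:6
  scr$bonds$from <- inv[scr$bonds$from]; scr$bonds$to <- inv[scr$bonds$to]
  scr$atoms$name <- paste0("Q", 1:6)
  a3 <- tiny_complex("s5", scr, sequence = strrep("HI", 15))
  netm <- build_network(list(a, a3))
  expect_equal(nrow(netm$chemicals), 1)
})

test_that("tanimoto is 1 on identical graphs, 0 on disjoint ones, and exact", {
  bnz <- ligand_template("benzene")
  expect_equal(tanimoto(bnz, bnz), 1.0)
  # same compound, different atom order and frame
  scr <- ligand_template("benzene")
  perm <- c(2, 4, 6, 1, 3, 5)
  scr$atoms <- scr$atoms[perm, ]
  inv <- integer(6); inv[perm] <- 1:6
  scr$bonds$from <- inv[scr$bonds$from]; scr$bonds$to <- inv[scr$bonds$to]
  expect_equal(tanimoto(bnz, scr), 1.0)
  # no shared element environments at all
  allc <- make_chain_ligand(5)
  allo <- make_chain_ligand(5)
  allo$atoms$element <- "O"
  expect_equal(tanimoto(allc, allo), 0.0)
  # the coefficient is plain bit-set arithmetic
  tri <- ligand_template("triol")
  fa <- fingerprint_bits(bnz); fb <- fingerprint_bits(tri)
  expect_equal(tanimoto(bnz, tri),
               length(intersect(fa, fb)) / length(union(fa, fb)))
  nog <- bnz; nog$bonds <- NULL
  expect_error(fingerprint_bits(nog), "no bond graph")
})

test_that("triplet enumeration matches hand enumeration on an engineered network", {
  set.seed(600)
  seq1 <- ligtrans:::random_sequence(60)
  seq2 <- mutate_sequence(seq1, 0.35)     # below the 80% exclusion
  seq3 <- mutate_sequence(seq1, 0.85)     # at/above the 80% exclusion
  seq4 <- ligtrans:::random_sequence(60)  # unrelated protein
  la <- ligand_template("benzene")        # 6 atoms
  lb <- ligand_template("triol")          # 6 atoms, ratio 1
  lc <- ligand_template("macrocycle")     # 20 atoms, ratio 3.3 -> excluded
  ld <- ligand_template("carboxylate")    # 4 atoms, ratio 1.5
  # every non-La ligand is bound by exactly one protein, so La (benzene)
  # is the only shared chemical and the enumeration is fully hand-checkable
  cx <- list(
    p1_la  = tiny_complex("e01", la, seq1),
    p1_lb  = tiny_complex("e02", lb, seq1),
    p1_lc  = tiny_complex("e03", lc, seq1),
    p2_la  = tiny_complex("e04", la, seq2),
    p2_ld  = tiny_complex("e05", ld, seq2),
    p3_la  = tiny_complex("e06", la, seq3),
    p4_le  = tiny_complex("e07", ligand_template("alkane"), seq4),
    p1_la2 = tiny_complex("e08", la, seq1),   # second structure of P1:La
    p4_lf  = tiny_complex("e09", ligand_template("adenine"), seq4),
    p4_lg  = tiny_complex("e10", ligand_template("ethanol"), seq4)
  )
  net <- build_network(unname(cx))
  expect_equal(nrow(net$proteins), 4)
  expect_equal(nrow(net$chemicals), 7)
  expect_equal(nrow(net$edges), 10)
  trips <- enumerate_triplets(net)
  tab <- triplet_table(trips)

  # hand enumeration. La is bound by P1, P2, P3; ordered protein pairs
  # passing the 80% filter: (P1,P2), (P2,P1), (P2,P3) — P3 shares 85%
  # identity with P1 so both (P1,P3) orders drop, (P3,P2) offers no
  # transfer ligand, and P4 shares nothing. Transfer ligands: P1 offers
  # Lb (ratio 1, kept) and Lc (ratio 20/6 > 2, dropped); P2 offers Ld
  # (ratio 6/4, kept). The P1:La edge is realised by two structures
  # (e01, e08), so combinations through it double:
  #   P1 -> P2: Lb x (2 P1:La structures x 1 P2:La)  = 2
  #   P2 -> P1: Ld x (1 P2:La x 2 P1:La)             = 2
  #   P2 -> P3: Ld x (1 x 1)                         = 1
  expect_equal(nrow(tab), 5)
  expect_equal(sum(tab$lb == "TRL"), 2)
  expect_equal(sum(tab$lb == "CBX"), 3)
  # no candidate involves the 85%-identical pair or the oversized ligand
  expect_false(any(tab$identity >= 0.80))
  expect_false(any(tab$lb == "MCY"))
  expect_true(all(tab$atom_ratio <= 2))
  expect_true(all(tab$tanimoto < 1))
  # self-audit: every emitted triplet satisfies every filter
  for (tr in trips) {
    expect_lt(attr(tr, "identity"), 0.80)
    expect_lt(attr(tr, "tanimoto"), 1)
    expect_lte(attr(tr, "atom_ratio"), 2)
  }
  # output is canonical: permuting the input leaves the table unchanged
  net_p <- build_network(unname(cx)[c(7, 2, 9, 4, 1, 10, 3, 6, 8, 5)])
  tab_p <- triplet_table(enumerate_triplets(net_p))
  expect_equal(tab[c("p1", "p2", "la", "lb")], tab_p[c("p1", "p2", "la", "lb")])
})

test_that("the atom-ratio filter cuts exactly at two-fold", {
  seqa <- ligtrans:::random_sequence(60)
  seqb <- mutate_sequence(seqa, 0.4)
  la <- make_chain_ligand(10, "C10")
  lb20 <- make_chain_ligand(20, "C20")
  lb21 <- make_chain_ligand(21, "C21")
  base <- list(
    tiny_complex("r1", la, seqa),
    tiny_complex("r2", la, seqb)
  )
  with20 <- c(base, list(tiny_complex("r3", lb20, seqa)))
  with21 <- c(base, list(tiny_complex("r4", lb21, seqa)))
  expect_equal(nrow(triplet_table(enumerate_triplets(build_network(with20)))), 1)
  expect_equal(nrow(triplet_table(enumerate_triplets(build_network(with21)))), 0)
})

test_that("triviality labels follow the identity and similarity rules", {
  mk_trip <- function(identity, tani, solvent = FALSE) {
    cx <- tiny_complex("t1", ligand_template("benzene"), strrep("AC", 15))
    lb <- ligand_template("triol")
    if (solvent) lb$is_solvent <- TRUE
    c_lb <- plc(cx$protein, lb, require_contacts = FALSE)
    tr <- candidate_triplet(cx, cx, c_lb, check = FALSE)
    attr(tr, "identity") <- identity
    attr(tr, "tanimoto") <- tani
    tr
  }
  expect_equal(classify_prediction(mk_trip(0.45, 0.20)), "easy_protein")
  expect_equal(classify_prediction(mk_trip(0.20, 0.95)), "easy_chemical")
  expect_equal(classify_prediction(mk_trip(0.20, 0.30)), "nontrivial")
  expect_setequal(classify_prediction(mk_trip(0.20, 0.30, solvent = TRUE)),
                  "solvent_involved")
  expect_setequal(classify_prediction(mk_trip(0.35, 0.95)),
                  c("easy_protein", "easy_chemical"))
})
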