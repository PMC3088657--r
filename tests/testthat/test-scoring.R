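# a single-carbon "ligand" at the origin, for analytic clash geometry
one_carbon_ligand <- function() {
  ligand("CX1", tibble::tibble(
    eleno = 1L, name = "C1", element = "C", x = 0, y = 0, z = 0,
    chain = "L", resno = 1L, insert = "", resid = "CX1", hetero = TRUE,
    occ = 1), bonds = tibble::tibble(from = integer(), to = integer()))
}

test_that("clash volume matches analytic containment and lens volumes", {
  lig <- one_carbon_ligand()
  far <- make_chain(cbind(8 + (1:5), 0, 0), rep("C", 5))
  expect_equal(clash_volume(far, lig), 0)
  # full containment: concentric equal spheres overlap in one full sphere
  conc <- make_chain(rbind(c(0, 0, 0), cbind(30 + (1:4), 0, 0)), rep("C", 5))
  v_sphere <- 4 / 3 * pi * 1.7^3
  expect_equal(clash_volume(conc, lig), v_sphere, tolerance = 0.05 * v_sphere)
  # two equal spheres at centre distance 2
  two <- make_chain(rbind(c(2, 0, 0), cbind(30 + (1:4), 0, 0)), rep("C", 5))
  v_lens <- lens_volume(1.7, 1.7, 2.0)
  expect_equal(clash_volume(two, lig), v_lens, tolerance = 0.05 * v_lens)
  # no double counting: two protein atoms overlapping the same ligand sphere
  # can never exceed the ligand sphere volume
  twin <- make_chain(rbind(c(0.5, 0, 0), c(-0.5, 0, 0), cbind(30 + (1:3), 0, 0)),
                     rep("C", 5))
  expect_lte(clash_volume(twin, lig), v_sphere * 1.05)
})

test_that("grid clash volume converges with spacing", {
  lig <- one_carbon_ligand()
  two <- make_chain(rbind(c(2, 0, 0), cbind(30 + (1:4), 0, 0)), rep("C", 5))
  v_coarse <- clash_volume(two, lig, scoring_config(grid_spacing = 0.25))
  v_fine <- clash_volume(two, lig, scoring_config(grid_spacing = 0.125))
  expect_lt(abs(v_coarse - v_fine) / v_fine, 0.02)
})

test_that("an isolated ligand scores zero contacts and full deficits", {
  lig <- ligand_template("triol")     # 3 C + 3 O, all O donor/acceptor
  far <- make_chain(cbind(50 + 2 * (1:10), 0, 0), rep("C", 10))
  ct <- count_interactions(far, lig)
  expect_equal(c(ct$b, ct$c, ct$d), c(0L, 0L, 0L))
  expect_equal(ct$e, 3L)   # every polar atom unsatisfied
  expect_equal(ct$f, 3L)   # every carbon uncontacted
})

test_that("a donor-acceptor pair at 3.0 A counts as a hydrogen bond", {
  lig <- ligand_template("triol")
  o_idx <- which(lig$atoms$element == "O")[1]
  o_pos <- atom_xyz(lig$atoms)[o_idx, ]
  xyz <- rbind(o_pos + c(0, 0, 3.0), cbind(50 + 2 * (1:9), 0, 0))
  ch <- make_chain(xyz, c("N", rep("C", 9)))
  ct <- count_interactions(ch, lig)
  expect_gte(ct$c, 1L)
  expect_lte(ct$e, 2L)                     # the bonded O leaves the deficit
  expect_equal(ct$e, brute_counts(ch$atoms, lig)$e)
})

test_that("interaction counts equal the brute-force distance-matrix oracle", {
  set.seed(14)
  for (tpl in c("triol", "adenine", "alkane")) {
    lig <- ligand_template(tpl)
    # ten protein atoms of mixed elements hand-placed around the ligand
    base <- atom_xyz(lig$atoms)
    xyz <- base[sample(nrow(base), 10, replace = TRUE), ] +
      matrix(runif(30, 2.2, 6), ncol = 3) * sample(c(-1, 1), 30, replace = TRUE)
    els <- sample(c("C", "N", "O", "S"), 10, replace = TRUE)
    ch <- make_chain(xyz, els)
    ct <- count_interactions(ch, lig)
    oracle <- brute_counts(ch$atoms, lig)
    expect_equal(ct[c("b", "c", "d", "e", "f")], oracle,
                 info = paste("template", tpl))
  }
})

test_that("solvent exposure counts free and caged polar atoms correctly", {
  lig <- ligand_template("carboxylate")   # two oxygens
  far <- make_chain(cbind(60 + 2 * (1:10), 0, 0), rep("C", 10))
  expect_equal(exposed_polar(far, lig), 2L)
  # a dense cage of protein atoms buries everything
  set.seed(4)
  dirs <- matrix(rnorm(3 * 300), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cage <- make_chain(dirs * 4.2, rep("C", 300))
  expect_equal(exposed_polar(cage, lig), 0L)
})

test_that("compiled SASA agrees with a fine-grained plain-R computation", {
  cx <- make_pocket_complex(91, 4.0, "triol", n_shell = 50)
  polar <- which(toupper(cx$ligand$atoms$element) != "C")
  pa <- cx$protein$atoms
  fast <- atom_sasa(cx$ligand$atoms, context = pa, n_points = 192L)
  fine <- sasa_r(cx$ligand$atoms, context = pa, n_points = 960)
  # half-buried fixture: the exposure verdicts at the 5 A^2 line agree
  expect_equal(sum(fast[polar] > 5), sum(fine[polar] > 5))
  expect_lt(max(abs(fast - fine)), 4)   # areas themselves are close (A^2)
})

ref_from_arrays <- function(vals) {
  score_reference(setNames(lapply(ligtrans:::descriptor_names(),
                                  function(nm) vals),
                           ligtrans:::descriptor_names()),
                  sigma = seq(0, 7, length.out = length(vals)))
}

test_that("normalization counts strict inequalities in the right direction", {
  ref <- ref_from_arrays(1:100)       # tie-free
  # beneficial descriptor below every reference value
  expect_equal(normalize_descriptor(0, "b", ref), 0)
  expect_equal(normalize_descriptor(1000, "b", ref), 1)
  # detrimental descriptor above every reference value
  expect_equal(normalize_descriptor(1000, "a", ref), 0)
  expect_equal(normalize_descriptor(0, "a", ref), 1)
  # the median of 100 tie-free values
  expect_equal(normalize_descriptor(50.5, "c", ref), 0.50)
  # ties contribute nothing under the strict inequality
  expect_equal(normalize_descriptor(50, "c", ref), 49 / 100)
  expect_error(normalize_descriptor(1, "z", ref), "unknown descriptor")
})

test_that("combined scores span 0 to 7 and sum their components", {
  ref <- ref_from_arrays(1:100)
  nm <- ligtrans:::descriptor_names()
  best <- tibble::as_tibble(setNames(as.list(c(0, 200, 200, 200, 0, 0, 0)), nm))
  worst <- tibble::as_tibble(setNames(as.list(c(200, 0, 0, 0, 200, 200, 200)), nm))
  mid <- tibble::as_tibble(setNames(as.list(rep(50.5, 7)), nm))
  expect_equal(combined_score(best, ref)$S, 7)
  expect_equal(combined_score(worst, ref)$S, 0)
  expect_equal(combined_score(mid, ref)$S, 3.5)
  sc <- combined_score(mid, ref)
  expect_true(all(sc$s >= 0 & sc$s <= 1))
  expect_equal(sc$S, sum(sc$s), tolerance = 1e-12)
})

test_that("improving any descriptor in its beneficial direction never lowers S", {
  set.seed(77)
  ref <- ref_from_arrays(sort(runif(200, 0, 100)))
  nm <- ligtrans:::descriptor_names()
  det <- ligtrans:::descriptor_detrimental()
  base_vals <- runif(7, 0, 100)
  base <- tibble::as_tibble(setNames(as.list(base_vals), nm))
  s0 <- combined_score(base, ref)$S
  for (k in seq_along(nm)) {
    for (step in c(1, 10, 50)) {
      v <- base_vals
      v[k] <- v[k] + if (det[[nm[k]]]) -step else step
      s1 <- combined_score(tibble::as_tibble(setNames(as.list(v), nm)), ref)$S
      expect_gte(s1, s0)
    }
  }
})

test_that("the empirical p-value is the strict exceedance fraction", {
  sigma <- seq_len(1000) / 100          # tie-free scores
  ref <- score_reference(
    setNames(lapply(ligtrans:::descriptor_names(), function(nm) 1:1000),
             ligtrans:::descriptor_names()), sigma = sigma)
  expect_equal(p_value(max(sigma) + 1, ref), 0)
  expect_equal(p_value(min(sigma) - 1, ref), 1)
  # S at the 95th percentile of a tie-free set of 1000
  expect_equal(p_value(sigma[950], ref), 0.05)
  empty <- ref; empty$sigma <- numeric()
  expect_error(p_value(1, empty), "empty")
})

test_that("element-only typing fallback is flagged", {
  lig <- ligand_template("triol")
  lig$bonds <- NULL
  far <- make_chain(cbind(50 + 2 * (1:10), 0, 0), rep("C", 10))
  ct <- count_interactions(far, lig)
  expect_true(ct$element_only_typing)
})
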