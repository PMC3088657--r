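#' Swap the ligands of two complexes at matched geometric centers
#'
#' Each ligand is translated so that its heavy-atom geometric center
#' coincides with the other ligand's center; orientation is preserved
#' exactly (no rotation to optimise the fit). This is the decoy construction
#' behind the empirical null: random fits of small molecules into protein
#' pockets.
#'
#' @param c1,c2 [plc] records.
#' @return list of two decoy complexes (class `plc`; contacts recomputed,
#'   not required to pass the contact rule — that is the filter's job).
#' @export
swap_ligands <- function(c1, c2) {
  ctr <- function(lg) colMeans(atom_xyz(lg$atoms))
  move_to <- function(lg, center) {
    shift <- center - ctr(lg)
    lg$atoms$x <- lg$atoms$x + shift[1]
    lg$atoms$y <- lg$atoms$y + shift[2]
    lg$atoms$z <- lg$atoms$z + shift[3]
    lg
  }
  d1 <- plc(c1$protein, move_to(c2$ligand, ctr(c1$ligand)),
            source = c1$source, require_contacts = FALSE)
  d2 <- plc(c2$protein, move_to(c1$ligand, ctr(c2$ligand)),
            source = c2$source, require_contacts = FALSE)
  list(d1, d2)
}

# TRUE when some protein-ligand heavy-atom pair is closer than
# factor * (r_i + r_j) -- the severe-clash decoy rejection rule
has_severe_clash <- function(cx, factor = 0.5) {
  pa <- heavy_atoms(cx$protein); la <- heavy_atoms(cx$ligand)
  d <- cross_dist(atom_xyz(pa), atom_xyz(la))
  lim <- factor * outer(vdw_radius(pa$element), vdw_radius(la$element), "+")
  any(d < lim)
}

#' Generate the random-decoy negative set
#'
#' Repeatedly samples a pair of distinct complexes, swaps their ligands at
#' matched geometric centers ([swap_ligands]) and keeps each resulting decoy
#' that neither clashes severely (some heavy-atom pair closer than half the
#' sum of vdW radii) nor fails the contact rule (at least two heavy-atom
#' pairs within 5 Angstrom). Sampling is with replacement across draws, so a
#' complex may contribute to many decoys. Fully reproducible from the seed.
#'
#' @param complexes list of at least two [plc] records.
#' @param n_target number of accepted decoys wanted.
#' @param seed integer seed.
#' @param config a [scoring_config] (`severe_clash_factor`,
#'   `contact_cutoff`).
#' @param draw_cap_factor give up after `draw_cap_factor * n_target` draws
#'   (default 50) and return the partial set with a warning.
#' @return list of decoy [plc] records, length `n_target` unless the draw
#'   cap was reached.
#' @export
generate_negatives <- function(complexes, n_target, seed,
                               config = scoring_config(),
                               draw_cap_factor = 50) {
  stopifnot(length(complexes) >= 2, n_target >= 1)
  set.seed(as.integer(seed))
  decoys <- vector("list", n_target)
  n_acc <- 0L
  draws <- 0L
  cap <- draw_cap_factor * n_target
  while (n_acc < n_target && draws < cap) {
    draws <- draws + 1L
    pick <- sample.int(length(complexes), 2)   # without replacement per draw
    cand <- swap_ligands(complexes[[pick[1]]], complexes[[pick[2]]])
    for (d in cand) {
      if (n_acc >= n_target) break
      if (has_severe_clash(d, config$severe_clash_factor)) next
      ct <- contact_pairs(d$protein, d$ligand, cutoff = config$contact_cutoff)
      if (nrow(ct) < 2) next
      d$contacts <- ct
      n_acc <- n_acc + 1L
      decoys[[n_acc]] <- d
    }
  }
  if (n_acc < n_target) {
    warning("draw cap reached: accepted ", n_acc, " of ", n_target, " decoys")
    decoys <- decoys[seq_len(n_acc)]
  }
  decoys
}

#' Build the score reference from a decoy set
#'
#' Computes the seven descriptors for every decoy and the decoy combined
#' scores (sigma) by leave-one-out normalisation: each decoy's descriptors
#' are ranked against the remaining decoys, exactly as a query would be
#' ranked against the full set.
#'
#' @param decoys list of decoy [plc] records, at least 100 (desk-scale
#'   floor; 100,000 is the paper-scale default).
#' @param config a [scoring_config].
#' @param seed seed recorded in the metadata (bookkeeping only).
#' @return a [score_reference].
#' @export
build_reference <- function(decoys, config = scoring_config(), seed = NA) {
  if (length(decoys) < 100) {
    stop("need at least 100 decoys to build a reference, got ", length(decoys))
  }
  desc <- purrr::map_dfr(decoys, function(d) {
    descriptor_vector(d$protein, d$ligand, config)
  })
  sigma <- loo_scores(desc)
  score_reference(
    values = as.list(desc[descriptor_names()]),
    sigma = sigma,
    metadata = list(seed = seed, n_decoys = length(decoys),
                    config = unclass(config), created = as.character(Sys.time()))
  )
}

#' Leave-one-out p-values of the decoys themselves
#'
#' Each decoy's combined score (already leave-one-out normalised in the
#' reference's sigma) is compared against the other decoys' scores:
#' `p_i = #(sigma_j > S_i, j != i) / (n - 1)`. Under the null these are
#' uniform on `[0, 1]` up to discreteness, which is the calibration check
#' for the empirical p-value.
#'
#' @param ref a [score_reference].
#' @return numeric vector of p-values, one per decoy.
#' @export
reference_loo_pvalues <- function(ref) {
  s <- ref$sigma
  n <- length(s)
  (n - rank(s, ties.method = "max")) / (n - 1)
}
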