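#' Geometric scoring configuration
#'
#' All geometric thresholds used by the descriptor computations, with their
#' defaults: contact cutoff 5.0 A (shared with complex extraction); hydrogen
#' bond donor-acceptor window 2.5-3.5 A; van der Waals contact window from
#' (r_i + r_j - 0.6) to (r_i + r_j + 0.5) A; solvent exposure threshold
#' 5 A^2 of accessible area with a 1.4 A probe and 192 sphere points; clash
#' grid spacing 0.25 A; severe-clash rejection at half the sum of vdW radii.
#' Every output that depends on these records the configuration used.
#'
#' @param ... overrides for individual keys.
#' @return named list of class `scoring_config`.
#' @export
scoring_config <- function(...) {
  cfg <- list(
    contact_cutoff = 5.0,
    hbond_min = 2.5, hbond_max = 3.5,
    vdw_outer = 0.5, vdw_inner = 0.6,
    sasa_threshold = 5.0, probe = 1.4, sasa_points = 192L,
    grid_spacing = 0.25,
    severe_clash_factor = 0.5,
    promiscuity_threshold = 20L,
    min_heavy_atoms = 4L,
    min_ca_pairs = 30L,
    p_cutoff = 0.05
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "scoring_config")
}

#' Clash volume between a ligand and a protein
#'
#' Total overlap volume between the union of ligand heavy-atom van der Waals
#' spheres and the union of protein heavy-atom spheres, integrated on a
#' regular grid over the ligand bounding box padded by the largest vdW
#' radius. Grid points inside both unions are counted once, so overlap with
#' several protein atoms is never double counted.
#'
#' @param protein a [protein_chain] (or heavy-atom tibble).
#' @param ligand a [ligand] (or heavy-atom tibble).
#' @param config a [scoring_config]; `grid_spacing` sets the resolution.
#' @return clash volume in cubic Angstrom.
#' @export
clash_volume <- function(protein, ligand, config = scoring_config()) {
  pa <- heavy_atoms(protein); la <- heavy_atoms(ligand)
  if (nrow(pa) == 0 || nrow(la) == 0) return(0)
  .clash_volume_grid(atom_xyz(la), vdw_radius(la$element),
                     atom_xyz(pa), vdw_radius(pa$element),
                     config$grid_spacing)
}

#' Interaction counts between a ligand and a protein
#'
#' Computes descriptors b-f of the empirical score from the heavy-atom
#' distance matrix: `b` protein-ligand pairs within the contact cutoff; `c`
#' donor/acceptor pairs with compatible typing at hydrogen-bond distance;
#' `d` pairs inside the van der Waals contact window; `e` ligand
#' donor/acceptor atoms left without a partner under rule c; `f` ligand
#' carbons without a partner under rule d. Donor/acceptor typing uses the
#' ligand bond graph (ether vs hydroxyl oxygens and the like); without a
#' graph it falls back to element-only typing and flags the result.
#'
#' @inheritParams clash_volume
#' @return list with integer fields `b`, `c`, `d`, `e`, `f` and logical
#'   `element_only_typing`.
#' @export
count_interactions <- function(protein, ligand, config = scoring_config()) {
  pa <- heavy_atoms(protein)
  la <- ligand$atoms
  n_lig <- nrow(la)
  lp <- ligand_polar_flags(ligand)
  is_c <- toupper(la$element) == "C"
  if (nrow(pa) == 0 || n_lig == 0) {
    return(list(b = 0L, c = 0L, d = 0L,
                e = sum(lp$donor | lp$acceptor), f = sum(is_c),
                element_only_typing = lp$element_only[1] %||% FALSE))
  }
  d <- cross_dist(atom_xyz(pa), atom_xyz(la))     # protein x ligand
  b <- sum(d <= config$contact_cutoff)

  pp <- protein_polar_flags(pa)
  compat <- outer(pp$donor, lp$acceptor, "&") | outer(pp$acceptor, lp$donor, "&")
  hb <- d >= config$hbond_min & d <= config$hbond_max & compat
  cc <- sum(hb)

  rsum <- outer(vdw_radius(pa$element), vdw_radius(la$element), "+")
  vdw <- d <= rsum + config$vdw_outer & d > rsum - config$vdw_inner
  dd <- sum(vdw)

  polar_lig <- lp$donor | lp$acceptor
  e <- sum(polar_lig & colSums(hb) == 0)
  f <- sum(is_c & colSums(vdw) == 0)
  list(b = as.integer(b), c = as.integer(cc), d = as.integer(dd),
       e = as.integer(e), f = as.integer(f),
       element_only_typing = isTRUE(lp$element_only[1]))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Solvent-exposed polar ligand atoms
#'
#' Counts ligand hydrogen-bond donor/acceptor atoms whose solvent-accessible
#' surface area in the complex exceeds the configured threshold
#' (Shrake-Rupley, 1.4 A probe, 192 sphere points by default); protein and
#' ligand heavy atoms together form the occluding set.
#'
#' @inheritParams clash_volume
#' @return integer count.
#' @export
exposed_polar <- function(protein, ligand, config = scoring_config()) {
  lp <- ligand_polar_flags(ligand)
  polar_idx <- which(lp$donor | lp$acceptor)
  if (length(polar_idx) == 0) return(0L)
  pa <- heavy_atoms(protein)
  all_xyz <- rbind(atom_xyz(ligand$atoms), atom_xyz(pa))
  all_r <- c(vdw_radius(ligand$atoms$element), vdw_radius(pa$element))
  areas <- .sasa_shrake_rupley(all_xyz, all_r, as.integer(polar_idx),
                               config$probe, as.integer(config$sasa_points))
  sum(areas > config$sasa_threshold)
}

#' Per-atom solvent-accessible surface area
#'
#' @param atoms heavy-atom tibble (the atoms to report).
#' @param context optional additional occluding heavy-atom tibble.
#' @param probe probe radius in Angstrom.
#' @param n_points sphere points per atom.
#' @return numeric vector of areas (A^2), one per row of `atoms`.
#' @export
atom_sasa <- function(atoms, context = NULL, probe = 1.4, n_points = 192L) {
  xyz <- atom_xyz(atoms); r <- vdw_radius(atoms$element)
  if (!is.null(context) && nrow(context) > 0) {
    xyz <- rbind(xyz, atom_xyz(context))
    r <- c(r, vdw_radius(context$element))
  }
  .sasa_shrake_rupley(xyz, r, seq_len(nrow(atoms)), probe, as.integer(n_points))
}

#' The seven-descriptor vector of a (putative) complex
#'
#' @param protein a [protein_chain] in the same frame as `ligand`.
#' @param ligand a [ligand].
#' @param config a [scoring_config].
#' @return one-row tibble with columns `a_clash_volume`, `b_contacts`,
#'   `c_hbonds`, `d_vdw_contacts`, `e_unsatisfied_polar`,
#'   `f_uncontacted_carbons`, `g_exposed_polar` and `element_only_typing`.
#' @export
descriptor_vector <- function(protein, ligand, config = scoring_config()) {
  ct <- count_interactions(protein, ligand, config)
  tibble(
    a_clash_volume = clash_volume(protein, ligand, config),
    b_contacts = ct$b, c_hbonds = ct$c, d_vdw_contacts = ct$d,
    e_unsatisfied_polar = ct$e, f_uncontacted_carbons = ct$f,
    g_exposed_polar = as.integer(exposed_polar(protein, ligand, config)),
    element_only_typing = ct$element_only_typing
  )
}

descriptor_names <- function() {
  c("a_clash_volume", "b_contacts", "c_hbonds", "d_vdw_contacts",
    "e_unsatisfied_polar", "f_uncontacted_carbons", "g_exposed_polar")
}

# beneficial descriptors count reference values strictly below the query;
# detrimental ones (a, e, f, g) count reference values strictly above
descriptor_detrimental <- function() {
  c(a_clash_volume = TRUE, b_contacts = FALSE, c_hbonds = FALSE,
    d_vdw_contacts = FALSE, e_unsatisfied_polar = TRUE,
    f_uncontacted_carbons = TRUE, g_exposed_polar = TRUE)
}
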