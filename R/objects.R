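#' Construct a protein chain object
#'
#' A polymer chain: an atom table plus its one-letter sequence. Atoms are kept
#' as parsed (including any hydrogens), but every distance computation in the
#' package uses heavy atoms only.
#'
#' @param chain_id chain identifier string.
#' @param atoms atom tibble (columns `eleno`, `name`, `element`, `x`, `y`,
#'   `z`, `chain`, `resno`, `insert`, `resid`, `hetero`, `occ`).
#' @param sequence one-letter amino-acid sequence, one letter per residue.
#' @param source structure accession or file identifier.
#' @return an object of class `protein_chain`.
#' @export
protein_chain <- function(chain_id, atoms, sequence, source = NA_character_) {
  stopifnot(is.character(chain_id), nchar(sequence) >= 1)
  resk <- unique(paste(atoms$resno, atoms$insert))
  if (length(resk) != nchar(sequence)) {
    stop("sequence length (", nchar(sequence), ") != residue count (",
         length(resk), ") for chain ", chain_id)
  }
  structure(
    list(chain_id = chain_id, atoms = as_tibble(atoms),
         sequence = sequence, source = source),
    class = "protein_chain"
  )
}

#' @export
print.protein_chain <- function(x, ...) {
  cat(sprintf("<protein_chain %s/%s: %d residues, %d atoms>\n",
              x$source, x$chain_id, nchar(x$sequence), nrow(x$atoms)))
  invisible(x)
}

heavy_atoms <- function(obj) {
  a <- if (inherits(obj, "protein_chain") || inherits(obj, "ligand")) obj$atoms else obj
  a[!is_hydrogen(a$element), , drop = FALSE]
}

ca_atoms <- function(chain) {
  a <- chain$atoms
  a[a$name == "CA" & !is_hydrogen(a$element), , drop = FALSE]
}

#' Construct a ligand instance
#'
#' A small-molecule instance: heavy atoms, an element-labelled bond graph and
#' bookkeeping flags. Hydrogens are dropped on construction.
#'
#' @param het_code component identifier (three letters or longer).
#' @param atoms atom tibble; hydrogens are removed.
#' @param bonds tibble with integer columns `from`, `to` indexing the heavy
#'   atoms, or `NULL` to perceive bonds from interatomic distances
#'   (covalent radii + 0.45 Angstrom tolerance).
#' @param is_solvent,is_promiscuous annotation flags.
#' @param source structure accession or file identifier.
#' @param instance_id identifier of this copy within its source (chain/resno).
#' @return an object of class `ligand`.
#' @export
ligand <- function(het_code, atoms, bonds = NULL, is_solvent = FALSE,
                   is_promiscuous = FALSE, source = NA_character_,
                   instance_id = NA_character_) {
  atoms <- as_tibble(atoms)
  atoms <- atoms[!is_hydrogen(atoms$element), , drop = FALSE]
  if (is.null(bonds)) bonds <- perceive_bonds(atoms)
  bonds <- as_tibble(bonds)
  if (nrow(bonds) > 0) {
    idx <- c(bonds$from, bonds$to)
    if (any(idx < 1 | idx > nrow(atoms))) stop("bond indices out of range")
  }
  structure(
    list(het_code = het_code, atoms = atoms, bonds = bonds,
         is_solvent = is_solvent, is_promiscuous = is_promiscuous,
         source = source, instance_id = instance_id),
    class = "ligand"
  )
}

#' @export
print.ligand <- function(x, ...) {
  cat(sprintf("<ligand %s: %d heavy atoms, %d bonds%s%s>\n", x$het_code,
              nrow(x$atoms), nrow(x$bonds),
              if (isTRUE(x$is_solvent)) ", solvent" else "",
              if (isTRUE(x$is_promiscuous)) ", promiscuous" else ""))
  invisible(x)
}

#' Perceive covalent bonds from heavy-atom distances
#'
#' Two heavy atoms are bonded when their distance is at most the sum of their
#' single-bond covalent radii plus a 0.45 Angstrom tolerance.
#'
#' @param atoms heavy-atom tibble.
#' @return tibble with columns `from`, `to` (integer atom indices, from < to).
#' @export
perceive_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(tibble(from = integer(), to = integer()))
  xyz <- atom_xyz(atoms)
  r <- covalent_radius(atoms$element)
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(r, r, "+") + 0.45
  hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
  tibble(from = as.integer(hit[, 1]), to = as.integer(hit[, 2]))
}

#' Construct a protein-ligand complex record
#'
#' One polymer chain and one bound small molecule, together with the list of
#' heavy-atom contacts (pairs closer than the contact cutoff) that qualified
#' the pair as a complex.
#'
#' @param protein a `protein_chain`.
#' @param ligand a `ligand`.
#' @param contacts tibble with columns `p_atom`, `l_atom` (row indices into
#'   the heavy-atom tables) and `dist` (Angstrom), or `NULL` to recompute at
#'   the 5 Angstrom cutoff.
#' @param source structure accession or file identifier.
#' @param require_contacts if `TRUE` (default), at least two contacts are
#'   required, mirroring complex extraction; decoys set this to `FALSE`
#'   until filtered.
#' @return an object of class `plc`.
#' @export
plc <- function(protein, ligand, contacts = NULL, source = NA_character_,
                require_contacts = TRUE) {
  stopifnot(inherits(protein, "protein_chain"), inherits(ligand, "ligand"))
  if (is.null(contacts)) contacts <- contact_pairs(protein, ligand, cutoff = 5.0)
  if (require_contacts && nrow(contacts) < 2) {
    stop("complex requires >= 2 heavy-atom contacts within 5 Angstrom")
  }
  if (nrow(contacts) > 0 && any(contacts$dist > 5.0 + 1e-9)) {
    stop("contact list includes a pair beyond the 5 Angstrom cutoff")
  }
  structure(
    list(protein = protein, ligand = ligand, contacts = contacts,
         source = if (is.na(source)) protein$source else source),
    class = "plc"
  )
}

#' @export
print.plc <- function(x, ...) {
  cat(sprintf("<complex %s: chain %s + %s (%d contacts)>\n",
              x$source, x$protein$chain_id, x$ligand$het_code, nrow(x$contacts)))
  invisible(x)
}

# heavy-atom protein/ligand pairs within cutoff
contact_pairs <- function(protein, ligand, cutoff = 5.0) {
  pa <- heavy_atoms(protein)
  la <- heavy_atoms(ligand)
  if (nrow(pa) == 0 || nrow(la) == 0) {
    return(tibble(p_atom = integer(), l_atom = integer(), dist = double()))
  }
  d <- cross_dist(atom_xyz(pa), atom_xyz(la))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  tibble(
    p_atom = as.integer(hit[, 1]),
    l_atom = as.integer(hit[, 2]),
    dist = d[hit]
  ) %>% arrange(.data$p_atom, .data$l_atom)
}

# all pairwise distances between two coordinate sets (rows)
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
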