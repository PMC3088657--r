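#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% filter mutate select arrange group_by ungroup summarise
#'   bind_rows left_join row_number n distinct pull across all_of
#' @importFrom rlang .data
NULL

# Bondi van der Waals radii (Angstrom); fallback 1.7 for unlisted elements
.vdw_table <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, B = 1.92
)

# single-bond covalent radii (Angstrom), used for distance-based bond perception
.cov_table <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20, B = 0.84
)

#' Van der Waals radius of an element
#'
#' Bondi radii for the common elements of protein-ligand structures; elements
#' not in the table fall back to the carbon radius (1.7 Angstrom).
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .vdw_table[toupper(element)]
  r[is.na(r)] <- 1.7
  unname(r)
}

covalent_radius <- function(element) {
  r <- .cov_table[toupper(element)]
  r[is.na(r)] <- 0.76
  unname(r)
}

is_hydrogen <- function(element) toupper(element) %in% c("H", "D", "T")

#' Extract an N x 3 coordinate matrix from an atom table
#'
#' @param atoms a tibble with numeric columns `x`, `y`, `z`.
#' @return numeric matrix with one row per atom.
#' @export
atom_xyz <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

# hydrogen-bond donor/acceptor typing for ligand heavy atoms.
# With a bond graph: ether/ester O (degree 2, all-C neighbours) is acceptor
# only; terminal or hydroxyl-like O is donor+acceptor; N is donor, and
# acceptor unless quaternary; S is a weak acceptor (and donor when terminal).
# Without a bond graph the typing degrades to element-only (N/O/S all
# donor+acceptor) and the caller is expected to flag the fallback.
ligand_polar_flags <- function(ligand) {
  el <- toupper(ligand$atoms$element)
  n <- length(el)
  donor <- rep(FALSE, n)
  acceptor <- rep(FALSE, n)
  has_graph <- !is.null(ligand$bonds) && nrow(ligand$bonds) > 0
  deg <- rep(0L, n)
  if (has_graph) {
    tab <- table(factor(c(ligand$bonds$from, ligand$bonds$to), levels = seq_len(n)))
    deg <- as.integer(tab)
  }
  for (i in seq_len(n)) {
    e <- el[i]
    if (e == "O") {
      acceptor[i] <- TRUE
      donor[i] <- !has_graph || deg[i] <= 1
    } else if (e == "N") {
      donor[i] <- TRUE
      acceptor[i] <- !has_graph || deg[i] <= 2
    } else if (e == "S") {
      acceptor[i] <- TRUE
      donor[i] <- !has_graph || deg[i] <= 1
    }
  }
  tibble(donor = donor, acceptor = acceptor, element_only = !has_graph)
}

# protein-side polar typing by element: N donates, O accepts, S (cysteine)
# can do either.
protein_polar_flags <- function(atoms) {
  el <- toupper(atoms$element)
  tibble(
    donor = el %in% c("N", "S"),
    acceptor = el %in% c("O", "S")
  )
}
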