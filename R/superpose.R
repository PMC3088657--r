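#' Rigid-body transforms
#'
#' A proper rotation plus a translation, acting on row-vector coordinates as
#' `x %*% t(rotation) + translation`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (Angstrom).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6) stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform: rotation %.2f deg, |t| = %.3f A>\n",
              ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param tf a [rigid_transform].
#' @param x an N x 3 coordinate matrix, an atom tibble with `x`,`y`,`z`
#'   columns, or a `protein_chain` / `ligand` / `plc` object.
#' @return the transformed object, same type as the input.
#' @export
apply_transform <- function(tf, x) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (is.matrix(x)) {
    return(sweep(x %*% t(tf$rotation), 2, tf$translation, "+"))
  }
  if (inherits(x, "plc")) {
    x$protein <- apply_transform(tf, x$protein)
    x$ligand <- apply_transform(tf, x$ligand)
    return(x)
  }
  if (inherits(x, "protein_chain") || inherits(x, "ligand")) {
    x$atoms <- apply_transform(tf, x$atoms)
    return(x)
  }
  xyz <- apply_transform(tf, atom_xyz(x))
  x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
  x
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(t2, t1)` applies `t1` first, then `t2`.
#'
#' @param t2,t1,tf rigid transforms.
#' @return a [rigid_transform].
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t1$translation %*% t(t2$rotation)) + t2$translation)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation),
                  as.numeric(-tf$translation %*% tf$rotation))
}

#' Least-squares rigid superposition of paired points (Kabsch)
#'
#' Finds the proper rotation and translation mapping `points_b` onto
#' `points_a` that minimise the root-mean-square deviation over the paired
#' rows. Reflections are never chosen: when the optimal orthogonal matrix has
#' a negative determinant, the smallest singular direction is flipped.
#'
#' @param points_a,points_b N x 3 matrices, rows paired by index, N >= 3.
#' @return list with `transform` (a [rigid_transform] mapping B onto A) and
#'   `rmsd` (the minimised RMSD in Angstrom).
#' @export
kabsch <- function(points_a, points_b) {
  points_a <- as.matrix(points_a); points_b <- as.matrix(points_b)
  if (nrow(points_a) != nrow(points_b)) stop("point sets must be paired")
  n <- nrow(points_a)
  if (n < 3) stop("degenerate input: need at least 3 paired points")
  ca <- colMeans(points_a); cb <- colMeans(points_b)
  ac <- sweep(points_a, 2, ca); bc <- sweep(points_b, 2, cb)
  sv_a <- svd(ac)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1)) {
    warning("collinear points: rotation about the common axis is unresolved")
  }
  h <- crossprod(bc, ac)                # 3x3 cross-covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(ca - cb %*% t(rot))
  tf <- rigid_transform(rot, tr)
  fitted <- apply_transform(tf, points_b)
  list(transform = tf, rmsd = rmsd_xyz(points_a, fitted))
}

#' RMSD between two paired coordinate sets
#'
#' @param a,b N x 3 matrices, rows paired.
#' @return RMSD in Angstrom.
#' @export
rmsd_xyz <- function(a, b) {
  sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
}

#' Align two protein chains by sequence
#'
#' Global Needleman-Wunsch alignment (BLOSUM62, gap open 11, gap extend 1)
#' of the one-letter sequences; the correspondence is the set of aligned
#' non-gap positions for which both residues have a C-alpha atom. Sequence
#' identity is the number of identical aligned residues divided by the
#' shorter sequence length.
#'
#' @param a,b [protein_chain] objects with >= 20 residues each.
#' @return list with `pairs` (tibble of residue indices `idx_a`, `idx_b`,
#'   1-based within each chain), `identity` (fraction), and `score`.
#' @export
align_protein_pair <- function(a, b) {
  if (nchar(a$sequence) < 20 || nchar(b$sequence) < 20) {
    stop("too short: protein alignment needs >= 20 residues per chain")
  }
  # BLOSUM62 has no row for gaps/unknowns beyond X; map exotic letters to X
  sa <- gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", a$sequence)
  sb <- gsub("[^ACDEFGHIKLMNPQRSTVWYX]", "X", b$sequence)
  pa <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  qb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- cumsum(qa != "-"); ib <- cumsum(qb != "-")
  both <- qa != "-" & qb != "-"
  ident <- sum(both & qa == qb) / min(nchar(sa), nchar(sb))
  pairs <- tibble(idx_a = ia[both], idx_b = ib[both])
  # keep only residues with a C-alpha in both chains
  ca_a <- ca_residue_index(a); ca_b <- ca_residue_index(b)
  pairs <- pairs[pairs$idx_a %in% ca_a & pairs$idx_b %in% ca_b, , drop = FALSE]
  list(pairs = pairs, identity = ident, score = Biostrings::score(pa))
}

# residue indices (1-based, in residue order) that carry a C-alpha atom
ca_residue_index <- function(chain) {
  resk <- unique(paste(chain$atoms$resno, chain$atoms$insert))
  ca <- ca_atoms(chain)
  match(unique(paste(ca$resno, ca$insert)), resk)
}

# C-alpha coordinates for given residue indices
ca_coords_at <- function(chain, idx) {
  resk <- unique(paste(chain$atoms$resno, chain$atoms$insert))
  ca <- ca_atoms(chain)
  key <- paste(ca$resno, ca$insert)
  atom_xyz(ca)[match(resk[idx], key), , drop = FALSE]
}

#' Read a residue correspondence file
#'
#' Plain-text interface for user-supplied structural alignments of remote
#' homologs: two whitespace-separated columns `chain:resno` for the reference
#' and the moving chain; lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return tibble with columns `chain_a`, `resno_a`, `chain_b`, `resno_b`.
#' @export
read_correspondence <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  parts <- strsplit(ln, "\\s+")
  bad <- vapply(parts, length, 1L) != 2
  if (any(bad)) stop("correspondence file: each line needs two chain:resno fields")
  split2 <- function(x) do.call(rbind, strsplit(x, ":", fixed = TRUE))
  a <- split2(vapply(parts, `[`, "", 1))
  b <- split2(vapply(parts, `[`, "", 2))
  tibble(chain_a = a[, 1], resno_a = as.integer(a[, 2]),
         chain_b = b[, 1], resno_b = as.integer(b[, 2]))
}

#' Map atoms between two chemically identical ligands
#'
#' When both ligands carry the same HET code and their atom names match
#' one-to-one, the map is name-based. Otherwise the element-labelled bond
#' graphs are matched by VF2 isomorphism and, among all isomorphisms
#' (automorphisms included), the one minimising the post-fit Kabsch RMSD is
#' returned.
#'
#' @param a,b [ligand] objects.
#' @param prefer_names use the name shortcut when available (default TRUE);
#'   set FALSE to always minimise over graph isomorphisms.
#' @return tibble with columns `idx_a`, `idx_b` (heavy-atom indices) and
#'   attribute `source` (`"name"` or `"graph"`).
#' @export
ligand_atom_map <- function(a, b, prefer_names = TRUE) {
  na <- nrow(a$atoms); nb <- nrow(b$atoms)
  if (prefer_names && identical(a$het_code, b$het_code) &&
      !anyDuplicated(a$atoms$name) && !anyDuplicated(b$atoms$name) &&
      setequal(a$atoms$name, b$atoms$name) && na == nb) {
    m <- tibble(idx_a = seq_len(na), idx_b = match(a$atoms$name, b$atoms$name))
    attr(m, "source") <- "name"
    return(m)
  }
  maps <- ligand_isomorphisms(a, b)
  if (length(maps) == 0) {
    stop("not the same ligand: bond graphs are not isomorphic (",
         a$het_code, " vs ", b$het_code, ")")
  }
  xa <- atom_xyz(a$atoms); xb <- atom_xyz(b$atoms)
  fits <- vapply(maps, function(mp) {
    if (na >= 3) kabsch(xa, xb[mp, , drop = FALSE])$rmsd else 0
  }, numeric(1))
  best <- maps[[which.min(fits)]]
  m <- tibble(idx_a = seq_len(na), idx_b = as.integer(best))
  attr(m, "source") <- "graph"
  m
}

# all element-respecting isomorphisms a -> b (list of index vectors:
# position i holds the b-atom matched to a-atom i); empty list if none
ligand_isomorphisms <- function(a, b) {
  ea <- toupper(a$atoms$element); eb <- toupper(b$atoms$element)
  if (nrow(a$atoms) != nrow(b$atoms)) return(list())
  if (!identical(sort(ea), sort(eb))) return(list())
  lev <- sort(unique(c(ea, eb)))
  ga <- igraph::graph_from_data_frame(
    d = as.data.frame(a$bonds), directed = FALSE,
    vertices = data.frame(name = seq_along(ea)))
  gb <- igraph::graph_from_data_frame(
    d = as.data.frame(b$bonds), directed = FALSE,
    vertices = data.frame(name = seq_along(eb)))
  maps <- igraph::graph.get.isomorphisms.vf2(
    ga, gb,
    vertex.color1 = as.integer(factor(ea, lev)),
    vertex.color2 = as.integer(factor(eb, lev))
  )
  lapply(maps, as.integer)
}

#' Superpose one complex onto another via the shared protein
#'
#' Aligns the two protein sequences (or uses a supplied residue
#' correspondence), then fits the corresponded C-alpha atoms by Kabsch. The
#' returned transform maps the whole moving complex into the reference frame.
#'
#' @param ref,mov [plc] objects.
#' @param correspondence optional tibble from [read_correspondence] giving
#'   residue pairs `resno_a` (in `ref`) / `resno_b` (in `mov`).
#' @param min_pairs minimum number of corresponded C-alpha pairs (default 3).
#' @return a [rigid_transform] mapping `mov` into `ref`'s frame, with
#'   attributes `n_pairs`, `identity` and `rmsd`.
#' @export
superpose_by_protein <- function(ref, mov, correspondence = NULL, min_pairs = 3) {
  a <- ref$protein; b <- mov$protein
  if (is.null(correspondence)) {
    al <- align_protein_pair(a, b)
    pairs <- al$pairs
    identity <- al$identity
  } else {
    resk_a <- unique(paste(a$atoms$resno, a$atoms$insert))
    resk_b <- unique(paste(b$atoms$resno, b$atoms$insert))
    pairs <- tibble(
      idx_a = match(paste(correspondence$resno_a, ""), resk_a),
      idx_b = match(paste(correspondence$resno_b, ""), resk_b)
    ) %>% filter(!is.na(.data$idx_a), !is.na(.data$idx_b))
    identity <- NA_real_
  }
  if (nrow(pairs) < min_pairs) {
    stop("protein superposition needs >= ", min_pairs, " C-alpha pairs, got ",
         nrow(pairs))
  }
  fit <- kabsch(ca_coords_at(a, pairs$idx_a), ca_coords_at(b, pairs$idx_b))
  tf <- fit$transform
  attr(tf, "n_pairs") <- nrow(pairs)
  attr(tf, "identity") <- identity
  attr(tf, "rmsd") <- fit$rmsd
  tf
}

#' Superpose one complex onto another via the shared ligand
#'
#' Maps the two chemically identical ligands atom-to-atom
#' ([ligand_atom_map]) and fits the mapped heavy atoms by Kabsch. The
#' returned transform maps the whole moving complex (protein and ligand)
#' into the reference frame.
#'
#' @param ref,mov [plc] objects whose ligands are chemically identical.
#' @return a [rigid_transform] with attributes `n_pairs` and `rmsd`.
#' @export
superpose_by_ligand <- function(ref, mov) {
  m <- ligand_atom_map(ref$ligand, mov$ligand)
  if (nrow(m) < 3) {
    stop("degenerate input: ligand superposition needs >= 3 mapped heavy atoms")
  }
  fit <- kabsch(atom_xyz(ref$ligand$atoms)[m$idx_a, , drop = FALSE],
                atom_xyz(mov$ligand$atoms)[m$idx_b, , drop = FALSE])
  tf <- fit$transform
  attr(tf, "n_pairs") <- nrow(m)
  attr(tf, "rmsd") <- fit$rmsd
  tf
}
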