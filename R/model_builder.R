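#' Construct a candidate triplet
#'
#' Three solved complexes feeding one prediction: protein P1 with the common
#' ligand La, protein P2 with La, and P1 with the transferred ligand Lb. The
#' two La copies must be chemically identical and the two P1 chains must share
#' the same sequence (they may come from different crystals).
#'
#' @param c_p1_la,c_p2_la,c_p1_lb [plc] records for the three roles.
#' @param check validate the invariants (default TRUE).
#' @return an object of class `candidate_triplet`.
#' @export
candidate_triplet <- function(c_p1_la, c_p2_la, c_p1_lb, check = TRUE) {
  if (check) {
    if (!identical(c_p1_la$protein$sequence, c_p1_lb$protein$sequence)) {
      stop("P1 must be the same protein (identical sequence) in both complexes")
    }
    maps <- ligand_isomorphisms(c_p1_la$ligand, c_p2_la$ligand)
    if (length(maps) == 0) {
      stop("the common ligand La must be chemically identical in P1 and P2 complexes")
    }
  }
  structure(list(c_p1_la = c_p1_la, c_p2_la = c_p2_la, c_p1_lb = c_p1_lb),
            class = "candidate_triplet")
}

#' @export
print.candidate_triplet <- function(x, ...) {
  cat(sprintf("<triplet: P1=%s/%s  P2=%s/%s  La=%s  Lb=%s>\n",
              x$c_p1_la$source, x$c_p1_la$protein$chain_id,
              x$c_p2_la$source, x$c_p2_la$protein$chain_id,
              x$c_p1_la$ligand$het_code, x$c_p1_lb$ligand$het_code))
  invisible(x)
}

#' Build the predicted complex from a candidate triplet
#'
#' Composes the two rigid superpositions: first the protein stage maps the
#' P1:Lb complex onto the P1:La complex (C-alpha Kabsch over the aligned P1
#' residues), then the ligand stage maps the P1:La complex onto the P2:La
#' complex via the common ligand's mapped heavy atoms — re-centering the
#' construction on La. Ligand Lb is carried through both transforms into
#' P2's original frame; P2 itself never moves. The order matters: the protein
#' stage must precede the ligand stage (the reverse composition lands Lb in
#' the wrong frame whenever the two transforms differ).
#'
#' @param t a [candidate_triplet].
#' @param correspondence optional residue correspondence (see
#'   [read_correspondence]) for the P1/P1 protein stage when the two P1
#'   copies cannot be sequence-aligned.
#' @param min_ca_pairs minimum C-alpha coverage of the protein stage; below
#'   this the candidate is rejected (default 30).
#' @return an object of class `predicted_complex`: fields `protein` (P2,
#'   original coordinates), `ligand` (Lb, transformed), `transforms`
#'   (protein stage, ligand stage) and `triplet` provenance.
#' @export
build_prediction <- function(t, correspondence = NULL, min_ca_pairs = 30) {
  stopifnot(inherits(t, "candidate_triplet"))
  t_protein <- tryCatch(
    superpose_by_protein(t$c_p1_la, t$c_p1_lb, correspondence = correspondence,
                         min_pairs = min_ca_pairs),
    error = function(e) stop("protein stage: ", conditionMessage(e), call. = FALSE)
  )
  t_ligand <- tryCatch(
    superpose_by_ligand(t$c_p2_la, t$c_p1_la),
    error = function(e) stop("ligand stage: ", conditionMessage(e), call. = FALSE)
  )
  lb <- t$c_p1_lb$ligand
  lb <- apply_transform(compose_transforms(t_ligand, t_protein), lb)
  structure(
    list(
      protein = t$c_p2_la$protein,
      ligand = lb,
      transforms = list(protein_stage = t_protein, ligand_stage = t_ligand),
      triplet = list(
        p1_la = t$c_p1_la$source, p2_la = t$c_p2_la$source,
        p1_lb = t$c_p1_lb$source,
        la = t$c_p1_la$ligand$het_code, lb = t$c_p1_lb$ligand$het_code
      )
    ),
    class = "predicted_complex"
  )
}

#' @export
print.predicted_complex <- function(x, ...) {
  cat(sprintf("<predicted complex: %s (chain %s) + %s [from %s/%s/%s]>\n",
              x$triplet$p2_la, x$protein$chain_id, x$ligand$het_code,
              x$triplet$p1_la, x$triplet$p2_la, x$triplet$p1_lb))
  invisible(x)
}

#' Ligand RMSD of a prediction against a known structure
#'
#' Superposes the reference complex's protein onto the predicted complex's
#' protein (C-alpha Kabsch over aligned residues, or a supplied
#' correspondence), carries the reference ligand along, and reports the
#' heavy-atom RMSD between predicted and reference ligand under the
#' minimal-RMSD graph isomorphism (symmetry-equivalent atom orders are never
#' penalised).
#'
#' @param pred a [predicted_complex].
#' @param ref a [plc] containing the same ligand chemistry.
#' @param correspondence optional residue correspondence for the
#'   protein-frame alignment.
#' @return RMSD in Angstrom.
#' @export
rmsd_to_reference <- function(pred, ref, correspondence = NULL) {
  maps <- ligand_isomorphisms(pred$ligand, ref$ligand)
  if (length(maps) == 0) {
    stop("reference ligand is not chemically identical to the prediction")
  }
  pseudo <- structure(list(protein = pred$protein, ligand = pred$ligand),
                      class = "plc")
  tf <- superpose_by_protein(pseudo, ref, correspondence = correspondence)
  ref_lig <- apply_transform(tf, ref$ligand)
  xa <- atom_xyz(pred$ligand$atoms)
  xb <- atom_xyz(ref_lig$atoms)
  min(vapply(maps, function(mp) rmsd_xyz(xa, xb[mp, , drop = FALSE]), numeric(1)))
}
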