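#' Build a prediction from three structure files
#'
#' Accession-style entry point: given structure files for the three triplet
#' roles and the HET codes of the common and transferred ligands, extracts
#' the matching chain-ligand complexes (the chain with the most contacts to
#' the named ligand wins), assembles the triplet, builds the predicted
#' complex and, when a reference structure is supplied, reports the ligand
#' RMSD against it.
#'
#' @param p1_la_file,p2_la_file,p1_lb_file structure files for P1:La, P2:La
#'   and P1:Lb.
#' @param het_la,het_lb HET codes of the common ligand La and the
#'   transferred ligand Lb.
#' @param reference_file optional structure holding the known P2:Lb complex.
#' @param het_ref HET code of the ligand in the reference (default
#'   `het_lb`).
#' @param correspondence optional residue correspondence (see
#'   [read_correspondence]) for the P1 protein stage.
#' @param ref_correspondence optional correspondence for aligning the
#'   reference protein onto P2.
#' @param config a [scoring_config].
#' @return list with `prediction` (a [predicted_complex]), `triplet`, and
#'   `rmsd` (Angstrom, `NA` without a reference).
#' @export
predict_from_structures <- function(p1_la_file, p2_la_file, p1_lb_file,
                                    het_la, het_lb,
                                    reference_file = NULL, het_ref = het_lb,
                                    correspondence = NULL,
                                    ref_correspondence = NULL,
                                    config = scoring_config()) {
  pick <- function(file, het) {
    parsed <- parse_structure(file, min_heavy_atoms = config$min_heavy_atoms)
    ligs <- Filter(function(l) toupper(l$het_code) == toupper(het),
                   parsed$ligands)
    if (length(ligs) == 0) {
      stop("no ligand ", het, " found in ", basename(file))
    }
    cxs <- extract_complexes(parsed$chains, ligs,
                             cutoff = config$contact_cutoff)
    if (length(cxs) == 0) {
      stop("ligand ", het, " has no contacting chain in ", basename(file))
    }
    cxs[[which.max(vapply(cxs, function(cx) nrow(cx$contacts), 1L))]]
  }
  c_p1_la <- pick(p1_la_file, het_la)
  c_p2_la <- pick(p2_la_file, het_la)
  c_p1_lb <- pick(p1_lb_file, het_lb)
  trip <- candidate_triplet(c_p1_la, c_p2_la, c_p1_lb, check = FALSE)
  pred <- build_prediction(trip, correspondence = correspondence,
                           min_ca_pairs = config$min_ca_pairs)
  rmsd <- NA_real_
  if (!is.null(reference_file)) {
    ref <- pick(reference_file, het_ref)
    rmsd <- rmsd_to_reference(pred, ref, correspondence = ref_correspondence)
  }
  list(prediction = pred, triplet = trip, rmsd = rmsd)
}

find_entry_file <- function(dir, accession) {
  for (ext in c(".pdb", ".ent", ".cif")) {
    for (acc in c(accession, tolower(accession), toupper(accession))) {
      f <- file.path(dir, paste0(acc, ext))
      if (file.exists(f)) return(f)
    }
  }
  stop("structure file for ", accession, " not found in ", dir,
       " (expected e.g. ", file.path(dir, paste0(accession, ".pdb")), ")")
}

#' Worked example: trimethoprim transferred into P. carinii DHFR
#'
#' Reconstructs the complex of Pneumocystis carinii dihydrofolate reductase
#' with trimethoprim from three solved complexes: M. tuberculosis DHFR with
#' methotrexate (PDB 3CD2, the P1:La role), P. carinii DHFR with
#' methotrexate (1DF7, P2:La) and M. tuberculosis DHFR with trimethoprim
#' (1DG5, P1:Lb). The ligand RMSD is measured against the experimentally
#' solved P. carinii DHFR:trimethoprim complex (1DYR). Requires the four
#' entries as files `1DG5/1DF7/3CD2/1DYR` (.pdb or .cif) in `dir`.
#'
#' @param dir directory containing the four structure files.
#' @param config a [scoring_config].
#' @return as [predict_from_structures] (the `rmsd` field is the headline
#'   number).
#' @export
dhfr_trimethoprim_example <- function(dir, config = scoring_config()) {
  predict_from_structures(
    p1_la_file = find_entry_file(dir, "3CD2"),
    p2_la_file = find_entry_file(dir, "1DF7"),
    p1_lb_file = find_entry_file(dir, "1DG5"),
    het_la = "MTX", het_lb = "TOP",
    reference_file = find_entry_file(dir, "1DYR"),
    config = config
  )
}

#' Worked example: radicicol transferred into GRP94
#'
#' Reconstructs the complex of the endoplasmic reticulum Hsp90 paralog GRP94
#' with radicicol from: pyruvate dehydrogenase kinase 3 (PDK3) with ATP
#' (PDB 1Y8O, P1:La), GRP94 with ATP (1TC6, P2:La) and PDK3 with radicicol
#' (2Q8I, P1:Lb); RMSD against the solved GRP94:radicicol complex (1QY8).
#' The two proteins share no detectable sequence similarity, so the
#' transfer rides entirely on the common ATP. Requires the four entries as
#' files in `dir`; a residue correspondence file can stand in for the
#' sequence alignment of the two PDK3 copies if needed.
#'
#' @param dir directory containing the four structure files.
#' @param correspondence optional [read_correspondence] table for the P1
#'   stage.
#' @param config a [scoring_config].
#' @return as [predict_from_structures].
#' @export
grp94_radicicol_example <- function(dir, correspondence = NULL,
                                    config = scoring_config()) {
  predict_from_structures(
    p1_la_file = find_entry_file(dir, "1Y8O"),
    p2_la_file = find_entry_file(dir, "1TC6"),
    p1_lb_file = find_entry_file(dir, "2Q8I"),
    het_la = "ATP", het_lb = "RDC",
    reference_file = find_entry_file(dir, "1QY8"),
    correspondence = correspondence,
    config = config
  )
}
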