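# combined atom table for output: polymer chains as ATOM, ligands as HETATM
combined_atom_table <- function(chains, ligands) {
  rows <- list()
  for (ch in chains) {
    a <- ch$atoms
    a$type <- "ATOM"
    rows[[length(rows) + 1L]] <- a
  }
  for (lg in ligands) {
    a <- lg$atoms
    a$type <- "HETATM"
    rows[[length(rows) + 1L]] <- a
  }
  at <- bind_rows(rows)
  at$eleno <- seq_len(nrow(at))
  at
}

#' Write chains and ligands to a structure file
#'
#' PDB output goes through `bio3d::write.pdb`; mmCIF output writes a minimal
#' `atom_site` loop (group, id, element, atom/comp/asym ids, coordinates,
#' occupancy, auth numbering, model number) that standard readers accept.
#'
#' @param chains list of [protein_chain].
#' @param ligands list of [ligand].
#' @param path output file; extension picks the dialect when `format` is
#'   `"auto"`.
#' @param format `"auto"`, `"pdb"` or `"mmcif"`.
#' @param remarks optional character vector written as REMARK records (PDB
#'   only).
#' @return `path`, invisibly.
#' @export
write_structure <- function(chains, ligands = list(), path,
                            format = c("auto", "pdb", "mmcif"),
                            remarks = character()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  at <- combined_atom_table(chains, ligands)
  if (format == "pdb") {
    if (length(remarks) > 0) {
      writeLines(sprintf("REMARK   3 %s", remarks), path)
    } else {
      unlink(path)
    }
    bio3d::write.pdb(
      file = path, append = length(remarks) > 0,
      xyz = as.numeric(t(atom_xyz(at))),
      type = at$type, resno = at$resno, resid = at$resid,
      eleno = at$eleno, elety = at$name, chain = at$chain,
      insert = ifelse(at$insert == "", NA, at$insert),
      o = at$occ, b = rep(0, nrow(at)), elesy = at$element
    )
  } else {
    write_cif_atoms(at, path)
  }
  invisible(path)
}

write_cif_atoms <- function(at, path) {
  hdr <- c(
    "data_ligtrans",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  body <- sprintf(
    "%-6s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
    at$type, at$eleno, at$element, at$name, at$resid, at$chain, at$resno,
    ifelse(at$insert == "", "?", at$insert),
    at$x, at$y, at$z, at$occ, at$resno, at$resid, at$chain, at$name
  )
  writeLines(c(hdr, body, "#"), path)
}

#' Write a predicted complex as a PDB file
#'
#' P2's chain is written as ATOM records with its original coordinates; the
#' transferred ligand as HETATM records under chain `Z`; the triplet
#' provenance goes into REMARK records.
#'
#' @param pred a [predicted_complex].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(pred, path) {
  lig <- pred$ligand
  lig$atoms$chain <- "Z"
  remarks <- c(
    sprintf("LIGTRANS PREDICTION %s + %s", pred$triplet$p2_la, pred$triplet$lb),
    sprintf("TRIPLET P1:La=%s P2:La=%s P1:Lb=%s La=%s Lb=%s",
            pred$triplet$p1_la, pred$triplet$p2_la, pred$triplet$p1_lb,
            pred$triplet$la, pred$triplet$lb)
  )
  write_structure(list(pred$protein), list(lig), path, format = "pdb",
                  remarks = remarks)
}
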