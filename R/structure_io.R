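#' Parse a structure file into chains and ligand instances
#'
#' Reads a PDB or mmCIF file (via bio3d), resolves alternate locations by
#' keeping the highest-occupancy copy (ties go to the first encountered in the
#' file), keeps the first model of multi-model entries, and separates polymer
#' chains from non-polymer HET groups. Waters and other listed solvents are
#' flagged `is_solvent`; non-solvent HET groups need at least `min_heavy_atoms`
#' heavy atoms to qualify as candidate ligands (monoatomic ions are dropped by
#' default).
#'
#' @param path path to the structure file.
#' @param dialect `"pdb"` or `"mmcif"`; `"auto"` (default) decides from the
#'   file extension.
#' @param min_heavy_atoms minimum heavy-atom count for a non-solvent HET
#'   group to be kept as a ligand (default 4).
#' @param solvent_codes character vector of solvent HET codes; defaults to
#'   the list shipped with the package (water plus common buffers and
#'   cryoprotectants).
#' @return list with elements `chains` (list of [protein_chain]) and
#'   `ligands` (list of [ligand]).
#' @export
parse_structure <- function(path, dialect = c("auto", "pdb", "mmcif"),
                            min_heavy_atoms = 4,
                            solvent_codes = default_solvent_codes()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  src <- sub("\\.(pdb|ent|cif)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  parsed <- tryCatch(
    if (dialect == "pdb") {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(  # read.cif warns about its beta status on every call
        bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) stop("parse error for ", path, ": ", conditionMessage(e))
  )
  at <- as_tibble(parsed$atom)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$file_order <- seq_len(nrow(at))
  at <- resolve_altloc(at)

  atoms <- tibble(
    eleno = as.integer(at$eleno),
    name = trimws(at$elety),
    element = guess_element(at),
    x = at$x, y = at$y, z = at$z,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = as.integer(at$resno),
    insert = at$insert,
    resid = trimws(at$resid),
    hetero = at$type == "HETATM",
    occ = at$o
  )

  poly <- atoms[!atoms$hetero, , drop = FALSE]
  if (nrow(poly) == 0) stop("empty structure: no polymer chain in ", path)
  chains <- lapply(split(poly, poly$chain), function(ca) {
    ca <- ca[order(match(paste(ca$resno, ca$insert), unique(paste(ca$resno, ca$insert)))), ]
    res <- ca[!duplicated(paste(ca$resno, ca$insert)), ]
    seq1 <- paste(bio3d::aa321(res$resid), collapse = "")
    protein_chain(ca$chain[1], ca, seq1, source = src)
  })

  het <- atoms[atoms$hetero, , drop = FALSE]
  ligands <- list()
  if (nrow(het) > 0) {
    key <- paste(het$chain, het$resno, het$insert, het$resid, sep = "|")
    for (grp in split(het, factor(key, levels = unique(key)))) {
      code <- grp$resid[1]
      solv <- toupper(code) %in% toupper(solvent_codes)
      n_heavy <- sum(!is_hydrogen(grp$element))
      if (!solv && n_heavy < min_heavy_atoms) next
      ligands[[length(ligands) + 1L]] <- ligand(
        het_code = code, atoms = grp, is_solvent = solv, source = src,
        instance_id = paste0(grp$chain[1], grp$resno[1], grp$insert[1])
      )
    }
  }
  list(chains = unname(chains), ligands = ligands)
}

# keep the highest-occupancy altloc per atom site; ties go to file order
resolve_altloc <- function(at) {
  site <- paste(at$chain, at$resno, at$insert, at$resid, trimws(at$elety), sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(site, levels = unique(site))),
                        function(idx) {
    if (length(idx) == 1) return(idx)
    o <- at$o[idx]
    idx[which.max(o)]  # which.max: first index on ties = first in file
  }), use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

guess_element <- function(at) {
  el <- if ("elesy" %in% names(at)) trimws(at$elesy) else rep(NA_character_, nrow(at))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # PDB convention: element is the leading alphabetic part of the atom name
    nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", trimws(at$elety[miss])))
    two <- toupper(substr(nm, 1, 2))
    one <- toupper(substr(nm, 1, 1))
    el[miss] <- ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN", "NA"),
                       two, one)
  }
  toupper(el)
}

#' Default solvent HET codes
#'
#' Water plus common buffer and cryoprotectant components, read from the
#' plain-text list shipped in `extdata/solvent_het_codes.txt`.
#'
#' @return character vector of HET codes.
#' @export
default_solvent_codes <- function() {
  path <- system.file("extdata", "solvent_het_codes.txt", package = "ligtrans")
  if (path == "") return(c("HOH", "DOD", "WAT"))
  codes <- readLines(path, warn = FALSE)
  codes <- trimws(sub("#.*$", "", codes))
  codes[nzchar(codes)]
}

#' Extract contacting chain-ligand pairs as complex records
#'
#' Emits one complex per chain-ligand pair with at least `min_contacts`
#' heavy-atom pairs closer than `cutoff` Angstrom. A ligand contacting two
#' chains yields two records: each chain-small-molecule pair is a separate
#' entry. Hydrogens never enter the distance computation.
#'
#' @param chains list of [protein_chain] (one common coordinate frame).
#' @param ligands list of [ligand] in the same frame.
#' @param cutoff contact distance cutoff in Angstrom (default 5.0).
#' @param min_contacts minimum number of qualifying pairs (default 2).
#' @return list of [plc] records (possibly empty).
#' @export
extract_complexes <- function(chains, ligands, cutoff = 5.0, min_contacts = 2) {
  out <- list()
  for (ch in chains) {
    for (lg in ligands) {
      ct <- contact_pairs(ch, lg, cutoff = cutoff)
      if (nrow(ct) >= min_contacts) {
        out[[length(out) + 1L]] <- plc(ch, lg, contacts = ct, source = ch$source)
      }
    }
  }
  out
}

#' Annotate complexes with solvent and promiscuity flags
#'
#' A HET code is promiscuous when it occurs in more than
#' `promiscuity_threshold` distinct source structures (default 20, i.e. a code
#' seen in 21 sources is promiscuous, one seen in 20 is not). Solvent flags
#' come from a configurable HET-code list and apply regardless of counts.
#'
#' @param complexes list of [plc].
#' @param solvent_codes character vector of solvent HET codes.
#' @param promiscuity_threshold source-count threshold (default 20).
#' @return the complex list with ligand flags set.
#' @export
flag_ligands <- function(complexes, solvent_codes = default_solvent_codes(),
                         promiscuity_threshold = 20) {
  if (length(complexes) == 0) return(complexes)
  inv <- complex_inventory(complexes)
  counts <- inv %>%
    distinct(.data$source, .data$het_code) %>%
    dplyr::count(.data$het_code, name = "n_sources")
  lapply(complexes, function(cx) {
    n_src <- counts$n_sources[match(cx$ligand$het_code, counts$het_code)]
    cx$ligand$is_promiscuous <- !is.na(n_src) && n_src > promiscuity_threshold
    cx$ligand$is_solvent <- toupper(cx$ligand$het_code) %in% toupper(solvent_codes)
    cx
  })
}

#' Tabulate a complex list
#'
#' @param complexes list of [plc].
#' @return tibble with one row per complex: `source`, `chain`, `het_code`,
#'   `instance`, `n_contacts`, `n_ligand_atoms`.
#' @export
complex_inventory <- function(complexes) {
  purrr::map_dfr(complexes, function(cx) {
    tibble(
      source = cx$source,
      chain = cx$protein$chain_id,
      het_code = cx$ligand$het_code,
      instance = cx$ligand$instance_id,
      n_contacts = nrow(cx$contacts),
      n_ligand_atoms = nrow(cx$ligand$atoms)
    )
  })
}

#' Write a complex inventory as TSV
#'
#' @param complexes list of [plc].
#' @param path output file.
#' @return the inventory tibble, invisibly.
#' @export
write_inventory <- function(complexes, path) {
  inv <- complex_inventory(complexes)
  utils::write.table(inv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(inv)
}
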