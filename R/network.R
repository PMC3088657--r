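# canonical key of an element-labelled bond graph (BLISS canonical
# permutation with element colours), so graph-identical ligands collide
ligand_graph_key <- function(lig) {
  el <- toupper(lig$atoms$element)
  n <- length(el)
  if (n == 0) return("empty")
  lev <- sort(unique(el))
  g <- igraph::graph_from_data_frame(as.data.frame(lig$bonds), directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  cp <- igraph::canonical_permutation(g, colors = as.integer(factor(el, lev)))
  gp <- igraph::permute(g, cp$labeling)
  am <- igraph::as_adjacency_matrix(gp, sparse = FALSE)
  el_perm <- character(n)
  el_perm[cp$labeling] <- el
  paste(paste(el_perm, collapse = ","),
        paste(which(am[upper.tri(am)] > 0), collapse = "."), sep = ";")
}

#' Build the bipartite protein-chemical structure network
#'
#' Protein nodes are keyed by exact sequence (point mutants stay distinct
#' and are handled by the identity filter at enumeration time); chemical
#' nodes are keyed by the canonical form of the element-labelled bond graph,
#' so two copies of the same compound merge regardless of atom order. Each
#' complex record is one edge; a protein-chemical pair solved in several
#' structures carries several edges.
#'
#' @param complexes non-empty list of [plc] records.
#' @return object of class `interaction_network` with tibbles `proteins`,
#'   `chemicals`, `edges` and the original `complexes` list.
#' @export
build_network <- function(complexes) {
  stopifnot(length(complexes) > 0)
  seqs <- vapply(complexes, function(cx) cx$protein$sequence, "")
  pseq <- unique(seqs)
  pnode <- match(seqs, pseq)
  keys <- vapply(complexes, function(cx) ligand_graph_key(cx$ligand), "")
  ckey <- unique(keys)
  cnode <- match(keys, ckey)
  # node labels are the lexicographic minimum over realising structures,
  # so they do not depend on input order
  proteins <- tibble(
    protein_node = seq_along(pseq), sequence = pseq,
    label = vapply(seq_along(pseq), function(i) {
      min(vapply(complexes[pnode == i], function(cx)
        paste0(cx$source, "/", cx$protein$chain_id), ""))
    }, "")
  )
  chemicals <- tibble(
    chemical_node = seq_along(ckey), graph_key = ckey,
    het_code = vapply(seq_along(ckey), function(i) {
      min(vapply(complexes[cnode == i], function(cx) cx$ligand$het_code, ""))
    }, ""),
    n_heavy = vapply(seq_along(ckey), function(i) {
      nrow(complexes[[which(cnode == i)[1]]]$ligand$atoms)
    }, 1L),
    is_solvent = vapply(seq_along(ckey), function(i) {
      any(vapply(complexes[cnode == i], function(cx)
        isTRUE(cx$ligand$is_solvent), TRUE))
    }, TRUE)
  )
  edges <- tibble(protein_node = pnode, chemical_node = cnode,
                  complex_idx = seq_along(complexes))
  structure(list(proteins = proteins, chemicals = chemicals, edges = edges,
                 complexes = complexes),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network: %d protein nodes, %d chemical nodes, %d edges>\n",
              nrow(x$proteins), nrow(x$chemicals), nrow(x$edges)))
  invisible(x)
}

# cached pairwise identity between protein nodes; non-alignable pairs get NA
protein_identity <- function(net, i, j, cache = NULL) {
  ch_i <- net$complexes[[net$edges$complex_idx[match(i, net$edges$protein_node)]]]$protein
  ch_j <- net$complexes[[net$edges$complex_idx[match(j, net$edges$protein_node)]]]$protein
  if (identical(ch_i$sequence, ch_j$sequence)) return(1)
  tryCatch(align_protein_pair(ch_i, ch_j)$identity, error = function(e) NA_real_)
}

#' Enumerate prediction candidates from the network
#'
#' Finds every triplet (P1, P2, La, Lb) with edges P1-La, P2-La and P1-Lb
#' and applies the candidate filters: the two proteins must share less than
#' `max_identity` sequence identity (default 80%), the two ligands must not
#' be chemically indistinguishable — implemented as graph identity, since
#' graph-identical ligands merge into one chemical node and always score
#' Tanimoto 1 — and their heavy-atom counts must not differ more than
#' `atom_ratio_max`-fold (default 2). The fingerprint Tanimoto is reported
#' per candidate but is not itself a filter: substructure fingerprints can
#' saturate at 1 for distinct molecules (homologous chains of different
#' length), which must not suppress a legitimate transfer. When several
#' structures realise an edge, every structure combination is emitted. The
#' output is canonically sorted, so it does not depend on input order.
#'
#' @param net an [build_network] result.
#' @param max_identity identity exclusion threshold (candidates with
#'   identity at or above it are dropped; default 0.80).
#' @param atom_ratio_max maximum heavy-atom count ratio between La and Lb.
#' @return list of [candidate_triplet] objects; each carries attributes
#'   `identity`, `tanimoto` and `atom_ratio`. The summary table is attached
#'   as attribute `table` (also available via [triplet_table]).
#' @export
enumerate_triplets <- function(net, max_identity = 0.80, atom_ratio_max = 2.0) {
  ed <- net$edges
  out <- list()
  rows <- list()
  id_cache <- new.env(parent = emptyenv())
  pair_identity <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(id_cache[[key]])) return(id_cache[[key]])
    v <- protein_identity(net, i, j)
    id_cache[[key]] <- v
    v
  }
  for (la_node in net$chemicals$chemical_node) {
    la_edges <- ed[ed$chemical_node == la_node, , drop = FALSE]
    p_nodes <- unique(la_edges$protein_node)
    if (length(p_nodes) < 2) next
    for (p1 in p_nodes) {
      lb_edges <- ed[ed$protein_node == p1 & ed$chemical_node != la_node, , drop = FALSE]
      if (nrow(lb_edges) == 0) next
      for (p2 in setdiff(p_nodes, p1)) {
        idy <- pair_identity(p1, p2)
        if (!is.na(idy) && idy >= max_identity) next
        for (k in seq_len(nrow(lb_edges))) {
          lb_node <- lb_edges$chemical_node[k]
          na_ <- net$chemicals$n_heavy[la_node]
          nb_ <- net$chemicals$n_heavy[lb_node]
          ratio <- max(na_, nb_) / min(na_, nb_)
          if (ratio > atom_ratio_max) next
          cx_lb <- net$complexes[[lb_edges$complex_idx[k]]]
          cx_la_p1_all <- la_edges$complex_idx[la_edges$protein_node == p1]
          cx_la_p2_all <- la_edges$complex_idx[la_edges$protein_node == p2]
          for (ia in cx_la_p1_all) for (ib in cx_la_p2_all) {
            cx_p1_la <- net$complexes[[ia]]
            cx_p2_la <- net$complexes[[ib]]
            tani <- tanimoto(cx_p1_la$ligand, cx_lb$ligand)
            tr <- candidate_triplet(cx_p1_la, cx_p2_la, cx_lb, check = FALSE)
            attr(tr, "identity") <- idy
            attr(tr, "tanimoto") <- tani
            attr(tr, "atom_ratio") <- ratio
            out[[length(out) + 1L]] <- tr
            rows[[length(rows) + 1L]] <- tibble(
              p1 = net$proteins$label[p1], p2 = net$proteins$label[p2],
              la = net$chemicals$het_code[la_node],
              lb = net$chemicals$het_code[lb_node],
              p1_la_idx = ia, p2_la_idx = ib,
              p1_lb_idx = lb_edges$complex_idx[k],
              identity = idy, tanimoto = tani, atom_ratio = ratio
            )
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    attr(out, "table") <- tibble(
      p1 = character(), p2 = character(), la = character(), lb = character(),
      p1_la_idx = integer(), p2_la_idx = integer(), p1_lb_idx = integer(),
      identity = double(), tanimoto = double(), atom_ratio = double())
    return(out)
  }
  tab <- bind_rows(rows)
  ord <- order(tab$p1, tab$p2, tab$la, tab$lb,
               tab$p1_la_idx, tab$p2_la_idx, tab$p1_lb_idx)
  out <- out[ord]
  attr(out, "table") <- tab[ord, ]
  out
}

#' Summary table of enumerated triplets
#'
#' @param triplets result of [enumerate_triplets].
#' @return tibble with one row per candidate.
#' @export
triplet_table <- function(triplets) {
  attr(triplets, "table")
}

#' Triviality labels for a prediction
#'
#' Classifies how surprising a candidate is: `easy_protein` when the two
#' proteins share at least 30% sequence identity (the prediction could come
#' from conventional homology modelling), `easy_chemical` when the two
#' ligands are at least 90% similar by Tanimoto, `solvent_involved` when
#' either ligand is a flagged solvent, and `nontrivial` when none of these
#' apply.
#'
#' @param t a [candidate_triplet] (attributes from [enumerate_triplets] are
#'   used when present).
#' @param scored optional `score_result` (not used for labelling; accepted
#'   so scored candidates can be piped through).
#' @return character vector of labels.
#' @export
classify_prediction <- function(t, scored = NULL) {
  idy <- attr(t, "identity")
  if (is.null(idy) || is.na(idy)) {
    idy <- tryCatch(
      align_protein_pair(t$c_p1_la$protein, t$c_p2_la$protein)$identity,
      error = function(e) NA_real_)
  }
  tani <- attr(t, "tanimoto")
  if (is.null(tani)) tani <- tanimoto(t$c_p1_la$ligand, t$c_p1_lb$ligand)
  labels <- character()
  if (!is.na(idy) && idy >= 0.30) labels <- c(labels, "easy_protein")
  if (tani >= 0.90) labels <- c(labels, "easy_chemical")
  if (isTRUE(t$c_p1_la$ligand$is_solvent) || isTRUE(t$c_p1_lb$ligand$is_solvent) ||
      isTRUE(t$c_p2_la$ligand$is_solvent)) {
    labels <- c(labels, "solvent_involved")
  }
  if (length(labels) == 0) labels <- "nontrivial"
  labels
}
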