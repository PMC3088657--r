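# deterministic 31-bit string-free hashing kept inside double precision
.hash_mix <- function(h, x) ((h * 31) %% 2147483647 + x + 1) %% 2147483647

#' Circular fingerprint of a ligand bond graph
#'
#' A Morgan-style hashed fingerprint over the element-labelled heavy-atom
#' bond graph: each atom starts from an element/degree invariant, which is
#' iteratively combined with the sorted invariants of its neighbours up to
#' the given radius; every invariant generated at any radius sets one of
#' `n_bits` bits. Identical labelled graphs always produce identical
#' fingerprints.
#'
#' @param lig a [ligand] with a bond graph.
#' @param radius neighbourhood radius (default 2).
#' @param n_bits fingerprint length (default 2048).
#' @return sorted integer vector of set bit positions (0-based).
#' @export
fingerprint_bits <- function(lig, radius = 2, n_bits = 2048) {
  if (is.null(lig$bonds)) stop("ligand has no bond graph")
  el <- toupper(lig$atoms$element)
  n <- length(el)
  if (n == 0) return(integer())
  nb <- vector("list", n)
  if (nrow(lig$bonds) > 0) {
    for (k in seq_len(nrow(lig$bonds))) {
      i <- lig$bonds$from[k]; j <- lig$bonds$to[k]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  el_code <- vapply(el, function(e) sum(utf8ToInt(e) * c(131, 1)[seq_along(utf8ToInt(e))]),
                    numeric(1))
  inv <- vapply(seq_len(n), function(i) .hash_mix(.hash_mix(7, el_code[i]),
                                                  length(nb[[i]])), numeric(1))
  all_inv <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(i) {
      h <- .hash_mix(17 + r, inv[i])
      for (v in sort(inv[nb[[i]]])) h <- .hash_mix(h, v)
      h
    }, numeric(1))
    all_inv <- c(all_inv, inv)
  }
  sort(unique(as.integer(all_inv %% n_bits)))
}

#' Tanimoto similarity of two ligands
#'
#' Tanimoto coefficient `|A n B| / |A u B|` over the circular fingerprint
#' bit sets of the two ligands. Graph-identical ligands score exactly 1.
#'
#' @param a,b [ligand] objects with bond graphs.
#' @param radius,n_bits fingerprint parameters (see [fingerprint_bits]).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b, radius = 2, n_bits = 2048) {
  fa <- fingerprint_bits(a, radius, n_bits)
  fb <- fingerprint_bits(b, radius, n_bits)
  if (length(fa) == 0 && length(fb) == 0) return(1)
  length(intersect(fa, fb)) / length(union(fa, fb))
}
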