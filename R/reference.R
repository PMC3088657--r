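#' Empirical score reference
#'
#' Houses the sorted per-descriptor value arrays of the decoy negative set
#' and the combined scores (sigma) of the decoys themselves, against which
#' query descriptors are normalised and p-values computed.
#'
#' @param values named list of numeric vectors, one per descriptor
#'   (`a_clash_volume` ... `g_exposed_polar`), all the same length.
#' @param sigma numeric vector of decoy combined scores.
#' @param metadata list (seed, generation parameters, configuration).
#' @return object of class `score_reference`.
#' @export
score_reference <- function(values, sigma, metadata = list()) {
  stopifnot(setequal(names(values), descriptor_names()))
  n <- length(values[[1]])
  if (!all(vapply(values, length, 1L) == n)) stop("descriptor arrays differ in length")
  if (length(sigma) != n) stop("sigma must have one entry per decoy")
  values <- lapply(values[descriptor_names()], sort)
  structure(list(values = values, sigma = sort(sigma), n = n,
                 metadata = metadata),
            class = "score_reference")
}

#' @export
print.score_reference <- function(x, ...) {
  cat(sprintf("<score_reference: %d decoys, sigma in [%.2f, %.2f]>\n",
              x$n, min(x$sigma), max(x$sigma)))
  invisible(x)
}

# resolve "a".."g" or full names to the canonical descriptor name
resolve_descriptor <- function(descriptor) {
  nm <- descriptor_names()
  if (descriptor %in% nm) return(descriptor)
  hit <- nm[substr(nm, 1, 1) == descriptor]
  if (length(hit) != 1) stop("unknown descriptor: ", descriptor)
  hit
}

#' Normalise a raw descriptor value against the reference
#'
#' For the beneficial descriptors (b, c, d) the normalised value is the
#' fraction of reference values strictly below the query; for the
#' detrimental ones (a, e, f, g) it is the fraction strictly above.
#' Strict inequalities mean ties with reference mass points contribute
#' nothing, which is the conservative reading.
#'
#' @param xi raw descriptor value.
#' @param descriptor descriptor label (`"a"`..`"g"` or the full column name).
#' @param ref a [score_reference].
#' @return normalised value in `[0, 1]`.
#' @export
normalize_descriptor <- function(xi, descriptor, ref) {
  nm <- resolve_descriptor(descriptor)
  v <- ref$values[[nm]]  # sorted ascending
  if (descriptor_detrimental()[[nm]]) {
    (ref$n - count_leq(v, xi)) / ref$n     # strictly greater
  } else {
    count_lt(v, xi) / ref$n                # strictly less
  }
}

# counts on a sorted vector via binary search
count_lt <- function(sorted, x) findInterval(x, sorted, left.open = TRUE)
count_leq <- function(sorted, x) findInterval(x, sorted)

#' Combined score of a descriptor vector
#'
#' Normalises each of the seven descriptors against the reference and sums
#' them into the combined score S in `[0, 7]`; larger is better. Improving
#' any single descriptor in its beneficial direction never decreases S.
#'
#' @param dv one-row tibble from [descriptor_vector] (or a named list with
#'   the seven descriptor fields).
#' @param ref a [score_reference].
#' @return object of class `score_result` with fields `s` (named vector of
#'   the seven normalised components), `S`, `p` (`NA` until [p_value] is
#'   applied) and `raw`.
#' @export
combined_score <- function(dv, ref) {
  s <- vapply(descriptor_names(),
              function(nm) normalize_descriptor(dv[[nm]][[1]], nm, ref),
              numeric(1))
  structure(list(s = s, S = sum(s), p = NA_real_,
                 raw = dv[descriptor_names()]),
            class = "score_result")
}

#' Empirical p-value of a combined score
#'
#' The fraction of decoy combined scores sigma strictly greater than S:
#' `p = #(sigma > S) / #sigma`. No continuity correction is applied, so a
#' score above every decoy gives p = 0 (reported as "< 1/n" in printed
#' output but stored as 0).
#'
#' @param S combined score (or a `score_result`).
#' @param ref a [score_reference] with non-empty sigma.
#' @return p in `[0, 1]` (or the `score_result` with `p` filled in).
#' @export
p_value <- function(S, ref) {
  if (length(ref$sigma) == 0) stop("empty decoy score set")
  if (inherits(S, "score_result")) {
    S$p <- p_value(S$S, ref)
    return(S)
  }
  (length(ref$sigma) - count_leq(ref$sigma, S)) / length(ref$sigma)
}

#' Score a (putative) complex against the decoy reference
#'
#' @param protein a [protein_chain] (P2, or any chain in frame with the
#'   ligand); a [predicted_complex] may be given instead, in which case
#'   `ligand` is taken from it.
#' @param ligand a [ligand] in the same frame.
#' @param ref a [score_reference].
#' @param config a [scoring_config].
#' @return a `score_result` with `p` filled in.
#' @export
score_complex <- function(protein, ligand = NULL, ref, config = scoring_config()) {
  if (inherits(protein, "predicted_complex")) {
    ligand <- protein$ligand
    protein <- protein$protein
  }
  dv <- descriptor_vector(protein, ligand, config)
  p_value(combined_score(dv, ref), ref)
}

#' @export
print.score_result <- function(x, ...) {
  p_lab <- if (!is.na(x$p) && x$p == 0) "< 1/n" else format(x$p, digits = 3)
  cat(sprintf("<score: S = %.3f / 7, p %s>\n", x$S,
              if (!is.na(x$p) && x$p == 0) p_lab else paste("=", p_lab)))
  invisible(x)
}

# leave-one-out normalised scores for the decoys themselves: each decoy's
# descriptors are normalised against the other n-1 decoys via ranks
loo_scores <- function(desc) {
  desc <- as.matrix(desc[, descriptor_names(), drop = FALSE])
  n <- nrow(desc)
  s_total <- numeric(n)
  det <- descriptor_detrimental()
  for (nm in descriptor_names()) {
    v <- desc[, nm]
    if (det[[nm]]) {
      cnt <- n - rank(v, ties.method = "max")   # strictly greater, self excluded
    } else {
      cnt <- rank(v, ties.method = "min") - 1   # strictly less, self excluded
    }
    s_total <- s_total + cnt / (n - 1)
  }
  s_total
}

#' Serialise / load a score reference as JSON
#'
#' @param ref a [score_reference].
#' @param path file path.
#' @return `read_reference` returns the [score_reference]; `write_reference`
#'   returns `path` invisibly.
#' @export
write_reference <- function(ref, path) {
  jsonlite::write_json(
    list(values = ref$values, sigma = ref$sigma, n = ref$n,
         metadata = ref$metadata),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  score_reference(as.list(x$values), x$sigma, as.list(x$metadata))
}
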