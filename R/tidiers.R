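#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a score result
#'
#' @param x a `score_result`.
#' @param ... unused.
#' @return tibble with one row per descriptor: `descriptor`, `raw`,
#'   `normalized`, `detrimental`.
#' @method tidy score_result
#' @export
tidy.score_result <- function(x, ...) {
  nm <- descriptor_names()
  tibble(
    descriptor = nm,
    raw = as.numeric(unlist(x$raw[nm])),
    normalized = as.numeric(x$s[nm]),
    detrimental = unname(descriptor_detrimental()[nm])
  )
}

#' @rdname tidy.score_result
#' @method glance score_result
#' @export
glance.score_result <- function(x, ...) {
  tibble(S = x$S, p = x$p)
}

#' Tidy a score reference
#'
#' @param x a [score_reference].
#' @param ... unused.
#' @return long tibble with `descriptor`, `value` (one row per decoy per
#'   descriptor; the combined decoy score appears as descriptor `"sigma"`).
#' @method tidy score_reference
#' @export
tidy.score_reference <- function(x, ...) {
  vals <- c(x$values, list(sigma = x$sigma))
  purrr::map_dfr(names(vals), function(nm) {
    tibble(descriptor = nm, value = vals[[nm]])
  })
}

#' @rdname tidy.score_reference
#' @method glance score_reference
#' @export
glance.score_reference <- function(x, ...) {
  tibble(n_decoys = x$n, sigma_min = min(x$sigma), sigma_max = max(x$sigma),
         sigma_median = stats::median(x$sigma))
}

#' Tidy a pipeline run
#'
#' @param x a `ligtrans_run`.
#' @param ... unused.
#' @return `tidy()` returns the prediction report; `glance()` the stage
#'   counts as one wide row.
#' @method tidy ligtrans_run
#' @export
tidy.ligtrans_run <- function(x, ...) x$report

#' @rdname tidy.ligtrans_run
#' @method glance ligtrans_run
#' @export
glance.ligtrans_run <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "stage", values_from = "count")
}
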