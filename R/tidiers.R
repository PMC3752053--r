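#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an adjusted prevalence fit
#'
#' @param x An `adjusted_prevalence` object.
#' @param ... Unused.
#' @return Tibble with one row per exposure level: `level`, `n`,
#'   `prevalence` and, when bootstrapped, `se`, `conf_low`, `conf_high`.
#' @export
tidy.adjusted_prevalence <- function(x, ...) x$estimates

#' @rdname tidy.adjusted_prevalence
#' @return For `glance()`: a one-row tibble with `n`, `n_boot` and
#'   `converged`.
#' @export
glance.adjusted_prevalence <- function(x, ...) {
  tibble::tibble(n = x$n, n_boot = x$n_boot,
                 converged = x$model$converged)
}

#' Tidy a Moran's I permutation test
#'
#' @param x A `moran_test` object.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `expected`, `p_value`.
#' @export
tidy.moran_test <- function(x, ...) {
  tibble::tibble(estimate = x$I, expected = x$expected,
                 p_value = x$p_value)
}

#' @rdname tidy.moran_test
#' @export
glance.moran_test <- function(x, ...) {
  tibble::tibble(n_regions = x$n, n_perm = x$n_perm)
}

#' Glance at a cohort reduction
#'
#' @param x A `cohort_reduction` object (from [reduce_cohort()]).
#' @param ... Unused.
#' @return One-row tibble with child counts: total, included, excluded,
#'   and the number of valid days contributed.
#' @export
glance.cohort_reduction <- function(x, ...) {
  tibble::tibble(
    n_children = nrow(x$inclusion),
    n_included = sum(x$inclusion$included),
    n_excluded = sum(!x$inclusion$included),
    n_valid_days = sum(x$days$is_valid_day)
  )
}
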