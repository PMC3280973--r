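#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a `ragdel_test`
#'
#' @param x A `ragdel_test` from [chi_square_2x2()], [fisher_exact_2x2()],
#'   [contingency_test()] or [compare_groups()].
#' @param ... Unused.
#' @return A one-row tibble: `test_used`, `statistic`, `df`, `p_value`
#'   (plus `significant` when set).
#' @export
tidy.ragdel_test <- function(x, ...) {
  out <- tibble::tibble(
    test_used = x$test_used,
    statistic = as.numeric(x$statistic),
    df = as.numeric(x$df),
    p_value = x$p_value
  )
  if (!is.na(x$significant)) out$significant <- x$significant
  out
}

#' @rdname tidy.ragdel_test
#' @export
glance.ragdel_test <- function(x, ...) tidy(x, ...)

#' Tidy a simulated cohort
#'
#' Returns the clone-level table (one row per deletion clone).
#'
#' @param x A `ragdel_cohort`.
#' @param ... Unused.
#' @export
tidy.ragdel_cohort <- function(x, ...) x$clones

#' One-row summary of a simulated cohort
#'
#' @param x A `ragdel_cohort`.
#' @param ... Unused.
#' @return A one-row tibble: sample and clone counts and the number of
#'   deletion-bearing samples.
#' @export
glance.ragdel_cohort <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_deletion_samples = sum(x$samples$n_clones > 0),
    n_clones = nrow(x$clones),
    locus_length = x$locus$locus_length,
    scale_factor = x$config$scale_factor,
    seed = x$config$seed
  )
}
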