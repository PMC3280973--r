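new_ragdel_test <- function(statistic, df, p_value, test_used,
                            estimate = NULL, significant = NA,
                            table = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 test_used = test_used, estimate = estimate,
                 significant = significant, table = table),
            class = "ragdel_test")
}

#' @export
print.ragdel_test <- function(x, ...) {
  cat(sprintf("<ragdel_test> %s: statistic = %s, df = %s, P = %.4g\n",
              x$test_used,
              if (is.null(x$statistic) || is.na(x$statistic)) "-" else
                format(x$statistic, digits = 4),
              if (is.null(x$df) || is.na(x$df)) "-" else x$df,
              x$p_value))
  invisible(x)
}

.as_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a) || is.table(a)) {
    m <- unclass(a)
    stopifnot(all(dim(m) == c(2, 2)))
    return(matrix(as.numeric(m), 2))
  }
  if (is.data.frame(a)) {
    stopifnot(all(c("a", "b", "c", "d") %in% names(a)), nrow(a) == 1)
    return(matrix(c(a$a, a$c, a$b, a$d), 2))
  }
  stopifnot(!is.null(b), !is.null(c), !is.null(d))
  matrix(c(a, c, b, d), 2)
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Pearson's chi-square without continuity correction (df = 1), matching
#' the closed form `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. The two-sided
#' P-value comes from the chi-square distribution. No Yates correction is
#' applied: the uncorrected statistic is what reproduces the reported
#' cohort P-values from their printed counts.
#'
#' @param a,b,c,d Cell counts (rows = group yes/no, columns = deletion
#'   positive/negative). Alternatively `a` may be a 2x2 matrix/table, or a
#'   one-row data frame with columns `a`, `b`, `c`, `d`.
#' @return A `ragdel_test` with `test_used = "chi_square"`.
#' @export
#' @examples
#' chi_square_2x2(0, 109, 65, 657)  # P ~ 0.001
chi_square_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- .as_2x2(a, b, c, d)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("a margin of the 2x2 table is zero; use fisher_exact_2x2()",
         call. = FALSE)
  }
  n <- sum(m)
  stat <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    prod(rowSums(m), colSums(m))
  new_ragdel_test(statistic = stat, df = 1,
                  p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                  test_used = "chi_square", table = m)
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Two-sided P by the minimum-likelihood method: with margins fixed, the
#' probabilities of all hypergeometric tables no more likely than the
#' observed one are summed (the common statistical-package definition).
#' A doubling alternative (`method = "doubling"`: twice the smaller
#' one-sided tail, capped at 1) is available behind a flag.
#'
#' @inheritParams chi_square_2x2
#' @param method `"min_likelihood"` (default) or `"doubling"`.
#' @return A `ragdel_test` with `test_used = "fisher"` (no statistic).
#' @export
#' @examples
#' fisher_exact_2x2(0, 17, 55, 577)  # P ~ 0.385
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                             method = c("min_likelihood", "doubling")) {
  method <- match.arg(method)
  m <- .as_2x2(a, b, c, d)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(m) == 0) stop("all-zero table", call. = FALSE)
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  k <- lo:hi
  probs <- stats::dhyper(k, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  p <- if (method == "min_likelihood") {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(probs[k <= m[1, 1]])
    upper <- sum(probs[k >= m[1, 1]])
    min(1, 2 * min(lower, upper))
  }
  new_ragdel_test(statistic = NA_real_, df = NA_real_, p_value = min(1, p),
                  test_used = "fisher", table = m)
}

#' Chi-square or Fisher, chosen by a small-sample rule
#'
#' Switches to Fisher's exact test "when sample groups are small". By
#' default a group is small when the table's smallest margin (row or column
#' total) falls below `threshold` (20): among the reference cohort tables
#' this selects exactly the one subgroup reported with Fisher's test while
#' keeping chi-square for the others, including a 23-sample subgroup whose
#' smallest expected cell is below 5. The textbook expected-count rule
#' (any expected cell < 5) is available via `small_rule = "expected"`.
#'
#' @inheritParams chi_square_2x2
#' @param small_rule `"group_size"` (default) or `"expected"`.
#' @param threshold Margin cutoff for the group-size rule (default 20).
#' @return A `ragdel_test`.
#' @export
contingency_test <- function(a, b = NULL, c = NULL, d = NULL,
                             small_rule = c("group_size", "expected"),
                             threshold = 20) {
  small_rule <- match.arg(small_rule)
  m <- .as_2x2(a, b, c, d)
  small <- if (small_rule == "group_size") {
    min(rowSums(m), colSums(m)) < threshold
  } else {
    any(outer(rowSums(m), colSums(m)) / sum(m) < 5)
  }
  if (small) fisher_exact_2x2(m) else chi_square_2x2(m)
}

#' Build 2x2 contingency tables from a cohort table
#'
#' Cross-tabulates group membership against deletion status. When the
#' grouping column is yes/no (or logical), one table is returned; when it
#' is multi-level, one level-vs-rest table is returned per level. Rows with
#' a missing group value are excluded (cohort classifications commonly have
#' missing values, so totals need not add up to the full cohort).
#'
#' @param data A data frame, one row per sample or one row per aggregated
#'   count (see `weight`).
#' @param group Column (tidy-eval) holding group membership: logical,
#'   `"yes"`/`"no"`, or a multi-level factor.
#' @param deletion Column (tidy-eval) holding deletion status: logical or
#'   `"yes"`/`"no"`/`"pos"`/`"neg"`.
#' @param weight Optional count column (tidy-eval) for pre-aggregated data.
#' @return A tibble with one row per table: `group_label`, `a` (group yes,
#'   deletion+), `b` (yes, deletion-), `c` (no, deletion+), `d` (no,
#'   deletion-), `n_total`.
#' @export
build_tables <- function(data, group, deletion, weight = NULL) {
  gq <- rlang::enquo(group)
  dq <- rlang::enquo(deletion)
  wq <- rlang::enquo(weight)
  g <- rlang::eval_tidy(gq, data)
  del <- rlang::eval_tidy(dq, data)
  w <- if (rlang::quo_is_null(wq)) rep(1, nrow(data)) else
    rlang::eval_tidy(wq, data)
  to_yes <- function(x) {
    if (is.logical(x)) return(x)
    xl <- tolower(as.character(x))
    if (all(xl %in% c("yes", "no", "pos", "neg", "true", "false", NA))) {
      return(xl %in% c("yes", "pos", "true"))
    }
    NULL
  }
  if (!nrow(data)) {
    return(tibble::tibble(group_label = character(), a = numeric(),
                          b = numeric(), c = numeric(), d = numeric(),
                          n_total = numeric()))
  }
  del_yes <- to_yes(del)
  if (is.null(del_yes)) {
    stop("`deletion` must be logical or yes/no-like", call. = FALSE)
  }
  keep <- !is.na(g) & !is.na(del)
  g <- g[keep]; del_yes <- del_yes[keep]; w <- w[keep]
  g_yes <- to_yes(g)
  one_table <- function(in_group, label) {
    tibble::tibble(
      group_label = label,
      a = sum(w[in_group & del_yes]),
      b = sum(w[in_group & !del_yes]),
      c = sum(w[!in_group & del_yes]),
      d = sum(w[!in_group & !del_yes]),
      n_total = sum(w)
    )
  }
  if (!is.null(g_yes)) {
    return(one_table(g_yes, "yes_vs_no"))
  }
  levels <- sort(unique(as.character(g)))
  purrr::map_dfr(levels, function(lv) one_table(as.character(g) == lv, lv))
}

#' Per-group enrichment tests for deletion status
#'
#' Builds one 2x2 table per group via [build_tables()] and applies
#' [contingency_test()] to each (Fisher when any expected count < 5,
#' uncorrected chi-square otherwise).
#'
#' @inheritParams build_tables
#' @return A tibble: table counts plus `test_used`, `statistic`, `df`,
#'   `p_value`.
#' @export
cohort_enrichment <- function(data, group, deletion, weight = NULL) {
  tabs <- build_tables(data, {{ group }}, {{ deletion }}, {{ weight }})
  tests <- purrr::pmap(tabs[c("a", "b", "c", "d")],
                       function(a, b, c, d) contingency_test(a, b, c, d))
  dplyr::bind_cols(
    tabs,
    purrr::map_dfr(tests, tidy)
  )
}

#' Subclonal-deletion screening summary
#'
#' Reproduces the structure of the PCR screen of MLPA-negative samples: per
#' stratum it reports how many samples are deletion-positive in the
#' predominant clone (any `MLPA+` clone), and, among the MLPA-negative
#' samples, how many carry PCR-only subclonal deletions, with the fraction
#' as numerator/denominator. Samples with two or more distinct deletion
#' clones are counted as multiclonal.
#'
#' @param clones A clone-level tibble with `sample_id` and `detection`
#'   columns (see [apply_detection()]); samples absent from it are supplied
#'   via `samples`.
#' @param samples Sample-level tibble with `sample_id` and the `by`
#'   column(s); defines the denominator including deletion-free samples.
#' @param by Character vector of stratification columns in `samples`
#'   (default `"lineage"`).
#' @return A tibble per stratum: `n_samples`, `n_mlpa_pos`, `n_mlpa_neg`,
#'   `n_pcr_only` (MLPA-negative samples with PCR-only clones),
#'   `pcr_only_fraction`, `n_multiclonal`.
#' @export
subclonal_summary <- function(clones, samples, by = "lineage") {
  stopifnot("detection" %in% names(clones),
            all(by %in% names(samples)))
  per_sample <- clones |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      mlpa_pos = any(.data$detection == "MLPA+"),
      pcr_only = any(.data$detection == "PCR-only"),
      n_clones_detected = sum(.data$detection != "undetected"),
      .groups = "drop"
    )
  samples |>
    dplyr::left_join(per_sample, by = "sample_id") |>
    dplyr::mutate(
      mlpa_pos = dplyr::coalesce(.data$mlpa_pos, FALSE),
      pcr_only = dplyr::coalesce(.data$pcr_only, FALSE),
      n_clones_detected = dplyr::coalesce(.data$n_clones_detected, 0L)
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_mlpa_pos = sum(.data$mlpa_pos),
      n_mlpa_neg = sum(!.data$mlpa_pos),
      n_pcr_only = sum(!.data$mlpa_pos & .data$pcr_only),
      pcr_only_fraction = ifelse(.data$n_mlpa_neg > 0,
                                 .data$n_pcr_only / .data$n_mlpa_neg, NA),
      n_multiclonal = sum(.data$n_clones_detected >= 2),
      .groups = "drop"
    )
}

#' Relative frequencies of recurrent deletion types
#'
#' Proportions over the classified (catalogued) labels sum to 1;
#' `"novel"` and unmapped labels are reported separately with `classified
#' = FALSE` and NA proportion.
#'
#' @param labels Character vector of labels from [classify_deletion()].
#' @return A tibble: `label`, `n`, `classified`, `proportion`.
#' @export
deletion_type_frequencies <- function(labels) {
  counts <- tibble::tibble(label = labels) |>
    dplyr::count(.data$label) |>
    dplyr::mutate(classified = !(.data$label %in% c("novel", "unmapped")))
  n_class <- sum(counts$n[counts$classified])
  counts |>
    dplyr::mutate(proportion = ifelse(.data$classified & n_class > 0,
                                      .data$n / n_class, NA_real_)) |>
    dplyr::arrange(dplyr::desc(.data$classified), .data$label)
}
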