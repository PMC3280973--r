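#' ChIP enrichment as percent recovery of input
#'
#' Computes `dilution * 2^(ct_input - ct_chip) * 100` per row. Recovery is
#' strictly increasing in the Ct difference and linear in the dilution
#' factor. Values above 100% are permitted but flagged with a warning,
#' since they usually signal an enrichment artifact or a dilution-factor
#' mistake.
#'
#' @param data A data frame with Ct columns.
#' @param ct_chip,ct_input,dilution Column names (strings) holding the ChIP
#'   Ct, input Ct, and input dilution factor.
#' @return `data` with a `pct_recovery` column added.
#' @export
#' @examples
#' pct_recovery(tibble::tibble(dilution = 0.01, ct_input = 30, ct_chip = 25))
pct_recovery <- function(data, ct_chip = "ct_chip", ct_input = "ct_input",
                         dilution = "dilution") {
  stopifnot(all(c(ct_chip, ct_input, dilution) %in% names(data)))
  dil <- data[[dilution]]
  if (any(dil <= 0)) {
    stop("dilution factor must be positive", call. = FALSE)
  }
  if (any(!is.finite(data[[ct_chip]]) | !is.finite(data[[ct_input]]))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  rec <- dil * 2^(data[[ct_input]] - data[[ct_chip]]) * 100
  if (any(rec > 100)) {
    warning("percent recovery above 100% for ", sum(rec > 100), " row(s)",
            call. = FALSE)
  }
  dplyr::mutate(data, pct_recovery = rec)
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per (sample, gene), the reference-gene
#' Ct is subtracted (dCt), the calibrator sample's dCt is subtracted
#' (ddCt), and the fold change is `2^-ddCt`. The calibrator maps to exactly
#' 1. Fold changes are invariant under adding a constant to all Cts of one
#' gene across all samples (a plate-wide gene offset), but not under
#' per-sample shifts of a single gene.
#'
#' @param data Long tibble with columns `sample_id`, `target` (gene label)
#'   and `ct`; replicate rows allowed.
#' @param calibrator Sample id used as calibrator (fold = 1).
#' @param target Target gene label (default `"BTG1"`).
#' @param reference Reference gene label (default `"HPRT"`); must be
#'   measured in every sample.
#' @return A tibble: `sample_id`, `dct`, `ddct`, `fold_change`.
#' @export
delta_delta_ct <- function(data, calibrator, target = "BTG1",
                           reference = "HPRT") {
  stopifnot(all(c("sample_id", "target", "ct") %in% names(data)))
  if (!calibrator %in% data$sample_id) {
    stop("calibrator sample not present in the data", call. = FALSE)
  }
  means <- data |>
    dplyr::filter(.data$target %in% c(.env$target, .env$reference)) |>
    dplyr::group_by(.data$sample_id, .data$target) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "target", values_from = "ct")
  if (!reference %in% names(means) || anyNA(means[[reference]])) {
    stop("reference gene Ct missing for one or more samples", call. = FALSE)
  }
  if (!target %in% names(means) || anyNA(means[[target]])) {
    stop("target gene Ct missing for one or more samples", call. = FALSE)
  }
  means <- dplyr::mutate(means, dct = .data[[target]] - .data[[reference]])
  cal_dct <- means$dct[means$sample_id == calibrator]
  means |>
    dplyr::mutate(ddct = .data$dct - cal_dct,
                  fold_change = 2^(-.data$ddct)) |>
    dplyr::select("sample_id", "dct", "ddct", "fold_change")
}

#' Two-sample comparison of enrichment or expression values
#'
#' Classical equal-variance (Student) two-sample t-test by default, with
#' Welch's unequal-variance test behind a flag. Two-sided; significance
#' flagged at `alpha`. When both groups have zero variance and equal
#' means the statistic is 0 and P = 1 by convention.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @param var_equal Use the pooled-variance Student test (default TRUE).
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return An object of class `ragdel_test` (see [tidy.ragdel_test()]).
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(11, 12, 13))
compare_groups <- function(x, y, var_equal = TRUE, alpha = 0.05) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  df <- length(x) + length(y) - 2
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(new_ragdel_test(statistic = 0, df = df, p_value = 1,
                             test_used = "student_t",
                             estimate = c(mean(x), mean(y)),
                             significant = FALSE))
    }
    return(new_ragdel_test(statistic = Inf * sign(mean(x) - mean(y)),
                           df = df, p_value = 0, test_used = "student_t",
                           estimate = c(mean(x), mean(y)),
                           significant = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  new_ragdel_test(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    test_used = if (var_equal) "student_t" else "welch_t",
    estimate = unname(tt$estimate),
    significant = tt$p.value < alpha
  )
}
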