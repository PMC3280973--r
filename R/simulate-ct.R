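#' Default ground-truth ChIP enrichment for the simulator
#'
#' A synthetic truth table for two histone marks (H3K4me3, H3K9/14Ac)
#' across four amplicons of the locus (-1 kb promoter, proximal promoter,
#' exon 2 near the breakpoint hotspot, 3'UTR) in three B-lineage and three
#' T-lineage cell lines. The magnitudes are invented (the source experiment
#' reports them only graphically) but reproduce the qualitative structure:
#' both lineages share high promoter H3K4me3, while only B-lineage lines
#' show elevated H3K4me3 at exon 2, and H3K9/14Ac differs between lineages
#' at the proximal promoter only.
#'
#' @return A tibble: `sample_id`, `lineage`, `antibody`, `region`,
#'   `true_recovery` (percent of input).
#' @export
chip_truth_default <- function() {
  b <- c("RS4;11", "Nalm6", "CCRF-SB")
  t <- c("HSB2", "Jurkat", "KARPAS45")
  regions <- c("-1kb prom", "prox prom", "exon 2", "3'UTR")
  grid <- tidyr::crossing(
    sample_id = c(b, t),
    antibody = c("H3K4me3", "H3K9/14Ac"),
    region = regions
  ) |>
    dplyr::mutate(lineage = ifelse(.data$sample_id %in% b, "BCP-ALL",
                                   "T-ALL"))
  grid |>
    dplyr::mutate(true_recovery = dplyr::case_when(
      antibody == "H3K4me3" & region == "prox prom" ~ 20,
      antibody == "H3K4me3" & region == "-1kb prom" ~ 4,
      antibody == "H3K4me3" & region == "exon 2" & lineage == "BCP-ALL" ~ 8,
      antibody == "H3K4me3" & region == "exon 2" ~ 1,
      antibody == "H3K4me3" ~ 0.5,
      antibody == "H3K9/14Ac" & region == "prox prom" &
        lineage == "BCP-ALL" ~ 10,
      antibody == "H3K9/14Ac" & region == "prox prom" ~ 3,
      TRUE ~ 1
    )) |>
    dplyr::select("sample_id", "lineage", "antibody", "region",
                  "true_recovery")
}

#' Simulate ChIP-qPCR Ct tables from true percent-recovery values
#'
#' Inverts the percent-recovery formula
#' `recovery = dilution * 2^(Ct_input - Ct_ChIP) * 100`: given a true
#' recovery, `Ct_ChIP` is placed `log2(recovery / (100 * dilution))` cycles
#' below the input Ct, and independent Gaussian noise (sd `sigma` cycles)
#' is added to each Ct.
#'
#' @param truth Tibble with columns `sample_id`, `antibody`, `region`,
#'   `true_recovery` (and optional extras, carried through). Default
#'   [chip_truth_default()].
#' @param sigma Ct noise standard deviation in cycles (default 0.1; must be
#'   >= 0).
#' @param dilution Input dilution factor in (0, 1] (default 0.01).
#' @param base_ct Mean input Ct (default 30).
#' @param seed Optional seed.
#' @return `truth` with `dilution`, `ct_input`, `ct_chip` columns added.
#' @export
simulate_chip_ct <- function(truth = chip_truth_default(), sigma = 0.1,
                             dilution = 0.01, base_ct = 30, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  stopifnot(dilution > 0, dilution <= 1)
  if (!is.null(seed)) set.seed(.child_seed(seed, "chip_ct"))
  n <- nrow(truth)
  truth |>
    dplyr::mutate(
      dilution = dilution,
      ct_input = base_ct + stats::rnorm(n, 0, sigma),
      ct_chip = base_ct - log2(.data$true_recovery / (100 * dilution)) +
        stats::rnorm(n, 0, sigma)
    )
}

#' Simulate relative-expression qPCR Ct tables from true fold changes
#'
#' Inverts the 2^-ddCt formula: each sample's target Ct is offset from the
#' calibrator's by `-log2(true_fold)` cycles (reference gene Ct held at a
#' common baseline), with `n_replicates` technical replicates and Gaussian
#' Ct noise per well.
#'
#' @param truth Tibble with `sample_id` and `true_fold`; must include the
#'   calibrator sample with `true_fold = 1`.
#' @param calibrator Calibrator sample id (default `"Nalm6"`).
#' @param target,reference Gene labels (defaults `"BTG1"`, `"HPRT"`).
#' @param sigma Ct noise sd in cycles (default 0.1; must be >= 0).
#' @param base_target,base_ref Baseline Cts (defaults 28 and 25).
#' @param n_replicates Technical replicates per well (default 3).
#' @param seed Optional seed.
#' @return A long tibble: `sample_id`, `target` (gene), `role`
#'   (`"calibrator"` or `"unknown"`), `replicate`, `ct`.
#' @export
simulate_qpcr_ct <- function(truth, calibrator = "Nalm6", target = "BTG1",
                             reference = "HPRT", sigma = 0.1,
                             base_target = 28, base_ref = 25,
                             n_replicates = 3, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  stopifnot(all(c("sample_id", "true_fold") %in% names(truth)),
            calibrator %in% truth$sample_id)
  if (!is.null(seed)) set.seed(.child_seed(seed, "qpcr_ct"))
  long <- tidyr::crossing(truth, replicate = seq_len(n_replicates)) |>
    tidyr::crossing(gene = c(target, reference))
  long |>
    dplyr::mutate(
      ct = ifelse(.data$gene == target,
                  base_target - log2(.data$true_fold),
                  base_ref) + stats::rnorm(nrow(long), 0, sigma),
      role = ifelse(.data$sample_id == calibrator, "calibrator", "unknown")
    ) |>
    dplyr::select("sample_id", target = "gene", "role", "replicate", "ct")
}
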