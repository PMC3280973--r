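# deterministic per-stage child seed so stages can rerun in isolation;
# stays below 2^31 - 1
.child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) + 10007 * (h %% 100003)) %% 2147483647)
}

#' Configuration for the synthetic-data generator
#'
#' Bundles the study conditions the generator emulates: subgroup sample
#' sizes and per-subgroup deletion prevalences taken from the cohort table
#' of 722 B-cell-precursor (BCP) ALL cases plus 109 T-ALL cases and 26
#' healthy bone-marrow controls; the multiclonal structure (up to four
#' independent deletion-bearing subclones per sample); the TdT
#' non-templated insertion length distribution; and the detection channels
#' (bulk MLPA, clonal-fraction-limited, versus breakpoint-spanning PCR,
#' sensitive to minor subclones).
#'
#' @param seed Integer seed; every stochastic stage derives its own child
#'   seed from it.
#' @param scale_factor Locus scale; 1 reproduces the full 101-557 kb
#'   deletion range, the default 0.01 gives a ~6 kb locus convenient for
#'   testing (distances scale, motifs and flanks do not).
#' @param n_samples Named integer vector of samples per group. Defaults:
#'   hyperdiploid 160, etv6_runx1 142, bcr_abl1 23, mll 17, other 180,
#'   unknown 200 (722 BCP-ALL in total), t_all 109, normal 26.
#' @param deletion_prob Named vector of per-group probabilities that a
#'   sample carries a clonal (MLPA-detectable) deletion. Defaults are the
#'   observed subgroup rates (0.031, 0.190, 0.261, 0, 0.072, 0.070; zero
#'   for T-ALL and normal), whose weighted mean is 0.090 -- the overall 9%
#'   prevalence.
#' @param subclonal_rate Probability that a BCP-ALL sample *without* a
#'   clonal deletion carries subclonal deletions detectable only by
#'   breakpoint-spanning PCR (default 0.18, the observed 16/89 screen rate).
#' @param clone_count_probs Probabilities of 1..4 independent
#'   deletion-bearing clones in a deletion-positive sample (default
#'   c(0.73, 0.18, 0.06, 0.03): 27% of positives carry more than one).
#' @param tdt_len Named vector `c(min =, max =)` for the uniform insertion
#'   length distribution (default 1-10 nt; 0 allowed).
#' @param mlpa_detect_fraction Minimal clonal fraction detected by bulk
#'   MLPA (default 0.30).
#' @param pcr_detect_fraction Minimal clonal fraction detected by
#'   breakpoint-spanning PCR (default 0.01). Must be below
#'   `mlpa_detect_fraction`.
#' @param ct_noise_sd Gaussian noise on simulated qPCR Ct values, in cycles
#'   (default 0.1; must be >= 0).
#' @param flank Junction flank length emitted per side, bp (default 60).
#' @param ext Extension of the references beyond each breakpoint, bp
#'   (default 30).
#' @param jitter Perturb breakpoints around the RSS cleavage edges to
#'   emulate end processing (default TRUE); see [simulate_deletion()].
#' @param hotspot_core_prob Probability that a jittered telomeric
#'   breakpoint falls in the 10-bp core of the 33-bp hotspot region
#'   (default 0.75).
#' @param non_extendable Resample insertions that could be extended into a
#'   flank (default TRUE), keeping the generating decomposition unique.
#' @return A list of class `ragdel_config`.
#' @export
simulator_config <- function(seed = 1L,
                             scale_factor = 0.01,
                             n_samples = c(hyperdiploid = 160L,
                                           etv6_runx1 = 142L,
                                           bcr_abl1 = 23L,
                                           mll = 17L,
                                           other = 180L,
                                           unknown = 200L,
                                           t_all = 109L,
                                           normal = 26L),
                             deletion_prob = c(hyperdiploid = 0.031,
                                               etv6_runx1 = 0.190,
                                               bcr_abl1 = 0.261,
                                               mll = 0,
                                               other = 0.072,
                                               unknown = 0.070,
                                               t_all = 0,
                                               normal = 0),
                             subclonal_rate = 0.18,
                             clone_count_probs = c(0.73, 0.18, 0.06, 0.03),
                             tdt_len = c(min = 1L, max = 10L),
                             mlpa_detect_fraction = 0.30,
                             pcr_detect_fraction = 0.01,
                             ct_noise_sd = 0.1,
                             flank = 60L,
                             ext = 30L,
                             jitter = TRUE,
                             hotspot_core_prob = 0.75,
                             non_extendable = TRUE) {
  cfg <- structure(list(
    seed = as.integer(seed),
    scale_factor = scale_factor,
    n_samples = n_samples,
    deletion_prob = deletion_prob,
    subclonal_rate = subclonal_rate,
    clone_count_probs = clone_count_probs,
    tdt_len = tdt_len,
    mlpa_detect_fraction = mlpa_detect_fraction,
    pcr_detect_fraction = pcr_detect_fraction,
    ct_noise_sd = ct_noise_sd,
    flank = as.integer(flank),
    ext = as.integer(ext),
    jitter = jitter,
    hotspot_core_prob = hotspot_core_prob,
    non_extendable = non_extendable
  ), class = "ragdel_config")
  v <- validate_simulator_config(cfg)
  if (nrow(v)) {
    stop("invalid simulator config:\n", paste0("  - ", v$message,
                                               collapse = "\n"),
         call. = FALSE)
  }
  cfg
}

#' Validate a simulator configuration
#'
#' @param config A [simulator_config()]-shaped list.
#' @return A tibble of violations (`field`, `message`); zero rows when the
#'   configuration is valid.
#' @export
validate_simulator_config <- function(config) {
  bad <- list()
  chk <- function(ok, field, message) {
    if (!isTRUE(ok)) bad[[length(bad) + 1L]] <<-
        tibble::tibble(field = field, message = message)
  }
  chk(is.numeric(config$scale_factor) && config$scale_factor > 0,
      "scale_factor", "scale_factor must be > 0")
  chk(all(config$deletion_prob >= 0 & config$deletion_prob <= 1),
      "deletion_prob", "deletion_prob values must be in [0, 1]")
  chk(config$subclonal_rate >= 0 && config$subclonal_rate <= 1,
      "subclonal_rate", "subclonal_rate must be in [0, 1]")
  chk(config$mlpa_detect_fraction > config$pcr_detect_fraction,
      "mlpa_detect_fraction",
      "mlpa_detect_fraction must exceed pcr_detect_fraction (MLPA is the less sensitive bulk assay)")
  chk(config$pcr_detect_fraction > 0, "pcr_detect_fraction",
      "pcr_detect_fraction must be > 0")
  chk(config$ct_noise_sd >= 0, "ct_noise_sd", "ct_noise_sd must be >= 0")
  chk(all(config$n_samples >= 0), "n_samples",
      "n_samples must be non-negative")
  chk(sum(config$n_samples) > 0, "n_samples",
      "at least one group must have samples")
  chk(all(names(config$deletion_prob) %in% names(config$n_samples)) &&
        all(names(config$n_samples) %in% names(config$deletion_prob)),
      "deletion_prob", "deletion_prob and n_samples must use the same group names")
  chk(abs(sum(config$clone_count_probs) - 1) < 1e-8, "clone_count_probs",
      "clone_count_probs must sum to 1")
  chk(config$tdt_len[["min"]] >= 0 &&
        config$tdt_len[["max"]] >= config$tdt_len[["min"]],
      "tdt_len", "tdt_len must satisfy 0 <= min <= max")
  if (length(bad)) dplyr::bind_rows(bad) else
    tibble::tibble(field = character(), message = character())
}

#' @export
print.ragdel_config <- function(x, ...) {
  cat("<ragdel_config> seed", x$seed, "scale", x$scale_factor, "\n")
  cat("  groups:", paste0(names(x$n_samples), "=", x$n_samples,
                          collapse = " "), "\n")
  cat("  detection: MLPA >=", x$mlpa_detect_fraction,
      "| PCR >=", x$pcr_detect_fraction, "\n")
  invisible(x)
}
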