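.lineage_of <- function(group) {
  dplyr::case_when(
    group == "t_all" ~ "T-ALL",
    group == "normal" ~ "normal",
    TRUE ~ "BCP-ALL"
  )
}

# symmetric Dirichlet over k clones + a residual normal compartment,
# rejection-sampled to satisfy the detection-class constraint
.draw_fractions <- function(k, kind, mlpa, pcr, max_iter = 2000L) {
  for (i in seq_len(max_iter)) {
    g <- stats::rgamma(k + 1L, shape = 1)
    f <- g / sum(g)
    clones <- sort(f[seq_len(k)], decreasing = TRUE)
    if (kind == "clonal") {
      if (clones[1] >= mlpa) return(clones)
    } else {
      if (clones[1] < mlpa && clones[1] >= pcr) return(clones)
    }
  }
  # fall back to a feasible deterministic assignment
  if (kind == "clonal") {
    f <- rep((1 - mlpa) / (k + 1), k)
    f[1] <- mlpa
    sort(f, decreasing = TRUE)
  } else {
    rep((pcr + mlpa) / 2 / k, k)
  }
}

#' Simulate a multiclonal leukemia cohort with focal deletions
#'
#' Draws one sample per row of the configured group sizes. A BCP-ALL sample
#' carries a clonal (MLPA-detectable) deletion with its subgroup's
#' prevalence; otherwise it carries PCR-only subclonal deletions with
#' probability `subclonal_rate`. Deletion-positive samples hold 1-4
#' independent deletion clones (each an independent [simulate_deletion()]
#' event with its own junction), with clonal fractions drawn from a
#' symmetric Dirichlet over the clones plus a residual normal compartment,
#' rejection-sampled so that clonal samples have a major clone at or above
#' the MLPA detection fraction and subclonal-only samples stay below it.
#' T-ALL and normal samples never carry deletions.
#'
#' @param config A [simulator_config()].
#' @param locus Optional pre-built `ragdel_locus` (default: simulated from
#'   `config`).
#' @return An object of class `ragdel_cohort`: list with `samples` (tibble:
#'   `sample_id`, `lineage`, `subgroup`, `timepoint`, `n_clones`), `clones`
#'   (tibble: sample columns plus `clone_id`, `deletion_type`,
#'   `clonal_fraction` and the full deletion-event fields), `locus`, and
#'   `config`.
#' @export
#' @examples
#' co <- simulate_cohort(simulator_config(seed = 3,
#'   n_samples = c(etv6_runx1 = 30L, t_all = 10L),
#'   deletion_prob = c(etv6_runx1 = 0.19, t_all = 0)))
#' co$samples
simulate_cohort <- function(config = simulator_config(), locus = NULL) {
  if (sum(config$n_samples) == 0) {
    stop("n_samples is zero for all groups", call. = FALSE)
  }
  if (is.null(locus)) locus <- simulate_locus(config)
  set.seed(.child_seed(config$seed, "cohort"))

  groups <- rep(names(config$n_samples), config$n_samples)
  n_tot <- length(groups)
  ids <- sprintf("S%04d", seq_len(n_tot))
  lineage <- .lineage_of(groups)

  samples <- vector("list", n_tot)
  clones <- vector("list", n_tot)
  kprobs <- config$clone_count_probs
  for (i in seq_len(n_tot)) {
    g <- groups[i]
    p <- config$deletion_prob[[g]]
    is_bcp <- lineage[i] == "BCP-ALL"
    clonal <- stats::runif(1) < p
    subclonal <- !clonal && is_bcp && stats::runif(1) < config$subclonal_rate
    kind <- if (clonal) "clonal" else if (subclonal) "subclonal" else "none"
    k <- 0L
    if (kind != "none") {
      k <- sample.int(length(kprobs), 1, prob = kprobs)
      fr <- .draw_fractions(k, kind, config$mlpa_detect_fraction,
                            config$pcr_detect_fraction)
      ev <- simulate_deletion(locus, n = k, config = config)
      clones[[i]] <- dplyr::bind_cols(
        tibble::tibble(
          sample_id = ids[i], lineage = lineage[i],
          subgroup = if (is_bcp) g else NA_character_,
          timepoint = "diagnosis",
          clone_id = paste0(ids[i], "_c", seq_len(k)),
          clonal_fraction = fr
        ),
        dplyr::select(ev, -"event_id")
      )
    }
    samples[[i]] <- tibble::tibble(
      sample_id = ids[i], lineage = lineage[i],
      subgroup = if (is_bcp) g else NA_character_,
      timepoint = "diagnosis", n_clones = k
    )
  }
  clones <- dplyr::bind_rows(clones)
  if (nrow(clones)) {
    clones <- dplyr::rename(clones, deletion_type = "site_label")
  } else {
    clones <- tibble::tibble(
      sample_id = character(), lineage = character(),
      subgroup = character(), timepoint = character(),
      clone_id = character(), clonal_fraction = double(),
      deletion_type = character()
    )
  }
  structure(list(
    samples = dplyr::bind_rows(samples),
    clones = clones,
    locus = locus,
    config = config
  ), class = "ragdel_cohort")
}

#' @export
print.ragdel_cohort <- function(x, ...) {
  cat(sprintf("<ragdel_cohort> %d samples, %d deletion clones in %d samples\n",
              nrow(x$samples), nrow(x$clones),
              sum(x$samples$n_clones > 0)))
  invisible(x)
}

#' Label deletion clones by detection channel
#'
#' A clone is `MLPA+` when its clonal fraction reaches the bulk MLPA
#' detection fraction, `PCR-only` when it is detectable only by
#' breakpoint-spanning PCR (fraction in `[pcr, mlpa)`), and `undetected`
#' below the PCR limit. Labels are monotone in the fraction.
#'
#' @param data A data frame with a `clonal_fraction` column (e.g. the
#'   `clones` tibble of a `ragdel_cohort`).
#' @param mlpa_detect_fraction,pcr_detect_fraction Detection thresholds
#'   (defaults 0.30 and 0.01).
#' @return `data` with a `detection` column added.
#' @export
#' @examples
#' apply_detection(tibble::tibble(clonal_fraction = c(0.5, 0.05, 0.001)))
apply_detection <- function(data, mlpa_detect_fraction = 0.30,
                            pcr_detect_fraction = 0.01) {
  stopifnot("clonal_fraction" %in% names(data),
            mlpa_detect_fraction > pcr_detect_fraction)
  dplyr::mutate(data, detection = dplyr::case_when(
    .data$clonal_fraction >= mlpa_detect_fraction ~ "MLPA+",
    .data$clonal_fraction >= pcr_detect_fraction ~ "PCR-only",
    TRUE ~ "undetected"
  ))
}

#' Cohort clone table in the interchange TSV layout
#'
#' One row per deletion clone; samples without deletions appear once with
#' NA clone fields. The column set matches the on-disk cohort TSV:
#' `sample_id lineage subgroup timepoint clone_id deletion_type
#' clonal_fraction`.
#'
#' @param cohort A `ragdel_cohort`.
#' @return A tibble.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "ragdel_cohort"))
  base <- dplyr::select(cohort$samples, "sample_id", "lineage", "subgroup",
                        "timepoint")
  cl <- dplyr::select(cohort$clones, "sample_id", "clone_id",
                      "deletion_type", "clonal_fraction")
  dplyr::left_join(base, cl, by = "sample_id")
}
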