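#' Full-run configuration
#'
#' Bundles the simulator configuration with the analysis parameters of the
#' downstream stages (RSS scan thresholds, breakpoint clustering tolerance,
#' hotspot fraction, detection thresholds) and output settings.
#'
#' @param seed Master seed; each stage derives a deterministic child seed
#'   from it, so stages can be rerun in isolation.
#' @param simulator A [simulator_config()]; its seed is overridden by
#'   `seed`.
#' @param scan List of [scan_rss()] arguments: `max_heptamer_mm`,
#'   `max_nonamer_mm`, `require_cac`, `spacer_class`.
#' @param clustering List: `tolerance` (single-linkage clustering, bp),
#'   `classify_tolerance` (catalog matching, bp), `hotspot_fraction`.
#' @param report_format `"tsv"` or `"json"`.
#' @return A list of class `ragdel_run_config`.
#' @export
run_config <- function(seed = 1L,
                       simulator = simulator_config(seed = seed),
                       scan = list(max_heptamer_mm = 3, max_nonamer_mm = 6,
                                   require_cac = TRUE,
                                   spacer_class = "both"),
                       clustering = list(tolerance = 10,
                                         classify_tolerance = 50,
                                         hotspot_fraction = 0.75),
                       report_format = c("tsv", "json")) {
  simulator$seed <- as.integer(seed)
  structure(list(
    seed = as.integer(seed),
    simulator = simulator,
    scan = scan,
    clustering = clustering,
    report_format = match.arg(report_format)
  ), class = "ragdel_run_config")
}

#' Read a run configuration from YAML
#'
#' Flat keys under `simulator`, `scan` and `clustering` blocks override
#' the defaults of [run_config()] and [simulator_config()].
#'
#' @param path YAML file.
#' @return A `ragdel_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulator %||% list()
  if (!is.null(sim_args$n_samples)) {
    sim_args$n_samples <- unlist(sim_args$n_samples)
  }
  if (!is.null(sim_args$deletion_prob)) {
    sim_args$deletion_prob <- unlist(sim_args$deletion_prob)
  }
  if (!is.null(sim_args$tdt_len)) sim_args$tdt_len <- unlist(sim_args$tdt_len)
  seed <- y$seed %||% 1L
  sim_args$seed <- seed
  cfg <- run_config(
    seed = seed,
    simulator = do.call(simulator_config, sim_args),
    report_format = y$report_format %||% "tsv"
  )
  for (blk in c("scan", "clustering")) {
    if (!is.null(y[[blk]])) cfg[[blk]] <- utils::modifyList(cfg[[blk]],
                                                            y[[blk]])
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a run configuration
#'
#' Checks every configuration invariant, including geometric feasibility of
#' the locus scale, and returns the violations rather than raising.
#'
#' @param config A `ragdel_run_config`.
#' @return A tibble of violations (`field`, `message`); zero rows means ok.
#' @export
validate_config <- function(config) {
  bad <- validate_simulator_config(config$simulator)
  add <- function(field, message) {
    bad <<- dplyr::bind_rows(bad, tibble::tibble(field = field,
                                                 message = message))
  }
  sc <- config$scan
  if (sc$max_heptamer_mm < 0 || sc$max_nonamer_mm < 0) {
    add("scan", "mismatch thresholds must be non-negative")
  }
  cl <- config$clustering
  if (cl$tolerance < 0) add("clustering.tolerance", "tolerance must be >= 0")
  if (cl$hotspot_fraction <= 0 || cl$hotspot_fraction > 1) {
    add("clustering.hotspot_fraction", "hotspot_fraction must be in (0, 1]")
  }
  # geometric feasibility of the locus at this scale
  feas <- tryCatch({
    simulate_locus(config$simulator)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(feas) && grepl("scale_factor", feas)) {
    add("simulator.scale_factor", feas)
  }
  bad
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full simulate-scan-decompose-classify-stats pipeline
#'
#' Deterministic under a fixed seed. Stages: (1) simulate the locus;
#' (2) simulate the multiclonal cohort; (3) label clones by detection
#' channel; (4) scan the locus for candidate RSSs and annotate the true
#' breakpoint positions with their best nearby candidate; (5) decompose
#' every clone's junction sequence; (6) build the breakpoint-cluster
#' catalog from the observed centromeric breakpoints and classify each
#' event; (7) compute per-subgroup enrichment statistics, the
#' subclonal-screen summary, deletion-type frequencies, and the telomeric
#' hotspot window.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, the report tables, locus
#'   FASTA, truth BED, cohort TSV, junction FASTA, deletion VCF and a
#'   manifest are written there.
#' @return An object of class `ragdel_report`: a list of tibbles
#'   (`samples`, `clones`, `rss_candidates`, `breakpoint_annotation`,
#'   `junction_calls`, `catalog`, `classification`, `type_frequencies`,
#'   `enrichment`, `subclonal`, `hotspot`, `unique_junctions`) plus
#'   `locus` and `config`.
#' @export
run_full <- function(config = run_config(), out_dir = NULL) {
  locus <- .stage("simulate_locus", simulate_locus(config$simulator))
  cohort <- .stage("simulate_cohort",
                   simulate_cohort(config$simulator, locus = locus))
  clones <- .stage("apply_detection", apply_detection(
    cohort$clones,
    mlpa_detect_fraction = config$simulator$mlpa_detect_fraction,
    pcr_detect_fraction = config$simulator$pcr_detect_fraction))

  sc <- config$scan
  candidates <- .stage("scan_rss", scan_rss(
    locus$sequence, spacer_class = sc$spacer_class,
    max_heptamer_mm = sc$max_heptamer_mm,
    max_nonamer_mm = sc$max_nonamer_mm,
    require_cac = sc$require_cac, contig = "locus"))

  truth_bps <- c(locus$hotspot$cleavage_edge, locus$distal_sites$breakpoint)
  annotation <- .stage("annotate_breakpoints",
                       annotate_breakpoints(candidates, truth_bps))

  calls <- .stage("decompose", {
    if (nrow(clones)) {
      decompose_junctions(
        dplyr::transmute(clones, sample_id = .data$sample_id,
                         junction_id = .data$clone_id,
                         junction = .data$junction,
                         proximal_ref = .data$proximal_ref,
                         distal_ref = .data$distal_ref))
    } else {
      tibble::tibble(sample_id = character(), junction_id = character(),
                     status = character(), proximal_break = integer(),
                     distal_break = integer(), inserted_nt = character(),
                     microhomology_len = integer(),
                     microhomology_seq = character())
    }
  })

  cl <- config$clustering
  stats_block <- .stage("stats", {
    if (nrow(clones)) {
      # map per-junction breakpoints back to locus coordinates
      obs <- dplyr::left_join(
        calls,
        dplyr::select(clones, junction_id = "clone_id", "prox_ref_start",
                      "dist_ref_start", "deletion_type"),
        by = "junction_id") |>
        dplyr::filter(.data$status == "ok") |>
        dplyr::mutate(
          prox_locus = .data$prox_ref_start + .data$proximal_break,
          dist_locus = .data$dist_ref_start + .data$distal_break)
      catalog <- cluster_breakpoints(obs$dist_locus,
                                     tolerance = cl$tolerance)
      classification <- classify_deletion(obs$dist_locus, catalog,
                                          tolerance = cl$classify_tolerance)
      hotspot <- hotspot_window(obs$prox_locus,
                                fraction = cl$hotspot_fraction)
      freqs <- deletion_type_frequencies(classification$label)
      list(catalog = catalog,
           classification = dplyr::bind_cols(
             dplyr::select(obs, "sample_id", "junction_id",
                           truth_type = "deletion_type"),
             dplyr::select(classification, "label", "distance")),
           hotspot = hotspot, type_frequencies = freqs)
    } else {
      list(catalog = tibble::tibble(), classification = tibble::tibble(),
           hotspot = tibble::tibble(), type_frequencies = tibble::tibble())
    }
  })

  enrichment <- .stage("enrichment", {
    status <- clones |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(mlpa_pos = any(.data$detection == "MLPA+"),
                       .groups = "drop")
    per_sample <- cohort$samples |>
      dplyr::left_join(status, by = "sample_id") |>
      dplyr::mutate(mlpa_pos = dplyr::coalesce(.data$mlpa_pos, FALSE))
    bcp <- dplyr::filter(per_sample, .data$lineage == "BCP-ALL")
    lineage_tab <- cohort_enrichment(
      dplyr::mutate(per_sample,
                    is_t = .data$lineage == "T-ALL") |>
        dplyr::filter(.data$lineage %in% c("BCP-ALL", "T-ALL")),
      group = .data$is_t, deletion = .data$mlpa_pos) |>
      dplyr::mutate(group_label = "T-ALL_vs_BCP-ALL")
    subgroup_tab <- if (nrow(bcp) && length(unique(bcp$subgroup)) > 1) {
      cohort_enrichment(bcp, group = .data$subgroup,
                        deletion = .data$mlpa_pos)
    } else {
      tibble::tibble()
    }
    dplyr::bind_rows(lineage_tab, subgroup_tab)
  })

  subclonal <- .stage("subclonal_summary",
                      subclonal_summary(clones, cohort$samples,
                                        by = "lineage"))

  uniq <- .stage("unique_junctions", {
    if (nrow(calls)) count_unique_junctions(calls) else
      tibble::tibble(sample_id = character(),
                     n_unique_junctions = integer())
  })

  report <- structure(list(
    samples = cohort$samples,
    clones = clones,
    rss_candidates = candidates,
    breakpoint_annotation = annotation,
    junction_calls = calls,
    catalog = stats_block$catalog,
    classification = stats_block$classification,
    type_frequencies = stats_block$type_frequencies,
    enrichment = enrichment,
    subclonal = subclonal,
    hotspot = stats_block$hotspot,
    unique_junctions = uniq,
    locus = locus,
    config = config
  ), class = "ragdel_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.ragdel_report <- function(x, ...) {
  cat("<ragdel_report>\n")
  cat(sprintf("  samples: %d | deletion clones: %d | RSS candidates: %d\n",
              nrow(x$samples), nrow(x$clones), nrow(x$rss_candidates)))
  if (nrow(x$hotspot)) {
    cat(sprintf("  hotspot window: %d bp [%d, %d] (%d/%d breakpoints)\n",
                x$hotspot$window_length, x$hotspot$start, x$hotspot$end,
                x$hotspot$n_inside, x$hotspot$n_total))
  }
  if (nrow(x$enrichment)) {
    cat("  enrichment:\n")
    for (i in seq_len(nrow(x$enrichment))) {
      cat(sprintf("    %-20s %s P = %.4g\n", x$enrichment$group_label[i],
                  x$enrichment$test_used[i], x$enrichment$p_value[i]))
    }
  }
  invisible(x)
}

#' Write a pipeline report bundle to a directory
#'
#' Emits the report tables (TSV or JSON per the configuration), the locus
#' FASTA, truth BED, cohort TSV, junction FASTA, deletion VCF, and a
#' `manifest.json` listing the files written.
#'
#' @param report A `ragdel_report`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- report$config$report_format
  files <- character()
  emit <- function(x, name) {
    if (!is.data.frame(x) || !nrow(x)) return()
    if (fmt == "json") {
      p <- file.path(out_dir, paste0(name, ".json"))
      jsonlite::write_json(x, p, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
    } else {
      p <- file.path(out_dir, paste0(name, ".tsv"))
      x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
      readr::write_tsv(x, p)
    }
    files <<- c(files, p)
  }
  for (name in c("samples", "clones", "rss_candidates",
                 "breakpoint_annotation", "junction_calls", "catalog",
                 "classification", "type_frequencies", "enrichment",
                 "subclonal", "hotspot", "unique_junctions")) {
    tab <- report[[name]]
    if (name == "clones" && nrow(tab)) {
      tab <- dplyr::select(tab, -dplyr::any_of(c("junction", "proximal_ref",
                                                 "distal_ref")))
    }
    emit(tab, name)
  }
  p <- file.path(out_dir, "locus.fa")
  write_fasta(c(locus = report$locus$sequence), p)
  files <- c(files, p)
  p <- file.path(out_dir, "locus_truth.bed")
  write_bed(locus_truth_bed(report$locus), p)
  files <- c(files, p)
  if (nrow(report$clones)) {
    p <- file.path(out_dir, "junctions.fa")
    write_junctions_fasta(report$clones, p)
    files <- c(files, p)
    p <- file.path(out_dir, "deletions.vcf")
    write_deletions_vcf(report$clones, p, contig = "locus",
                        contig_length = report$locus$locus_length)
    files <- c(files, p)
  }
  manifest <- tibble::tibble(file = basename(files))
  jsonlite::write_json(list(seed = report$config$seed,
                            files = manifest$file),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
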