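#' Write sequences to FASTA
#'
#' @param sequences Named character vector of DNA sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a BED-style tibble (0-based half-open) to disk
#'
#' @param bed Tibble with at least `chrom`, `start`, `end`.
#' @param path Output file.
#' @export
write_bed <- function(bed, path) {
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write the cohort clone table as TSV
#'
#' Layout: `sample_id lineage subgroup timepoint clone_id deletion_type
#' clonal_fraction`, one row per clone (deletion-free samples once with NA
#' clone fields).
#'
#' @param cohort A `ragdel_cohort`.
#' @param path Output file.
#' @export
write_cohort_tsv <- function(cohort, path) {
  readr::write_tsv(cohort_table(cohort), path)
  invisible(path)
}

#' Write per-clone junction sequences to FASTA
#'
#' @param clones Clone tibble with `clone_id` and `junction` columns.
#' @param path Output file.
#' @export
write_junctions_fasta <- function(clones, path) {
  stopifnot(all(c("clone_id", "junction") %in% names(clones)))
  write_fasta(stats::setNames(clones$junction, clones$clone_id), path)
}

#' Write deletion events as minimal VCF 4.2 symbolic DEL records
#'
#' One `SVTYPE=DEL` record per event with 1-based `POS` at the base before
#' the deleted interval, `END` at its last deleted base, and the
#' non-templated junction insertion in `INS_SEQ`.
#'
#' @param events Tibble with `proximal_break`, `distal_break` (0-based
#'   half-open deleted interval) and optional `inserted_nt`, `clone_id`.
#' @param path Output file.
#' @param contig Contig name (default `"locus"`).
#' @param contig_length Contig length for the VCF header.
#' @export
write_deletions_vcf <- function(events, path, contig = "locus",
                                contig_length = NULL) {
  stopifnot(all(c("proximal_break", "distal_break") %in% names(events)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ragdelscan",
    if (!is.null(contig_length))
      sprintf("##contig=<ID=%s,length=%d>", contig, contig_length)
    else sprintf("##contig=<ID=%s>", contig),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=INS_SEQ,Number=1,Type=String,Description=\"Non-templated nucleotides at the junction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  ids <- if ("clone_id" %in% names(events)) events$clone_id else
    sprintf("del%04d", seq_len(nrow(events)))
  ins <- if ("inserted_nt" %in% names(events)) events$inserted_nt else
    rep("", nrow(events))
  recs <- sprintf(
    "%s\t%d\t%s\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=%d;SVLEN=%d%s",
    contig,
    events$proximal_break,        # 1-based position of base before the DEL
    ids,
    events$distal_break,          # 1-based last deleted base
    -(events$distal_break - events$proximal_break),
    ifelse(nchar(ins) > 0, paste0(";INS_SEQ=", ins), "")
  )
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Published per-classification deletion counts (packaged fixture)
#'
#' Aggregated 2x2 counts of focal deletion status across lineages and
#' cytogenetic subgroup classifications of a 722-sample BCP-ALL / 109-sample
#' T-ALL diagnostic cohort, in the long layout consumed by
#' [build_tables()] (`classification`, `in_group`, `deletion`, `n`).
#' Classifications overlap and have missing values, so totals differ per
#' classification.
#'
#' @return A tibble.
#' @export
cohort_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "cohort_deletion_counts.tsv",
                package = "ragdelscan"),
    col_types = readr::cols(
      classification = readr::col_character(),
      in_group = readr::col_character(),
      deletion = readr::col_character(),
      n = readr::col_integer()
    )
  )
}
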